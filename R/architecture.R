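# Declarative 1D-CNN architecture descriptions with analytic shape
# propagation, exact trainable-parameter counts and a documented FLOP
# convention (FLOPs = 2 x multiply-accumulates over conv and dense layers).

#' Layer descriptors
#'
#' Small constructors for the closed set of layer kinds used by the
#' reference architectures.
#'
#' @param filters,kernel_size,padding,activation conv parameters; padding is
#'   `"same"` or `"valid"`, activation `"relu"` or `"none"`.
#' @param pool_size,stride max-pool parameters (valid padding).
#' @param rate dropout rate in `[0, 1)`.
#' @param units dense layer width.
#' @return a list of class `layer_descriptor`.
#' @name layers
NULL

.layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_descriptor")
}

#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel_size, padding = c("same", "valid"),
                         activation = c("relu", "none")) {
  stopifnot(filters >= 1, kernel_size >= 1)
  .layer("conv1d", filters = as.integer(filters),
         kernel_size = as.integer(kernel_size),
         padding = match.arg(padding), activation = match.arg(activation))
}

#' @rdname layers
#' @export
layer_maxpool1d <- function(pool_size, stride = pool_size) {
  stopifnot(pool_size >= 1, stride >= 1)
  .layer("maxpool1d", pool_size = as.integer(pool_size),
         stride = as.integer(stride), padding = "valid")
}

#' @rdname layers
#' @export
layer_flatten <- function() .layer("flatten")

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  .layer("dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_dense <- function(units, activation = c("relu", "none")) {
  stopifnot(units >= 1)
  .layer("dense", units = as.integer(units), activation = match.arg(activation))
}

#' @rdname layers
#' @export
layer_softmax <- function() .layer("softmax")

#' Assemble a model specification
#'
#' @param name model name.
#' @param input_len input window length in samples.
#' @param input_channels input channels (1 for single-lead ECG).
#' @param layers ordered list of [layers] descriptors; must contain exactly
#'   one flatten, end in softmax, and have a final dense width equal to
#'   `n_classes`.
#' @param n_classes number of output classes.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, input_len, input_channels = 1L, layers,
                       n_classes) {
  stopifnot(is.character(name), input_len >= 1, input_channels >= 1,
            n_classes >= 2)
  kinds <- vapply(layers, `[[`, "", "kind")
  if (sum(kinds == "flatten") != 1L) {
    stop("a model_spec must contain exactly one flatten layer")
  }
  if (tail(kinds, 1) != "softmax") {
    stop("the final layer must be softmax")
  }
  dense_units <- vapply(layers[kinds == "dense"], `[[`, 0L, "units")
  if (!length(dense_units) || tail(dense_units, 1) != n_classes) {
    stop("the last dense layer must have n_classes = ", n_classes, " units")
  }
  structure(list(name = name, input_len = as.integer(input_len),
                 input_channels = as.integer(input_channels),
                 layers = layers, n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' The two reference architectures
#'
#' `"mitbih_multiclass"`: input 1000 x 1; four same-padded ReLU conv layers
#' with 16/32/64/128 filters and kernels 11/13/15/17, each followed by a
#' size-2 max-pool (the first with stride 1, the rest stride 2, valid),
#' giving the length chain 1000 -> 999 -> 499 -> 249 -> 124 and a
#' 15,872-element flatten; then dropout, dense 35 (ReLU), dense 5, softmax.
#'
#' `"simband_binary"`: the same conv stack but every max-pool has size 3 and
#' stride 2 (valid), giving 499 -> 249 -> 124 -> 61 and a 7,808-element
#' flatten; then dropout, dense 128 (ReLU), dense 2, softmax.
#'
#' @param name `"mitbih_multiclass"` or `"simband_binary"`.
#' @param dropout_rate dropout rate for the head (default 0.5).
#' @return a [model_spec()].
#' @export
#' @examples
#' propagate_shapes(reference_spec("mitbih_multiclass"))
reference_spec <- function(name = c("mitbih_multiclass", "simband_binary"),
                           dropout_rate = 0.5) {
  if (!is.character(name) || !name[1] %in%
      c("mitbih_multiclass", "simband_binary")) {
    stop("unknown reference spec '", name[1],
         "'; valid names: mitbih_multiclass, simband_binary")
  }
  name <- name[1]
  filters <- c(16L, 32L, 64L, 128L)
  kernels <- c(11L, 13L, 15L, 17L)
  conv_stack <- function(pool_sizes, pool_strides) {
    out <- list()
    for (i in 1:4) {
      out[[2 * i - 1]] <- layer_conv1d(filters[i], kernels[i], "same", "relu")
      out[[2 * i]] <- layer_maxpool1d(pool_sizes[i], pool_strides[i])
    }
    out
  }
  if (name == "mitbih_multiclass") {
    layers <- c(conv_stack(rep(2L, 4), c(1L, 2L, 2L, 2L)),
                list(layer_flatten(), layer_dropout(dropout_rate),
                     layer_dense(35L, "relu"), layer_dense(5L, "none"),
                     layer_softmax()))
    model_spec(name, 1000L, 1L, layers, 5L)
  } else {
    layers <- c(conv_stack(rep(3L, 4), rep(2L, 4)),
                list(layer_flatten(), layer_dropout(dropout_rate),
                     layer_dense(128L, "relu"), layer_dense(2L, "none"),
                     layer_softmax()))
    model_spec(name, 1000L, 1L, layers, 2L)
  }
}

#' Analytic shape propagation
#'
#' Propagates (length, channels) through the layer list: same-padded conv
#' preserves length, a valid max-pool maps length L to
#' `floor((L - pool) / stride) + 1`, flatten collapses to length x channels.
#'
#' @param spec a [model_spec()].
#' @return object of class `shape_trace`: data frame of per-layer output
#'   shapes with attribute `flatten_size`.
#' @export
propagate_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  len <- spec$input_len
  ch <- spec$input_channels
  flat <- NA_integer_
  rows <- data.frame(layer = integer(), kind = character(),
                     out_len = integer(), out_channels = integer())
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    switch(ly$kind,
      conv1d = {
        if (ly$padding == "valid") len <- len - ly$kernel_size + 1L
        ch <- ly$filters
      },
      maxpool1d = {
        len <- (len - ly$pool_size) %/% ly$stride + 1L
      },
      flatten = {
        flat <- len * ch
        len <- flat
        ch <- 1L
      },
      dense = {
        len <- ly$units
        ch <- 1L
      },
      dropout = NULL,
      softmax = NULL)
    if (len <= 0L) {
      stop("non-positive length at layer ", i, " (", ly$kind, ")")
    }
    rows <- rbind(rows, data.frame(layer = i, kind = ly$kind,
                                   out_len = len, out_channels = ch))
  }
  if (is.na(flat)) flat <- spec$input_len * spec$input_channels
  structure(rows, flatten_size = as.integer(flat), class =
              c("shape_trace", "data.frame"))
}

#' @export
print.shape_trace <- function(x, ...) {
  cat("shape trace (out_len x out_channels per layer):\n")
  print.data.frame(x)
  cat("flatten size:", attr(x, "flatten_size"), "\n")
  invisible(x)
}

#' Exact trainable-parameter count
#'
#' Conv layer: `kernel_size * in_channels * filters + filters` (weights plus
#' biases); dense layer: `in * units + units`; pooling, flatten, dropout and
#' softmax contribute nothing.  Matches the realized training engine's
#' parameter total exactly.
#'
#' @param spec a [model_spec()].
#' @return integer parameter total.
#' @export
#' @examples
#' count_parameters(reference_spec("simband_binary")) # 1,176,866
count_parameters <- function(spec) {
  sum(.per_layer_accounting(spec)$params)
}

#' FLOP estimate under the 2 x MAC convention
#'
#' FLOPs are counted as two per multiply-accumulate: a conv layer costs
#' `2 * out_len * kernel_size * in_channels * filters`, a dense layer
#' `2 * in * units`.  Biases, pooling and activations are ignored.  This is
#' the standard convention of common profiler tools; other counters that
#' include bias adds or activation ops will report different totals.
#'
#' @param spec a [model_spec()].
#' @return total FLOPs for one forward pass on one window.
#' @export
estimate_flops <- function(spec) {
  sum(.per_layer_accounting(spec)$flops)
}

# Shared per-layer params/FLOPs walk.
.per_layer_accounting <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  len <- spec$input_len
  ch <- spec$input_channels
  params <- numeric(0)
  flops <- numeric(0)
  for (ly in spec$layers) {
    p <- 0; f <- 0
    switch(ly$kind,
      conv1d = {
        out_len <- if (ly$padding == "same") len else len - ly$kernel_size + 1L
        p <- ly$kernel_size * ch * ly$filters + ly$filters
        f <- 2 * out_len * ly$kernel_size * ch * ly$filters
        len <- out_len
        ch <- ly$filters
      },
      maxpool1d = {
        len <- (len - ly$pool_size) %/% ly$stride + 1L
      },
      flatten = {
        len <- len * ch
        ch <- 1L
      },
      dense = {
        p <- len * ly$units + ly$units
        f <- 2 * len * ly$units
        len <- ly$units
      },
      dropout = NULL,
      softmax = NULL)
    params <- c(params, p)
    flops <- c(flops, f)
  }
  list(params = params, flops = flops)
}

#' Ablation variants of a reference architecture
#'
#' `"three_conv"` removes the last conv + pool pair; `"kernel_plus_two"`
#' adds 2 to every conv kernel size.  All other fields are unchanged.
#'
#' @param base a [model_spec()].
#' @param variant `"three_conv"` or `"kernel_plus_two"`.
#' @return a [model_spec()].
#' @export
ablation_spec <- function(base, variant = c("three_conv", "kernel_plus_two")) {
  stopifnot(inherits(base, "model_spec"))
  variant <- match.arg(variant)
  layers <- base$layers
  kinds <- vapply(layers, `[[`, "", "kind")
  if (variant == "three_conv") {
    conv_idx <- which(kinds == "conv1d")
    if (length(conv_idx) < 2L) stop("need at least two conv layers to ablate")
    last_conv <- tail(conv_idx, 1)
    drop <- last_conv
    if (last_conv < length(layers) &&
        layers[[last_conv + 1L]]$kind == "maxpool1d") {
      drop <- c(drop, last_conv + 1L)
    }
    layers <- layers[-drop]
  } else {
    for (i in which(kinds == "conv1d")) {
      layers[[i]]$kernel_size <- layers[[i]]$kernel_size + 2L
    }
  }
  model_spec(paste0(base$name, "_", variant), base$input_len,
             base$input_channels, layers, base$n_classes)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: input %d x %d, %d classes\n",
              x$name, x$input_len, x$input_channels, x$n_classes))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
      conv1d = sprintf("conv1d(filters=%d, kernel=%d, %s, %s)",
                       ly$filters, ly$kernel_size, ly$padding, ly$activation),
      maxpool1d = sprintf("maxpool1d(pool=%d, stride=%d)",
                          ly$pool_size, ly$stride),
      dropout = sprintf("dropout(rate=%g)", ly$rate),
      dense = sprintf("dense(units=%d, %s)", ly$units, ly$activation),
      ly$kind)
    cat(sprintf("  %2d. %s\n", i, desc))
  }
  cat(sprintf("  parameters: %s; FLOPs (2xMAC): %s\n",
              format(count_parameters(x), big.mark = ","),
              format(estimate_flops(x), big.mark = ",")))
  invisible(x)
}
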