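# 1D Grad-CAM: channel-averaged gradients of a class logit weight the
# activations of a convolutional layer; the ReLU of the weighted sum,
# upsampled to the input length and max-normalized, localizes the signal
# regions driving the classification.

#' Grad-CAM saliency map for one window
#'
#' Computes channel weights `w_k` as the temporal mean of the gradient of
#' the class logit with respect to the chosen conv layer's activations
#' `A_k`, forms `ReLU(sum_k w_k A_k)`, linearly interpolates the result to
#' the input length and normalizes by its maximum.  The map is invariant to
#' positive rescaling of the final-layer weights for the target class.
#'
#' @param model a fitted [fit_model()] object.
#' @param window a single input window (length `input_len`).
#' @param class_index target class (integer index into the model's class
#'   order, or a class name).
#' @param layer index of a conv1d layer; defaults to the last conv layer.
#' @return an object of class `saliency_map`: list with `values`
#'   (length `input_len`, in `[0, 1]`, max 1 unless identically zero),
#'   `target_class`, `source_layer` and `all_zero`.
#' @export
gradcam_map <- function(model, window, class_index = 1L, layer = NULL) {
  stopifnot(inherits(model, "ecg_cnn"))
  if (is.character(class_index)) {
    class_index <- match(class_index, model$class_order)
    if (is.na(class_index)) stop("unknown class name")
  }
  stopifnot(class_index >= 1, class_index <= model$spec$n_classes)
  kinds <- vapply(model$layers, `[[`, "", "kind")
  conv_idx <- which(kinds == "conv1d")
  if (is.null(layer)) layer <- tail(conv_idx, 1)
  if (!(layer %in% conv_idx)) {
    stop("layer ", layer, " is not a convolutional layer (conv layers: ",
         paste(conv_idx, collapse = ", "), ")")
  }
  X <- matrix(as.numeric(window), 1L)
  if (ncol(X) != model$spec$input_len) {
    stop("window length must equal the model input length ",
         model$spec$input_len)
  }
  fw <- .net_forward(model$layers, model$spec, X, training = FALSE,
                     keep_activations = TRUE)
  dLogits <- matrix(0, 1L, model$spec$n_classes)
  dLogits[1L, class_index] <- 1
  bw <- .net_backward(model$layers, fw, dLogits, upto = layer)
  A <- fw$activations[[layer]]   # (L, channels, 1)
  dA <- bw$dA
  w <- apply(dA[, , 1L, drop = FALSE], 2L, mean)
  cam <- drop(A[, , 1L] %*% w)
  cam <- pmax(cam, 0)
  L <- length(cam)
  target_len <- model$spec$input_len
  if (L != target_len) {
    cam <- stats::approx(seq(0, 1, length.out = L), cam,
                         seq(0, 1, length.out = target_len))$y
  }
  mx <- max(cam)
  all_zero <- mx <= 0
  if (!all_zero) cam <- cam / mx
  structure(list(values = cam,
                 target_class = model$class_order[class_index],
                 source_layer = layer, all_zero = all_zero),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> class %s, conv layer %d, %d samples%s\n",
              x$target_class, x$source_layer, length(x$values),
              if (x$all_zero) " (identically zero)" else ""))
  invisible(x)
}

#' @export
plot.saliency_map <- function(x, window = NULL, ...) {
  plot(x$values, type = "l", xlab = "sample", ylab = "saliency",
       ylim = c(0, 1), main = paste("Grad-CAM:", x$target_class), ...)
  if (!is.null(window)) {
    w <- (window - min(window)) / max(1e-12, diff(range(window)))
    lines(w, col = "grey60")
  }
  invisible(x)
}
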