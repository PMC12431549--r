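# The training engine: a small 1D-CNN stack (conv via im2col + BLAS
# matrix products, valid max-pooling, dense layers, inverted dropout,
# softmax/cross-entropy) with reverse-mode gradients and Adam, written
# against the declarative model_spec.  Activations travel as 3D arrays
# (length, channels, batch) until flatten, then as (batch, features)
# matrices.  Everything is seeded through R's RNG, so runs are exactly
# reproducible.

#' Training configuration
#'
#' Defaults follow the reference protocol: 50 epochs, batch size 32,
#' categorical cross-entropy, Adam at learning rate 0.001.
#'
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 0.001).
#' @param dropout_rate optional override of the spec's dropout rate.
#' @param seed RNG seed used for weight init, shuffling and dropout.
#' @param verbose print per-epoch loss/accuracy.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 0.001, dropout_rate = NULL,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  if (!is.null(dropout_rate)) {
    stopifnot(dropout_rate >= 0, dropout_rate < 1)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 dropout_rate = dropout_rate,
                 loss = "categorical_crossentropy",
                 optimizer = "adam",
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Evaluate a block of code with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- parameter initialization (Glorot uniform) ------------------------------

.realize_layers <- function(spec, dropout_override = NULL) {
  len <- spec$input_len
  ch <- spec$input_channels
  layers <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    rl <- ly
    switch(ly$kind,
      conv1d = {
        fan_in <- ly$kernel_size * ch
        fan_out <- ly$kernel_size * ly$filters
        lim <- sqrt(6 / (fan_in + fan_out))
        rl$W <- matrix(runif(fan_in * ly$filters, -lim, lim),
                       fan_in, ly$filters)
        rl$b <- numeric(ly$filters)
        rl$in_channels <- ch
        ch <- ly$filters
      },
      maxpool1d = {
        len <- (len - ly$pool_size) %/% ly$stride + 1L
      },
      flatten = {
        len <- len * ch
        ch <- 1L
      },
      dropout = {
        if (!is.null(dropout_override)) rl$rate <- dropout_override
      },
      dense = {
        lim <- sqrt(6 / (len + ly$units))
        rl$W <- matrix(runif(len * ly$units, -lim, lim), len, ly$units)
        rl$b <- numeric(ly$units)
        rl$in_units <- len
        len <- ly$units
      },
      softmax = NULL)
    layers[[i]] <- rl
  }
  layers
}

# ---- forward pass -----------------------------------------------------------

# conv1d forward on A (len, ch, n): returns list(out, cache)
.conv_forward <- function(ly, A) {
  d <- dim(A)
  len <- d[1]; C <- d[2]; N <- d[3]
  K <- ly$kernel_size
  if (ly$padding == "same") {
    pl <- (K - 1L) %/% 2L
    pr <- K - 1L - pl
    out_len <- len
  } else {
    pl <- 0L; pr <- 0L
    out_len <- len - K + 1L
  }
  Lp <- len + pl + pr
  Ap <- array(0, c(Lp, C, N))
  Ap[(pl + 1L):(pl + len), , ] <- A
  # im2col: rows index (position, batch), cols index (kernel offset, channel)
  base_r <- rep(seq_len(out_len), N) + Lp * C * rep(seq_len(N) - 1L,
                                                    each = out_len)
  off_col <- rep(seq_len(K) - 1L, each = C) + Lp * rep(seq_len(C) - 1L, K)
  # column order: (k-1)*C + c  -> off = (k-1) + Lp*(c-1)
  idx <- outer(base_r, off_col, `+`)
  # index as a flat vector: a matrix index whose width equals the array
  # dimensionality would be read as coordinate rows
  M <- Ap[as.vector(idx)]
  dim(M) <- c(out_len * N, K * C)
  Z <- M %*% ly$W
  Z <- Z + matrix(ly$b, nrow(Z), length(ly$b), byrow = TRUE)
  mask <- NULL
  if (ly$activation == "relu") {
    mask <- Z > 0
    Z[!mask] <- 0
  }
  dim(Z) <- c(out_len, N, ncol(ly$W))
  out <- aperm(Z, c(1, 3, 2))
  list(out = out,
       cache = list(M = M, mask = mask, out_len = out_len, len = len,
                    C = C, N = N, K = K, pl = pl, Lp = Lp))
}

.conv_backward <- function(ly, cache, dOut) {
  cc <- cache
  Ff <- dim(dOut)[2]
  dZ <- aperm(dOut, c(1, 3, 2))
  dim(dZ) <- c(cc$out_len * cc$N, Ff)
  if (!is.null(cc$mask)) dZ[!cc$mask] <- 0
  db <- colSums(dZ)
  dW <- crossprod(cc$M, dZ)
  dM <- tcrossprod(dZ, ly$W)
  dAp <- array(0, c(cc$Lp, cc$C, cc$N))
  for (k in seq_len(cc$K)) {
    block <- dM[, ((k - 1L) * cc$C + 1L):((k - 1L) * cc$C + cc$C),
                drop = FALSE]
    dim(block) <- c(cc$out_len, cc$N, cc$C)
    rows <- k:(k + cc$out_len - 1L)
    dAp[rows, , ] <- dAp[rows, , , drop = FALSE] + aperm(block, c(1, 3, 2))
  }
  dA <- dAp[(cc$pl + 1L):(cc$pl + cc$len), , , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

.pool_forward <- function(ly, A) {
  d <- dim(A)
  len <- d[1]; C <- d[2]; N <- d[3]
  P <- (len - ly$pool_size) %/% ly$stride + 1L
  rows1 <- seq(1L, by = ly$stride, length.out = P)
  out <- A[rows1, , , drop = FALSE]
  arg <- array(1L, c(P, C, N))
  if (ly$pool_size > 1L) {
    for (j in 2:ly$pool_size) {
      Sj <- A[rows1 + (j - 1L), , , drop = FALSE]
      upd <- Sj > out
      out[upd] <- Sj[upd]
      arg[upd] <- j
    }
  }
  list(out = out, cache = list(arg = arg, len = len, C = C, N = N, P = P))
}

.pool_backward <- function(ly, cache, dOut) {
  cc <- cache
  dA <- array(0, c(cc$len, cc$C, cc$N))
  rows1 <- seq(1L, by = ly$stride, length.out = cc$P)
  for (j in seq_len(ly$pool_size)) {
    sel <- cc$arg == j
    if (!any(sel)) next
    rows <- rows1 + (j - 1L)
    slice <- dA[rows, , , drop = FALSE]
    slice[sel] <- slice[sel] + dOut[sel]
    dA[rows, , ] <- slice
  }
  dA
}

# Full forward pass.  X: (n, input_len) matrix.  training toggles dropout.
# Returns prob (n x K), logits, and per-layer caches/activations.
.net_forward <- function(layers, spec, X, training = FALSE,
                         keep_activations = FALSE) {
  N <- nrow(X)
  A <- aperm(array(t(X), c(spec$input_len, spec$input_channels, N)),
             c(1, 2, 3))
  flat <- FALSE
  caches <- vector("list", length(layers))
  acts <- if (keep_activations) vector("list", length(layers)) else NULL
  logits <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    switch(ly$kind,
      conv1d = {
        r <- .conv_forward(ly, A)
        A <- r$out
        caches[[i]] <- r$cache
      },
      maxpool1d = {
        r <- .pool_forward(ly, A)
        A <- r$out
        caches[[i]] <- r$cache
      },
      flatten = {
        d <- dim(A)
        caches[[i]] <- d
        A <- matrix(A, d[1] * d[2], d[3])
        A <- t(A)
        flat <- TRUE
      },
      dropout = {
        if (training && ly$rate > 0) {
          keep <- 1 - ly$rate
          mask <- matrix((runif(length(A)) < keep) / keep,
                         nrow(A), ncol(A))
          A <- A * mask
          caches[[i]] <- mask
        }
      },
      dense = {
        Xin <- A
        Z <- Xin %*% ly$W
        Z <- Z + matrix(ly$b, nrow(Z), length(ly$b), byrow = TRUE)
        mask <- NULL
        if (ly$activation == "relu") {
          mask <- Z > 0
          Z[!mask] <- 0
        }
        caches[[i]] <- list(X = Xin, mask = mask)
        A <- Z
      },
      softmax = {
        logits <- A
        m <- apply(A, 1L, max)
        E <- exp(A - m)
        A <- E / rowSums(E)
      })
    if (keep_activations) acts[[i]] <- A
  }
  list(prob = A, logits = logits, caches = caches, activations = acts)
}

# Backward pass from a gradient at the logits (input of softmax).  Stops
# after processing layer `upto + 1`, returning gradients for every
# parameterized layer and, if `upto > 0`, the gradient flowing into layer
# `upto`'s output.
.net_backward <- function(layers, fw, dLogits, upto = 0L) {
  grads <- vector("list", length(layers))
  dA <- dLogits
  for (i in rev(seq_along(layers))) {
    if (i <= upto) break
    ly <- layers[[i]]
    switch(ly$kind,
      softmax = NULL, # handled by the caller via dLogits
      dense = {
        cc <- fw$caches[[i]]
        dZ <- dA
        if (!is.null(cc$mask)) dZ[!cc$mask] <- 0
        grads[[i]] <- list(dW = crossprod(cc$X, dZ), db = colSums(dZ))
        dA <- tcrossprod(dZ, ly$W)
      },
      dropout = {
        mask <- fw$caches[[i]]
        if (!is.null(mask)) dA <- dA * mask
      },
      flatten = {
        d <- fw$caches[[i]]
        dA <- t(dA)
        dim(dA) <- d
      },
      maxpool1d = {
        dA <- .pool_backward(ly, fw$caches[[i]], dA)
      },
      conv1d = {
        r <- .conv_backward(ly, fw$caches[[i]], dA)
        grads[[i]] <- list(dW = r$dW, db = r$db)
        dA <- r$dA
      })
  }
  list(grads = grads, dA = dA)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a 1D-CNN arrhythmia classifier
#'
#' Realizes a [model_spec()] in the package's own training engine and trains
#' it with categorical cross-entropy and Adam on the given window set.
#' Weight initialization (Glorot uniform), epoch shuffling and dropout all
#' draw from a single RNG stream seeded by `cfg$seed`, so two runs with the
#' same data and seed produce identical models.
#'
#' @param spec a [model_spec()]; `spec$n_classes` must equal the label width
#'   of `train_ws`.
#' @param train_ws a [window_set()] of training windows.
#' @param cfg a [train_config()].
#' @return an object of class `ecg_cnn` with components `spec`, `layers`
#'   (realized parameters), `class_order`, `config` and `history`
#'   (per-epoch mean loss and training accuracy).
#' @seealso [predict.ecg_cnn()], [gradcam_map()]
#' @export
fit_model <- function(spec, train_ws, cfg = train_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(train_ws, "window_set"),
            inherits(cfg, "train_config"))
  if (ncol(train_ws$labels_onehot) != spec$n_classes) {
    stop("label width ", ncol(train_ws$labels_onehot),
         " does not match spec n_classes ", spec$n_classes)
  }
  if (ncol(train_ws$windows) != spec$input_len) {
    stop("window length ", ncol(train_ws$windows),
         " does not match spec input_len ", spec$input_len)
  }
  n <- nrow(train_ws$windows)
  if (n == 0L) stop("empty training set")
  X <- train_ws$windows
  Y <- train_ws$labels_onehot
  .with_seed(cfg$seed, {
    layers <- .realize_layers(spec, cfg$dropout_rate)
    adam <- .adam_init(layers)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       accuracy = numeric())
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]
        Yb <- Y[bi, , drop = FALSE]
        fw <- .net_forward(layers, spec, Xb, training = TRUE)
        p <- fw$prob
        loss <- -mean(log(pmax(p[Yb == 1], 1e-12)))
        ep_loss <- ep_loss + loss * length(bi)
        ep_correct <- ep_correct +
          sum(max.col(p, ties.method = "first") ==
              max.col(Yb, ties.method = "first"))
        dLogits <- (p - Yb) / nrow(Xb)
        bw <- .net_backward(layers, fw, dLogits)
        step <- step + 1L
        upd <- .adam_update(layers, adam, bw$grads, cfg$learning_rate, step)
        layers <- upd$layers
        adam <- upd$state
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     accuracy = ep_correct / n))
      if (cfg$verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                        ep, ep_loss / n, ep_correct / n))
      }
    }
    structure(list(spec = spec, layers = layers,
                   class_order = train_ws$class_order, config = cfg,
                   history = hist, n_train = n),
              class = "ecg_cnn")
  })
}

.adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (!is.null(ly$W)) {
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    } else NULL
  })
}

.adam_update <- function(layers, state, grads, lr, step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    layers[[i]]$W <- layers[[i]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

#' Predict class probabilities for ECG windows
#'
#' @param object a fitted [fit_model()] object.
#' @param windows n x input_len matrix, a [window_set()], or a single
#'   window vector.
#' @param type `"prob"` for the n x K softmax matrix (rows sum to 1) or
#'   `"class"` for predicted class names.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @export
predict.ecg_cnn <- function(object, windows, type = c("prob", "class"),
                            batch_size = 64L, ...) {
  type <- match.arg(type)
  if (inherits(windows, "window_set")) windows <- windows$windows
  if (is.null(dim(windows))) windows <- matrix(windows, 1L)
  if (ncol(windows) != object$spec$input_len) {
    stop("window length ", ncol(windows), " does not match model input ",
         object$spec$input_len)
  }
  n <- nrow(windows)
  out <- matrix(0, n, object$spec$n_classes)
  for (b0 in seq(1L, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, n)
    fw <- .net_forward(object$layers, object$spec,
                       windows[bi, , drop = FALSE], training = FALSE)
    out[bi, ] <- fw$prob
  }
  colnames(out) <- object$class_order
  if (type == "class") {
    object$class_order[max.col(out, ties.method = "first")]
  } else {
    out
  }
}

# Total trainable parameters of a realized model (used to cross-check the
# analytic count).
.realized_parameter_count <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (is.null(ly$W)) 0L else length(ly$W) + length(ly$b)
  }, numeric(1)))
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat(sprintf("<ecg_cnn> %s: %s parameters, trained %d epoch(s) on %d windows\n",
              x$spec$name,
              format(.realized_parameter_count(x), big.mark = ","),
              nrow(x$history), x$n_train))
  h <- tail(x$history, 1)
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              h$loss, h$accuracy))
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ecg_cnn <- function(object, ...) {
  print(object$spec)
  print(object)
  invisible(object)
}

#' @export
coef.ecg_cnn <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$layers)) {
    ly <- object$layers[[i]]
    if (!is.null(ly$W)) {
      out[[sprintf("layer%02d_%s", i, ly$kind)]] <- list(W = ly$W, b = ly$b)
    }
  }
  out
}

#' Plot the training history of a fitted model
#'
#' @param x a fitted [fit_model()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecg_cnn <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  plot(h$epoch, h$accuracy, type = "l", xlab = "epoch", ylab = "accuracy",
       main = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
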