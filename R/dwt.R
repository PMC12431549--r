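# Periodized discrete wavelet transform with the Symlet-4 filter bank.
#
# sym4 is an orthogonal wavelet, so the periodized analysis operator (even
# circular shifts of the low- and high-pass filters) is orthonormal and the
# inverse transform is its transpose: reconstruction is exact to rounding.
# Odd-length inputs are extended by repeating the last sample before a level
# and cropped after inversion, so the multi-level transform round-trips at
# any length >= the filter support.

# Symlet-4 decomposition filters (orthonormal, length 8).
.SYM4_LO <- c(-0.075765714789273330, -0.029635527645998510,
               0.497618667632015450,  0.803738751805916100,
               0.297857795605277360, -0.099219543576847220,
              -0.012603967262037833,  0.032223100604042700)
.SYM4_HI <- c(-0.032223100604042700, -0.012603967262037833,
               0.099219543576847220,  0.297857795605277360,
              -0.803738751805916100,  0.497618667632015450,
               0.029635527645998510, -0.075765714789273330)

#' Maximum wavelet decomposition level for a signal length
#'
#' The deepest level at which the periodized transform still has more
#' coefficients than the filter has taps: `floor(log2(n / (support - 1)))`
#' where `support` is the wavelet filter length (8 for sym4).  A 1000-sample
#' window therefore decomposes to level 7.
#'
#' @param n signal length in samples.
#' @param support wavelet filter length (default 8, sym4).
#' @return integer decomposition level (>= 0).
#' @export
#' @examples
#' dwt_max_level(1000) # 7
dwt_max_level <- function(n, support = 8L) {
  if (n < support) return(0L)
  as.integer(floor(log2(n / (support - 1))))
}

# One analysis level (periodized). Returns list(approx, detail, odd = was the
# input length odd before extension).
.dwt_step <- function(x) {
  n0 <- length(x)
  odd <- n0 %% 2L == 1L
  if (odd) x <- c(x, x[n0])
  n <- length(x)
  L <- length(.SYM4_LO)
  half <- n %/% 2L
  # index matrix: row k, column m -> x[(2(k-1) + m - 1) mod n + 1]
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], half, L)
  list(approx = drop(xm %*% .SYM4_LO),
       detail = drop(xm %*% .SYM4_HI),
       odd = odd)
}

# One synthesis level (transpose of the analysis operator).
.idwt_step <- function(approx, detail, odd) {
  half <- length(approx)
  n <- 2L * half
  L <- length(.SYM4_LO)
  y <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    pos <- (base + m - 1L) %% n + 1L
    y[pos] <- y[pos] + approx * .SYM4_LO[m] + detail * .SYM4_HI[m]
  }
  if (odd) y <- y[-n]
  y
}

#' Multi-level periodized sym4 wavelet decomposition
#'
#' @param x numeric signal.
#' @param level decomposition depth; defaults to [dwt_max_level()] of
#'   `length(x)`.
#' @return a list with `approx` (coarsest approximation coefficients),
#'   `details` (list of detail coefficient vectors, coarsest first) and
#'   `odd_flags` used internally for exact reconstruction.
#' @seealso [wavedec_inverse()], [denoise_window()]
#' @export
wavedec <- function(x, level = dwt_max_level(length(x))) {
  stopifnot(is.numeric(x), level >= 0)
  if (length(x) < length(.SYM4_LO)) {
    stop("signal shorter than the sym4 filter support (8 samples)")
  }
  details <- vector("list", level)
  odd_flags <- logical(level)
  a <- as.numeric(x)
  if (level > 0) {
    for (j in seq_len(level)) {
      s <- .dwt_step(a)
      details[[level - j + 1L]] <- s$detail
      odd_flags[level - j + 1L] <- s$odd
      a <- s$approx
    }
  }
  structure(list(approx = a, details = details, odd_flags = odd_flags),
            class = "ecg_wavedec")
}

#' Invert a multi-level sym4 decomposition
#'
#' @param w an object from [wavedec()].
#' @return the reconstructed signal.
#' @export
wavedec_inverse <- function(w) {
  stopifnot(inherits(w, "ecg_wavedec"))
  a <- w$approx
  level <- length(w$details)
  if (level > 0) {
    for (j in seq_len(level)) {
      a <- .idwt_step(a, w$details[[j]], w$odd_flags[j])
    }
  }
  a
}
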