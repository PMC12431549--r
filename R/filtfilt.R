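# Zero-phase IIR filtering with proper edge handling.
#
# stats::filter / signal::filtfilt leave large edge transients for filters
# with long impulse responses (a 0.5 Hz high-pass at 128 Hz has a time
# constant of hundreds of samples).  We therefore apply the standard remedy:
# odd-reflection extension at both ends plus initial filter conditions
# matched to a step of the first sample's amplitude, forward and backward.

# Single-pass IIR filter y[n] = sum(b*x[n-k]) - sum(a[-1]*y[n-k]), a[1] = 1,
# with constant-history initial conditions: past inputs equal x0, past
# outputs equal x0 * dcgain.  Vectorized via stats::filter.
.iir_filter_step_init <- function(b, a, x) {
  if (abs(a[1] - 1) > 1e-12) {
    b <- b / a[1]
    a <- a / a[1]
  }
  nb <- length(b)
  na <- length(a)
  x0 <- x[1]
  g <- sum(b) / sum(a) # DC gain; ~0 for a high-pass
  # FIR part with constant pre-history
  v <- stats::filter(c(rep(x0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  # AR part with steady-state pre-history
  if (na > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive",
                       init = rep(g * x0, na - 1))
    y <- as.numeric(y)
  } else {
    y <- v
  }
  y
}

# Forward-backward ("zero-phase") application of an IIR filter with
# odd-reflection padding at both ends.
.filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) + 60L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- .iir_filter_step_init(b, a, ext)
  y <- rev(.iir_filter_step_init(b, a, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}
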