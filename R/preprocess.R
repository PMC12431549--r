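# Five-stage preprocessing: baseline removal -> (per-window) wavelet
# denoising -> z-score -> segmentation -> class coding.  Baseline removal is
# applied to the continuous signal; denoising and z-scoring are applied to
# each extracted 1000-sample window.

#' Preprocessing configuration
#'
#' Defaults follow the reference pipeline: a 0.5 Hz 4th-order Butterworth
#' high-pass for baseline wander, sym4 wavelet denoising with a per-level
#' hard threshold of 0.04 x the level's maximum absolute detail coefficient,
#' non-overlapping 1000-sample windows at 128 Hz (about 7.81 s each).
#'
#' @param highpass_cutoff_hz high-pass cutoff in Hz (default 0.5).
#' @param butterworth_order filter order (default 4).
#' @param wavelet_name wavelet; only `"sym4"` is supported.
#' @param threshold_factor per-level threshold as a fraction of the level's
#'   max absolute detail coefficient (default 0.04, >= 0).
#' @param window_len window length in samples (default 1000).
#' @param target_fs_hz target sampling rate in Hz (default 128).
#' @param zero_phase use forward-backward (zero-phase) filtering
#'   (default TRUE).
#' @param soft_threshold use soft (shrinkage) instead of hard thresholding
#'   (default FALSE).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_cutoff_hz = 0.5,
                              butterworth_order = 4L,
                              wavelet_name = "sym4",
                              threshold_factor = 0.04,
                              window_len = 1000L,
                              target_fs_hz = 128,
                              zero_phase = TRUE,
                              soft_threshold = FALSE) {
  if (!identical(wavelet_name, "sym4")) {
    stop("only the sym4 wavelet is supported")
  }
  stopifnot(highpass_cutoff_hz > 0, butterworth_order >= 1,
            threshold_factor >= 0, window_len > 0, target_fs_hz > 0)
  if (highpass_cutoff_hz >= target_fs_hz / 2) {
    stop("highpass cutoff must be below the Nyquist rate target_fs_hz/2")
  }
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 butterworth_order = as.integer(butterworth_order),
                 wavelet_name = wavelet_name,
                 threshold_factor = threshold_factor,
                 window_len = as.integer(window_len),
                 target_fs_hz = target_fs_hz,
                 zero_phase = isTRUE(zero_phase),
                 soft_threshold = isTRUE(soft_threshold)),
            class = "preprocess_config")
}

#' Resample a record to the target rate (polyphase)
#'
#' Identity when the record is already at the target rate.  Annotation
#' indices are rescaled by the rate ratio and rounded to the nearest sample.
#'
#' @param record an [ecg_record()].
#' @param target_fs_hz target rate in Hz.
#' @return an [ecg_record()] at `target_fs_hz`.
#' @export
resample_to_target <- function(record, target_fs_hz = 128) {
  stopifnot(inherits(record, "ecg_record"), target_fs_hz > 0)
  if (isTRUE(all.equal(record$fs, target_fs_hz))) return(record)
  # rational rate ratio p/q
  scale <- 1e6
  p0 <- round(target_fs_hz * scale); q0 <- round(record$fs * scale)
  g <- .gcd(p0, q0)
  p <- p0 / g; q <- q0 / g
  y <- .resample_poly(record$signal, p, q)
  n_out <- round(length(record$signal) * target_fs_hz / record$fs)
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else
    y <- c(y, rep(y[length(y)], n_out - length(y)))
  ann <- record$annotations
  if (nrow(ann)) {
    ann$index <- pmin(pmax(as.integer(round(
      ann$index * target_fs_hz / record$fs)), 0L), n_out - 1L)
  }
  ecg_record(record$patient_id, target_fs_hz, y, ann, record$lead_name)
}

.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Polyphase rational resampling by p/q: zero-stuff by p, apply a windowed-
# sinc anti-aliasing low-pass (cutoff at the tighter of the two Nyquist
# rates, gain p, Hamming window, 10 taps per phase), compensate the exact
# FIR group delay, and keep every q-th sample.
.resample_poly <- function(x, p, q) {
  n <- length(x)
  half <- 10L * max(p, q)
  M <- 2L * half              # filter order; length M + 1, delay = half
  k <- seq(0, M) - half
  fc <- 1 / (2 * max(p, q))   # cycles per sample at the upsampled rate
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- p * h * (0.54 + 0.46 * cos(pi * k / half))  # Hamming taper
  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- x
  y <- stats::convolve(up, rev(h), type = "open")  # FFT convolution
  # y index (i + half) corresponds to upsampled position i
  n_out <- ceiling(n * p / q)
  pos <- half + seq(1L, by = q, length.out = n_out)
  y[pos]
}

#' Remove baseline wander with a Butterworth high-pass
#'
#' A 4th-order Butterworth high-pass at 0.5 Hz (defaults), applied
#' forward-backward for zero phase so QRS morphology is preserved.  The
#' effective magnitude response of the two-pass filter is the squared
#' single-pass response.
#'
#' @param signal numeric signal.
#' @param fs sampling rate in Hz.
#' @param cfg a [preprocess_config()].
#' @return filtered signal, same length.
#' @export
remove_baseline <- function(signal, fs, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (fs <= 2 * cfg$highpass_cutoff_hz) {
    stop("sampling rate must exceed twice the high-pass cutoff")
  }
  if (length(signal) <= 3L * cfg$butterworth_order) {
    stop("signal too short for a ", cfg$butterworth_order,
         "th-order filter (", length(signal), " samples)")
  }
  bf <- signal::butter(cfg$butterworth_order,
                       cfg$highpass_cutoff_hz / (fs / 2), type = "high")
  if (cfg$zero_phase) {
    .filtfilt_zp(bf$b, bf$a, signal)
  } else {
    .iir_filter_step_init(bf$b, bf$a, signal)
  }
}

#' Wavelet-denoise one window
#'
#' The window is decomposed with the periodized sym4 transform to the
#' maximum level admitted by its length ([dwt_max_level()]).  Within each
#' detail level `d_j` the threshold is `tau_j = threshold_factor *
#' max(|d_j|)`; coefficients with `|c| < tau_j` are zeroed (hard
#' thresholding; soft shrinkage behind `cfg$soft_threshold`).  Approximation
#' coefficients are untouched.  With `threshold_factor = 0` the operation is
#' the identity up to rounding.
#'
#' @param window numeric window (length >= 8, the sym4 support).
#' @param cfg a [preprocess_config()].
#' @return denoised window, same length.
#' @export
denoise_window <- function(window, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (length(window) < 8L) {
    stop("window shorter than the sym4 filter support (8 samples)")
  }
  w <- wavedec(window)
  for (j in seq_along(w$details)) {
    d <- w$details[[j]]
    tau <- cfg$threshold_factor * max(abs(d))
    if (cfg$soft_threshold) {
      d <- sign(d) * pmax(abs(d) - tau, 0)
    } else {
      d[abs(d) < tau] <- 0
    }
    w$details[[j]] <- d
  }
  wavedec_inverse(w)
}

#' Z-score a window
#'
#' Standardizes to mean 0 and population standard deviation 1 (division by
#' n, not n-1).  A constant window (zero standard deviation) maps to all
#' zeros.
#'
#' @param window numeric vector.
#' @return standardized window.
#' @export
zscore <- function(window) {
  m <- mean(window)
  s <- sqrt(mean((window - m)^2))
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(window)))
  (window - m) / s
}

#' Cut a record into non-overlapping windows
#'
#' Consecutive windows of exactly `cfg$window_len` samples starting at
#' sample 0; a trailing remainder is dropped.  Any window whose span
#' contains a NOISE annotation is excluded.
#'
#' @param record an [ecg_record()] (assumed at the target rate).
#' @param cfg a [preprocess_config()].
#' @return list with `starts` (0-based start indices) and `windows`
#'   (matrix, one row per window).
#' @export
segment_record <- function(record, cfg = preprocess_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(cfg, "preprocess_config"))
  L <- cfg$window_len
  n <- length(record$signal)
  nw <- n %/% L
  if (nw == 0L) {
    return(list(starts = integer(0), windows = matrix(0, 0, L)))
  }
  starts <- (seq_len(nw) - 1L) * L
  noise_idx <- record$annotations$index[record$annotations$symbol == "NOISE"]
  keep <- vapply(starts, function(s) {
    !any(noise_idx >= s & noise_idx < s + L)
  }, logical(1))
  starts <- starts[keep]
  windows <- t(vapply(starts, function(s) {
    record$signal[(s + 1L):(s + L)]
  }, numeric(L)))
  if (length(starts) == 1L) windows <- matrix(windows, 1L, L)
  list(starts = starts, windows = windows)
}

#' Label one window from beat annotations
#'
#' Considers beat annotations (N, L, R, A, V and OTHER; NOISE markers are
#' handled upstream by [segment_record()]) whose index falls inside
#' `[start, start + window_len)`.  Returns `"REJECT"` if the span holds no
#' beat or any OTHER beat; otherwise the majority symbol, with ties broken
#' in favor of the non-N symbol and then by the fixed order L < R < A < V.
#'
#' @param start 0-based window start index.
#' @param window_len window length in samples.
#' @param annotations annotation data frame (`index`, `symbol`), sorted.
#' @return a class symbol or `"REJECT"`.
#' @export
label_window <- function(start, window_len, annotations) {
  inside <- annotations$index >= start &
    annotations$index < start + window_len
  sym <- annotations$symbol[inside]
  sym <- sym[sym != "NOISE"]
  if (!length(sym) || any(sym == "OTHER")) return("REJECT")
  counts <- table(factor(sym, levels = .BEAT_SYMBOLS))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  non_n <- setdiff(top, "N")
  if (length(non_n)) {
    # fixed tie-break order L < R < A < V
    order_v <- c("L", "R", "A", "V")
    return(order_v[order_v %in% non_n][1])
  }
  "N"
}

#' One-hot encode class labels
#'
#' Multiclass mode uses the fixed beat order (N, L, R, A, V) and length-5
#' vectors.  Binary mode uses (Normal, Arrhythmia) and length-2 vectors;
#' segment-class codes 0.0 map to Normal and 1.0/2.0/3.0 (AF, PAC, PVC) to
#' Arrhythmia, as do beat symbols N vs. L/R/A/V.
#'
#' @param labels character symbols, rhythm names (NSR/AF/PAC/PVC) or numeric
#'   segment codes 0-3.
#' @param mode `"multiclass"` or `"binary"`.
#' @return list with `onehot` (n x K matrix) and `class_order`.
#' @export
encode_labels <- function(labels, mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  if (mode == "multiclass") {
    order_v <- .BEAT_SYMBOLS
    lab <- as.character(labels)
    bad <- setdiff(unique(lab), order_v)
    if (length(bad)) {
      stop("unknown multiclass label(s): ", paste(bad, collapse = ", "))
    }
  } else {
    order_v <- c("Normal", "Arrhythmia")
    to_binary <- function(x) {
      if (is.numeric(x)) {
        if (!all(x %in% c(0, 1, 2, 3))) {
          stop("unknown segment class code(s): ",
               paste(setdiff(unique(x), 0:3), collapse = ", "))
        }
        return(ifelse(x == 0, "Normal", "Arrhythmia"))
      }
      x <- as.character(x)
      m <- c(NSR = "Normal", AF = "Arrhythmia", PAC = "Arrhythmia",
             PVC = "Arrhythmia", N = "Normal", L = "Arrhythmia",
             R = "Arrhythmia", A = "Arrhythmia", V = "Arrhythmia",
             Normal = "Normal", Arrhythmia = "Arrhythmia",
             `0` = "Normal", `1` = "Arrhythmia", `2` = "Arrhythmia",
             `3` = "Arrhythmia")
      out <- m[x]
      if (anyNA(out)) {
        stop("unknown binary label(s): ",
             paste(unique(x[is.na(out)]), collapse = ", "))
      }
      unname(out)
    }
    lab <- to_binary(labels)
  }
  onehot <- matrix(0, length(lab), length(order_v))
  onehot[cbind(seq_along(lab), match(lab, order_v))] <- 1
  list(onehot = onehot, class_order = order_v)
}

#' Run the full preprocessing pipeline
#'
#' For continuous records: resample to the target rate, remove baseline on
#' the continuous signal, cut non-overlapping 1000-sample windows (dropping
#' noise-marked spans), label each window from its beat annotations
#' (REJECTed windows dropped), wavelet-denoise and z-score each window, and
#' one-hot encode.  For a [segment_table()]: baseline removal per 30-s
#' segment, then the same windowing/denoise/z-score chain with the segment's
#' class code as the label.
#'
#' @param x a list of [ecg_record()]s or a [segment_table()].
#' @param cfg a [preprocess_config()].
#' @param mode `"multiclass"` (beat symbols N/L/R/A/V) or `"binary"`
#'   (Normal vs. Arrhythmia).
#' @return a [window_set()].
#' @export
run_preprocessing <- function(x, cfg = preprocess_config(),
                              mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  if (inherits(x, "ecg_record")) x <- list(x)
  wins <- list()
  labs <- list()
  pats <- list()
  if (inherits(x, "segment_table")) {
    for (i in seq_len(nrow(x$segments))) {
      seg <- remove_baseline(x$segments[i, ], cfg$target_fs_hz, cfg)
      rec <- ecg_record(x$patient_id[i], cfg$target_fs_hz, seg)
      sw <- segment_record(rec, cfg)
      if (!length(sw$starts)) next
      w <- t(apply(sw$windows, 1L, function(v) zscore(denoise_window(v, cfg))))
      wins[[length(wins) + 1L]] <- w
      labs[[length(labs) + 1L]] <- rep(x$class_code[i], nrow(w))
      pats[[length(pats) + 1L]] <- rep(x$patient_id[i], nrow(w))
    }
    labels <- unlist(labs)
  } else {
    stopifnot(all(vapply(x, inherits, logical(1), "ecg_record")))
    for (rec in x) {
      rec <- resample_to_target(rec, cfg$target_fs_hz)
      rec$signal <- remove_baseline(rec$signal, rec$fs, cfg)
      sw <- segment_record(rec, cfg)
      if (!length(sw$starts)) next
      lab <- vapply(sw$starts, label_window, character(1),
                    window_len = cfg$window_len,
                    annotations = rec$annotations)
      keep <- lab != "REJECT"
      if (!any(keep)) next
      w <- sw$windows[keep, , drop = FALSE]
      w <- t(apply(w, 1L, function(v) zscore(denoise_window(v, cfg))))
      wins[[length(wins) + 1L]] <- w
      labs[[length(labs) + 1L]] <- lab[keep]
      pats[[length(pats) + 1L]] <- rep(rec$patient_id, sum(keep))
    }
    labels <- unlist(labs)
  }
  if (!length(wins)) {
    enc <- encode_labels(character(0), mode)
    return(window_set(matrix(0, 0, cfg$window_len),
                      matrix(0, 0, length(enc$class_order)),
                      character(0), enc$class_order))
  }
  enc <- encode_labels(labels, mode)
  window_set(do.call(rbind, wins), enc$onehot, unlist(pats), enc$class_order)
}
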