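# Seeded synthetic single-lead ECG cohorts at 128 Hz.
#
# Beats are sums of five Gaussian bumps (P, Q, R, S, T) concatenated along
# a class-dependent RR sequence: normal sinus rhythm (low RR variability,
# P waves present), atrial fibrillation (high RR variability, no P waves),
# and NSR with premature atrial (early, narrow) or ventricular (early,
# wide, P-suppressed) ectopic beats.  Baseline wander and white noise are
# added on top.  Every beat carries a ground-truth annotation (N, A or V),
# so downstream labeling logic is testable exactly.

.SYNTH_CLASSES <- c("NSR", "AF", "PAC", "PVC")
.CLASS_CODE <- c(NSR = 0, AF = 1, PAC = 2, PVC = 3)

#' Synthetic cohort configuration
#'
#' Defaults emulate the statistical structure of 128 Hz single-lead
#' smartwatch/Holter recordings: resting heart rates around 70 bpm (faster
#' and highly irregular for AF), 15% ectopic beats for PAC/PVC records,
#' respiratory-band baseline wander and wideband noise.
#'
#' @param fs sampling rate in Hz (default 128).
#' @param duration_s record duration in seconds (default 64).
#' @param heart_rate_bpm named mean heart rate per class.
#' @param rr_cv named RR-interval coefficient of variation per class; AF
#'   must be more variable than NSR.
#' @param p_wave_present named logical per class.
#' @param qrs_width_scale QRS width multiplier for ventricular ectopics.
#' @param ectopic_rate fraction of ectopic beats in PAC/PVC records.
#' @param baseline_amp baseline-wander amplitude in mV.
#' @param baseline_freq baseline-wander frequency in Hz (< 0.5).
#' @param noise_sd white-noise standard deviation in mV.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(fs = 128,
                         duration_s = 64,
                         heart_rate_bpm = c(NSR = 70, AF = 95, PAC = 70,
                                            PVC = 70),
                         rr_cv = c(NSR = 0.03, AF = 0.25, PAC = 0.03,
                                   PVC = 0.03),
                         p_wave_present = c(NSR = TRUE, AF = FALSE,
                                            PAC = TRUE, PVC = TRUE),
                         qrs_width_scale = 2.5,
                         ectopic_rate = 0.15,
                         baseline_amp = 0.2,
                         baseline_freq = 0.3,
                         noise_sd = 0.03) {
  stopifnot(fs > 0, duration_s > 0, all(heart_rate_bpm > 0),
            all(rr_cv >= 0), qrs_width_scale > 0,
            ectopic_rate >= 0, ectopic_rate <= 1,
            baseline_amp >= 0, baseline_freq > 0, noise_sd >= 0)
  if (rr_cv[["AF"]] <= rr_cv[["NSR"]]) {
    stop("AF RR variability must exceed NSR RR variability")
  }
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
                 p_wave_present = p_wave_present,
                 qrs_width_scale = qrs_width_scale,
                 ectopic_rate = ectopic_rate,
                 baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq,
                 noise_sd = noise_sd),
            class = "synth_config")
}

#' Synthesize one PQRST beat
#'
#' One RR interval's worth of samples: five Gaussian bumps centered at
#' physiological offsets around the R wave.  The P bump is omitted when
#' `p_wave = FALSE`; `qrs_scale` widens the QRS complex (ventricular
#' morphology); `amplitude` scales the whole waveform linearly.
#'
#' @param rr_s RR interval in seconds.
#' @param fs sampling rate in Hz.
#' @param p_wave include the P wave.
#' @param qrs_scale QRS width multiplier.
#' @param amplitude overall amplitude factor (mV).
#' @return list with `samples` (numeric, `round(rr_s * fs)` values) and
#'   `r_index` (0-based sample offset of the R-wave center).
#' @export
synth_beat <- function(rr_s, fs = 128, p_wave = TRUE, qrs_scale = 1,
                       amplitude = 1) {
  stopifnot(rr_s > 0, fs > 0, qrs_scale > 0)
  n <- max(1L, as.integer(round(rr_s * fs)))
  t <- (seq_len(n) - 1L) / fs
  r_t <- max(0.2, 0.3 * rr_s)
  waves <- list(
    P = list(c = r_t - 0.16, w = 0.028, a = 0.12),
    Q = list(c = r_t - 0.035 * qrs_scale, w = 0.012 * qrs_scale, a = -0.10),
    R = list(c = r_t, w = 0.014 * qrs_scale, a = 1.10),
    S = list(c = r_t + 0.035 * qrs_scale, w = 0.012 * qrs_scale, a = -0.18),
    T = list(c = r_t + 0.28, w = 0.070, a = 0.35))
  if (!p_wave) waves$P <- NULL
  y <- numeric(n)
  for (w in waves) {
    y <- y + w$a * exp(-0.5 * ((t - w$c) / w$w)^2)
  }
  list(samples = amplitude * y,
       r_index = as.integer(round(r_t * fs)))
}

# Class-dependent RR sequence covering at least duration_s seconds.
# Returns list(rr = intervals in s, ectopic = logical per beat).
.synth_rr_sequence <- function(class_name, cfg) {
  rr_mean <- 60 / cfg$heart_rate_bpm[[class_name]]
  cv <- cfg$rr_cv[[class_name]]
  n_max <- ceiling(cfg$duration_s / rr_mean * 3) + 10L
  rr <- pmax(0.3, rnorm(n_max, rr_mean, cv * rr_mean))
  ect <- rep(FALSE, n_max)
  if (class_name %in% c("PAC", "PVC") && cfg$ectopic_rate > 0) {
    ect <- runif(n_max) < cfg$ectopic_rate
    ect[1] <- FALSE
    # premature beat: the interval ending at the ectopic is short, the one
    # after it carries a compensatory pause
    rr[ect] <- rr[ect] * 0.62
    after <- which(ect) + 1L
    after <- after[after <= n_max]
    rr[after] <- rr[after] * 1.35
  }
  keep <- cumsum(rr) <= cfg$duration_s
  n <- max(2L, sum(keep))
  list(rr = rr[seq_len(n)], ectopic = ect[seq_len(n)])
}

#' Synthesize one annotated ECG record
#'
#' Draws a class-dependent RR sequence, concatenates per-beat PQRST
#' waveforms, adds baseline wander (a slow two-tone sinusoid below 0.5 Hz)
#' and white noise, and annotates every beat at its R-wave sample (ectopics
#' labeled A or V, all other beats N).  Fully deterministic given
#' `(class_name, cfg, seed)`.
#'
#' @param class_name one of `"NSR"`, `"AF"`, `"PAC"`, `"PVC"`.
#' @param cfg a [synth_config()].
#' @param seed RNG seed.
#' @param patient_id record identifier.
#' @return an [ecg_record()] with attribute `class_name`.
#' @export
synth_record <- function(class_name, cfg = synth_config(), seed = 1L,
                         patient_id = "P01") {
  if (!class_name %in% .SYNTH_CLASSES) {
    stop("unknown class '", class_name, "'; valid: ",
         paste(.SYNTH_CLASSES, collapse = ", "))
  }
  .with_seed(seed, {
    seqs <- .synth_rr_sequence(class_name, cfg)
    n_total <- as.integer(round(cfg$duration_s * cfg$fs))
    signal <- numeric(n_total + as.integer(4 * cfg$fs))
    ann_idx <- integer(0)
    ann_sym <- character(0)
    pos <- 0L
    for (i in seq_along(seqs$rr)) {
      is_ect <- seqs$ectopic[i]
      p_wave <- cfg$p_wave_present[[class_name]] &&
        !(is_ect && class_name == "PVC")
      qrs <- if (is_ect && class_name == "PVC") cfg$qrs_width_scale else 1
      amp <- if (is_ect && class_name == "PVC") 1.3 else 1
      beat <- synth_beat(seqs$rr[i], cfg$fs, p_wave = p_wave,
                         qrs_scale = qrs, amplitude = amp)
      m <- length(beat$samples)
      if (pos + m > length(signal)) break
      signal[(pos + 1L):(pos + m)] <-
        signal[(pos + 1L):(pos + m)] + beat$samples
      r <- pos + beat$r_index
      if (r < n_total) {
        ann_idx <- c(ann_idx, r)
        ann_sym <- c(ann_sym,
                     if (!is_ect) "N"
                     else if (class_name == "PAC") "A" else "V")
      }
      pos <- pos + m
    }
    signal <- signal[seq_len(n_total)]
    t <- (seq_len(n_total) - 1L) / cfg$fs
    ph <- runif(2, 0, 2 * pi)
    wander <- cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq * t + ph[1]) +
      0.5 * cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq / 2.7 * t +
                                   ph[2])
    signal <- signal + wander + rnorm(n_total, 0, cfg$noise_sd)
    rec <- ecg_record(patient_id, cfg$fs, signal,
                      data.frame(index = ann_idx, symbol = ann_sym))
    attr(rec, "class_name") <- class_name
    rec
  })
}

#' Generate a synthetic patient cohort
#'
#' Allocates patients to classes by largest-remainder rounding of
#' `class_mix`, derives one sub-seed per patient from the master seed, and
#' synthesizes one annotated record per patient.
#'
#' @param n_patients number of patients (>= 1).
#' @param class_mix named fractions over NSR/AF/PAC/PVC summing to 1.
#' @param cfg a [synth_config()].
#' @param seed master RNG seed.
#' @return an object of class `synth_cohort`: list with `records` (list of
#'   [ecg_record()]) and `manifest` (data frame of patient, class, seed).
#' @export
synth_cohort <- function(n_patients, class_mix = c(NSR = 0.5, AF = 0.5),
                         cfg = synth_config(), seed = 1L) {
  stopifnot(n_patients >= 1)
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% .SYNTH_CLASSES)) {
    stop("class_mix must be named with classes among ",
         paste(.SYNTH_CLASSES, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  counts <- .largest_remainder(class_mix, n_patients)
  classes <- rep(names(counts), counts)
  manifest <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    class_name = classes,
    seed = seed + 104729L * seq_len(n_patients),
    stringsAsFactors = FALSE)
  records <- lapply(seq_len(n_patients), function(i) {
    synth_record(manifest$class_name[i], cfg, manifest$seed[i],
                 manifest$patient_id[i])
  })
  structure(list(records = records, manifest = manifest, config = cfg,
                 seed = seed),
            class = "synth_cohort")
}

# Largest-remainder apportionment of n among named fractions.
.largest_remainder <- function(mix, n) {
  q <- mix * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_order <- order(q - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d patient(s), %g s each @ %g Hz\n",
              nrow(x$manifest), x$config$duration_s, x$config$fs))
  print(table(class = x$manifest$class_name))
  invisible(x)
}

#' Export a cohort's 30-s segment table (Simband-style)
#'
#' Cuts each record into consecutive 30-s segments (a trailing remainder is
#' dropped) labeled with the record's class code (NSR 0.0, AF 1.0, PAC 2.0,
#' PVC 3.0).
#'
#' @param cohort a [synth_cohort()].
#' @param segment_s segment length in seconds (default 30).
#' @return a [segment_table()].
#' @export
cohort_segment_table <- function(cohort, segment_s = 30) {
  stopifnot(inherits(cohort, "synth_cohort"))
  L <- as.integer(round(segment_s * cohort$config$fs))
  pats <- character(0)
  codes <- numeric(0)
  segs <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    nseg <- length(rec$signal) %/% L
    if (nseg == 0L) next
    for (s in seq_len(nseg)) {
      segs[[length(segs) + 1L]] <- rec$signal[((s - 1L) * L + 1L):(s * L)]
    }
    pats <- c(pats, rep(rec$patient_id, nseg))
    codes <- c(codes, rep(.CLASS_CODE[[attr(rec, "class_name")]], nseg))
  }
  segment_table(pats, codes, do.call(rbind, segs))
}

#' Export a cohort as WFDB records
#'
#' Writes one WFDB record (`.hea`/`.dat`/`.atr`) per patient plus a
#' `manifest.csv` into `dir`, exercising the same on-disk layout the reader
#' consumes.
#'
#' @param cohort a [synth_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort_wfdb <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$records) {
    write_wfdb_record(rec, file.path(dir, rec$patient_id))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
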