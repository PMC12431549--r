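cfg <- preprocess_config()

test_that("resampling preserves content and rescales annotations", {
  rec <- synth_record("NSR", synth_config(duration_s = 10), seed = 5)
  expect_identical(resample_to_target(rec, 128), rec)  # already at target
  r360 <- ecg_record("R", 360, sin(2 * pi * 5 * (0:3599) / 360),
                     data.frame(index = 360L, symbol = "N"))
  out <- resample_to_target(r360, 128)
  expect_equal(length(out$signal), 1280L)  # 3600 * 128/360
  expect_equal(out$annotations$index, 128L)
  expect_equal(out$fs, 128)
  # a mid-band tone survives resampling (interior, away from edges)
  t_new <- (0:1279) / 128
  expect_lt(max(abs(out$signal[200:1000] -
                    sin(2 * pi * 5 * t_new)[200:1000])), 0.05)
})

test_that("baseline removal rejects DC and sub-band drift, keeps passband", {
  fs <- 128
  n <- fs * 60
  expect_lt(max(abs(remove_baseline(rep(5, n), fs, cfg))), 1e-6)
  t <- (0:(n - 1)) / fs
  drift <- remove_baseline(sin(2 * pi * 0.05 * t), fs, cfg)
  expect_lt(max(abs(drift[(20 * fs):(40 * fs)])), 1e-3)  # steady state
  tone <- remove_baseline(sin(2 * pi * 5 * t), fs, cfg)
  expect_lt(abs(max(abs(tone[(20 * fs):(40 * fs)])) - 1), 0.01)
  expect_error(remove_baseline(1:5, fs, cfg), "too short")
  expect_error(remove_baseline(rnorm(100), 0.8, cfg), "cutoff")
})

test_that("two-pass high-pass: >60 dB at cutoff/10, <1% ripple at 10x cutoff", {
  fs <- 128
  t <- (0:(fs * 120 - 1)) / fs
  mid <- (40 * fs):(80 * fs)
  low <- remove_baseline(sin(2 * pi * 0.05 * t), fs, cfg)
  expect_lt(20 * log10(max(abs(low[mid]))), -60)
  pass <- remove_baseline(sin(2 * pi * 5 * t), fs, cfg)
  expect_lt(abs(max(abs(pass[mid])) - 1), 0.01)
})

test_that("wavelet round-trip is the identity at zero threshold", {
  cfg0 <- preprocess_config(threshold_factor = 0)
  set.seed(11)
  for (n in c(512L, 600L, 777L, 1000L, 1024L)) {
    x <- rnorm(n)
    expect_lt(max(abs(denoise_window(x, cfg0) - x)), 1e-8)
  }
})

test_that("hard thresholding zeroes exactly the sub-threshold detail mass", {
  set.seed(12)
  x <- rnorm(1000)
  w <- wavedec(x)
  # replicate the rule coefficient-wise, then compare reconstructions
  for (j in seq_along(w$details)) {
    d <- w$details[[j]]
    tau <- 0.04 * max(abs(d))
    d[abs(d) < tau] <- 0
    expect_true(all(abs(d[d != 0]) >= tau))
    w$details[[j]] <- d
  }
  expect_equal(denoise_window(x, cfg), wavedec_inverse(w), tolerance = 1e-10)
})

test_that("denoising reduces RMSE to a clean beat template", {
  beat <- synth_beat(1, 128)$samples
  clean <- rep(beat, length.out = 1000)
  set.seed(21)
  noisy <- clean + rnorm(1000, 0, 0.05)
  den <- denoise_window(noisy, cfg)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
})

test_that("z-score matches hand computation and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  expect_equal(zscore(rep(4.2, 50)), rep(0, 50))
  set.seed(3)
  w <- rnorm(200)
  expect_equal(zscore(zscore(w)), zscore(w), tolerance = 1e-9)
})

test_that("segmentation emits exact non-overlapping windows, noise excluded", {
  mk <- function(n, noise_at = integer()) {
    sym <- rep("NOISE", length(noise_at))
    ecg_record("S", 128, rnorm(n),
               data.frame(index = as.integer(noise_at), symbol = sym))
  }
  s <- segment_record(mk(2500), cfg)
  expect_equal(s$starts, c(0L, 1000L))
  expect_equal(ncol(s$windows), 1000L)
  expect_equal(length(segment_record(mk(999), cfg)$starts), 0L)
  s2 <- segment_record(mk(3000, noise_at = 1500), cfg)
  expect_equal(s2$starts, c(0L, 2000L))
})

test_that("window labels follow majority with the fixed tie-break", {
  ann <- function(sym) data.frame(index = seq(100, by = 100,
                                              length.out = length(sym)),
                                  symbol = sym)
  expect_equal(label_window(0, 1000, ann(c("N", "N", "V"))), "N")
  expect_equal(label_window(0, 1000, ann(c("N", "V"))), "V")
  expect_equal(label_window(0, 1000, ann(c("R", "L"))), "L")  # L < R
  expect_equal(label_window(0, 1000, ann(c("A", "V", "N", "N"))), "N")
  expect_equal(label_window(0, 1000, ann(c("A", "V"))), "A")  # A < V
  expect_equal(label_window(0, 1000, ann(c("N", "OTHER"))), "REJECT")
  expect_equal(label_window(0, 1000, ann(character(0))), "REJECT")
  # annotations outside the span are ignored
  expect_equal(label_window(1000, 1000, ann(c("N", "N"))), "REJECT")
})

test_that("one-hot encoding fixes the class orders", {
  m <- encode_labels(c("N", "V"), "multiclass")
  expect_equal(m$class_order, c("N", "L", "R", "A", "V"))
  expect_equal(m$onehot[1, ], c(1, 0, 0, 0, 0))
  expect_equal(m$onehot[2, ], c(0, 0, 0, 0, 1))
  b <- encode_labels(c(2, 0, 1, 3), "binary")
  expect_equal(b$class_order, c("Normal", "Arrhythmia"))
  expect_equal(b$onehot[, 2], c(1, 0, 1, 1))
  expect_equal(b$onehot[2, ], c(1, 0))
  expect_error(encode_labels(c("N", "Q"), "multiclass"), "unknown")
  expect_error(encode_labels(c(0, 4), "binary"), "unknown")
})

test_that("the full pipeline emits standardized labeled 1000-sample windows", {
  co <- synth_cohort(2, c(NSR = 0.5, PVC = 0.5),
                     synth_config(duration_s = 24), seed = 8)
  ws <- run_preprocessing(co$records, cfg, mode = "multiclass")
  expect_s3_class(ws, "window_set")
  expect_equal(ncol(ws$windows), 1000L)
  expect_true(all(rowSums(ws$labels_onehot) == 1))
  expect_true(all(abs(rowMeans(ws$windows)) < 1e-6))
  sds <- apply(ws$windows, 1, function(w) sqrt(mean((w - mean(w))^2)))
  expect_true(all(abs(sds - 1) < 1e-6))
  expect_equal(sort(unique(ws$patient_ids)), c("P01", "P02"))
})

test_that("an all-noise record contributes zero windows", {
  rec <- ecg_record("NZ", 128, rnorm(3000),
                    data.frame(index = c(500L, 1500L, 2500L),
                               symbol = rep("NOISE", 3)))
  good <- synth_record("NSR", synth_config(duration_s = 16), seed = 2,
                       patient_id = "OK")
  ws <- run_preprocessing(list(rec, good), cfg, mode = "multiclass")
  expect_false("NZ" %in% ws$patient_ids)
  expect_true(all(ws$patient_ids == "OK"))
})

test_that("window count equals floor(length/window_len) minus exclusions", {
  rec <- synth_record("NSR", synth_config(duration_s = 40), seed = 6)
  s <- segment_record(rec, cfg)
  expect_equal(length(s$starts), (40 * 128) %/% 1000)
  # inject one NOISE marker into the second window's span
  rec$annotations <- rbind(rec$annotations,
                           data.frame(index = 1500L, symbol = "NOISE"))
  rec$annotations <- rec$annotations[order(rec$annotations$index), ]
  s2 <- segment_record(rec, cfg)
  expect_equal(length(s2$starts), length(s$starts) - 1L)
})
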