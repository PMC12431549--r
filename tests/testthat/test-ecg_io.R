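test_that("WFDB write/read round-trips a synthetic record", {
  rec <- synth_record("PAC", synth_config(duration_s = 20), seed = 3,
                      patient_id = "RT01")
  path <- file.path(withr::local_tempdir(), "RT01")
  write_wfdb_record(rec, path)
  back <- read_wfdb_record(path)
  expect_s3_class(back, "ecg_record")
  expect_equal(back$patient_id, "RT01")
  expect_equal(back$fs, rec$fs)
  expect_equal(length(back$signal), length(rec$signal))
  # format 16 at gain 200 quantizes to 1/200 mV; half-step worst case
  expect_lt(max(abs(back$signal - rec$signal)), 1 / 200)
  expect_equal(back$annotations$index, rec$annotations$index)
  expect_equal(back$annotations$symbol, rec$annotations$symbol)
})

test_that("annotation symbols outside the beat set map to OTHER and NOISE", {
  rec <- ecg_record("X", 128, rnorm(2000),
                    data.frame(index = c(100L, 500L, 900L),
                               symbol = c("N", "OTHER", "NOISE")))
  path <- file.path(withr::local_tempdir(), "X")
  write_wfdb_record(rec, path)
  back <- read_wfdb_record(path)
  expect_equal(back$annotations$symbol, c("N", "OTHER", "NOISE"))
  # unknown type code in the raw stream also maps to OTHER: write an
  # annotation file with code 10 ("/", paced) by hand
  con <- file(paste0(path, ".atr"), "wb")
  writeBin(as.raw(c(50L, bitwShiftL(10L, 2L))), con)  # code 10, time 50
  writeBin(as.raw(c(0L, 0L)), con)
  close(con)
  back2 <- read_wfdb_record(path)
  expect_equal(back2$annotations$symbol, "OTHER")
  expect_equal(back2$annotations$index, 50L)
})

test_that("long annotation gaps survive via SKIP words", {
  idx <- c(10L, 5000L, 200000L)  # gaps far beyond the 10-bit increment
  rec <- ecg_record("G", 128, numeric(230400),
                    data.frame(index = idx, symbol = c("N", "V", "A")))
  path <- file.path(withr::local_tempdir(), "G")
  write_wfdb_record(rec, path)
  back <- read_wfdb_record(path)
  expect_equal(back$annotations$index, idx)
  expect_equal(back$annotations$symbol, c("N", "V", "A"))
})

test_that("a 30-min record at 128 Hz holds 230,400 samples", {
  rec <- synth_record("NSR", synth_config(duration_s = 1800), seed = 1)
  expect_equal(length(rec$signal), 30 * 60 * 128)
  path <- file.path(withr::local_tempdir(), "long")
  write_wfdb_record(rec, path)
  expect_equal(length(read_wfdb_record(path)$signal), 230400)
})

test_that("the reader understands WFDB format 212", {
  # hand-built two-channel 212 record with known samples
  dir <- withr::local_tempdir()
  path <- file.path(dir, "f212")
  samp1 <- c(100L, -200L, 300L, -400L)
  samp2 <- c(-50L, 60L, -70L, 80L)
  inter <- as.vector(rbind(samp1, samp2))
  u <- ifelse(inter < 0L, inter + 4096L, inter)
  raw <- raw(0)
  for (i in seq(1, length(u), by = 2)) {
    s1 <- u[i]; s2 <- u[i + 1]
    raw <- c(raw, as.raw(c(s1 %% 256, (s1 %/% 256) + 16 * (s2 %/% 256),
                           s2 %% 256)))
  }
  writeBin(raw, file.path(dir, "f212.dat"))
  writeLines(c("f212 2 360 4",
               "f212.dat 212 200 12 0 100 0 0 MLII",
               "f212.dat 212 200 12 0 -50 0 0 V5"),
             file.path(dir, "f212.hea"))
  r1 <- read_wfdb_record(path, channel = 1)
  r2 <- read_wfdb_record(path, channel = 2)
  expect_equal(r1$signal, samp1 / 200)
  expect_equal(r2$signal, samp2 / 200)
  expect_equal(r1$fs, 360)
})

test_that("record validation rejects out-of-range and unknown annotations", {
  expect_error(ecg_record("B", 128, numeric(100),
                          data.frame(index = 100L, symbol = "N")),
               "outside")
  expect_error(ecg_record("B", 128, numeric(100),
                          data.frame(index = 5L, symbol = "Z")),
               "unknown annotation symbol")
  expect_error(ecg_record("B", -1, numeric(100)), "positive")
  expect_error(read_wfdb_record("does/not/exist"), "missing")
})

test_that("segment tables validate codes and round-trip through CSV", {
  st <- segment_table(c("P1", "P1", "P2"), c(0, 1, 0),
                      matrix(rnorm(3 * 100), 3))
  expect_s3_class(st, "segment_table")
  expect_error(segment_table("P1", 4, matrix(0, 1, 10)),
               "invalid class code")
  path <- file.path(withr::local_tempdir(), "seg.csv")
  write_segment_table(st, path)
  back <- read_segment_table(path)
  expect_equal(back$patient_id, st$patient_id)
  expect_equal(back$class_code, st$class_code)
  expect_equal(back$segments, st$segments, tolerance = 1e-12)
  # corrupt a code on disk -> validation error naming the row
  df <- read.csv(path, check.names = FALSE)
  df$class_code[2] <- 4
  write.csv(df, path, row.names = FALSE)
  expect_error(read_segment_table(path), "invalid class code.*row.*2")
})

test_that("window sets round-trip losslessly and reject empties", {
  ws <- toy_window_set(5)
  path <- file.path(withr::local_tempdir(), "ws.rds")
  write_window_set(ws, path)
  back <- read_window_set(path)
  expect_identical(back$labels_onehot, ws$labels_onehot)
  expect_equal(back$windows, ws$windows, tolerance = 1e-9)
  expect_identical(back$patient_ids, ws$patient_ids)
  expect_equal(nrow(back$windows), 10L)
  empty <- window_set(matrix(0, 0, 10), matrix(0, 0, 2),
                      character(0), c("a", "b"))
  expect_error(write_window_set(empty, path), "empty")
  expect_error(window_set(matrix(1, 2, 3), matrix(0.5, 2, 2),
                          c("a", "b"), c("x", "y")),
               "one-hot")
})

test_that("an exported synthetic cohort re-reads with annotations intact", {
  co <- synth_cohort(3, c(NSR = 0.4, PVC = 0.6),
                     synth_config(duration_s = 20), seed = 9)
  dir <- withr::local_tempdir()
  export_cohort_wfdb(co, dir)
  for (rec in co$records) {
    back <- read_wfdb_record(file.path(dir, rec$patient_id))
    expect_equal(nrow(back$annotations), nrow(rec$annotations))
    expect_equal(back$annotations$symbol, rec$annotations$symbol)
    expect_equal(sum(back$annotations$symbol == "OTHER"), 0L)
  }
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
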