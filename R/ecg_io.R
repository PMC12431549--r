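# ECG record and window-set I/O.
#
# Continuous records use the WFDB layout (text .hea header, binary .dat
# signal, MIT-format .atr beat annotations).  The reader understands signal
# formats 16 (16-bit little-endian) and 212 (packed 12-bit pairs, the MIT-BIH
# native format); the writer emits format 16.  Amplitudes are converted to
# physical units (mV) at read time using the header gain/baseline.

# Closed symbol enumeration for beat annotations.
.BEAT_SYMBOLS <- c("N", "L", "R", "A", "V")
.ANN_SYMBOLS <- c(.BEAT_SYMBOLS, "NOISE", "OTHER")

# MIT annotation type codes <-> symbols.
.ANN_CODE_TO_SYMBOL <- c(`1` = "N", `2` = "L", `3` = "R", `8` = "A",
                         `5` = "V", `14` = "NOISE")
.ANN_SYMBOL_TO_CODE <- c(N = 1L, L = 2L, R = 3L, A = 8L, V = 5L,
                         NOISE = 14L, OTHER = 13L)

#' Construct a single-lead ECG record
#'
#' @param patient_id record/patient identifier.
#' @param fs sampling rate in Hz (> 0).
#' @param signal numeric vector of amplitudes in mV.
#' @param annotations data frame with columns `index` (0-based sample
#'   positions, sorted) and `symbol` (one of N, L, R, A, V, NOISE, OTHER).
#' @param lead_name lead label (default "ECG").
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(patient_id, fs, signal,
                       annotations = data.frame(index = integer(),
                                                symbol = character()),
                       lead_name = "ECG") {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz")
  }
  signal <- as.numeric(signal)
  annotations <- as.data.frame(annotations)
  if (!all(c("index", "symbol") %in% names(annotations))) {
    stop("annotations need columns 'index' and 'symbol'")
  }
  annotations$index <- as.integer(annotations$index)
  annotations$symbol <- as.character(annotations$symbol)
  bad <- setdiff(unique(annotations$symbol), .ANN_SYMBOLS)
  if (length(bad)) {
    stop("unknown annotation symbol(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(annotations)) {
    if (any(annotations$index < 0L) ||
        any(annotations$index >= length(signal))) {
      stop("annotation index outside [0, length(signal)) for record ",
           patient_id)
    }
    annotations <- annotations[order(annotations$index), , drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(patient_id = patient_id, fs = fs, signal = signal,
                 annotations = annotations, lead_name = lead_name),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s), lead %s\n",
              x$patient_id, length(x$signal), x$fs,
              length(x$signal) / x$fs, x$lead_name))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$symbol)
    cat("  annotations:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  } else {
    cat("  annotations: none\n")
  }
  invisible(x)
}

#' Read a WFDB record (header + signal + annotations)
#'
#' Reads `<path>.hea`, `<path>.dat` and, if present, `<path>.atr`.  Signal
#' formats 16 and 212 are supported.  Samples are converted to mV using the
#' header gain and baseline.  Annotation type codes outside the beat
#' enumeration map to `"OTHER"`; the noise marker maps to `"NOISE"`.
#'
#' @param path record path without extension (e.g. `"data/100"`).
#' @param channel which signal channel to take (default 1).
#' @return an [ecg_record()].
#' @export
read_wfdb_record <- function(path, channel = 1L) {
  hea <- paste0(path, ".hea")
  dat <- paste0(path, ".dat")
  if (!file.exists(hea)) stop("missing WFDB header file: ", hea)
  if (!file.exists(dat)) stop("missing WFDB signal file: ", dat)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", rec[1])
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  if (is.na(fs) || fs <= 0) stop("invalid sampling rate in ", hea)
  if (nsig < channel) stop("record has ", nsig, " signal(s), channel ",
                           channel, " requested")
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2]))
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    units <- sub("^[^/]*/?", "", gain_spec)
    gain_base <- sub("/.*$", "", gain_spec)
    baseline <- NA_real_
    if (grepl("\\(", gain_base)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_base))
      gain_base <- sub("\\(.*$", "", gain_base)
    }
    gain <- as.numeric(gain_base)
    if (is.na(gain) || gain == 0) gain <- 200
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else "ECG"
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline,
         desc = desc, units = if (nzchar(units)) units else "mV")
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, 0L, "fmt"))
  if (length(fmts) != 1L) stop("mixed signal formats are not supported")
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- switch(as.character(fmts),
    "16" = {
      n16 <- length(raw) %/% 2L
      readBin(raw, "integer", n = n16, size = 2L, signed = TRUE,
              endian = "little")
    },
    "212" = .decode_fmt212(raw),
    stop("unsupported WFDB signal format: ", fmts))
  total <- (length(adc) %/% nsig) * nsig
  adc <- adc[seq_len(total)]
  mat <- matrix(adc, nrow = nsig)
  if (!is.na(nsamp) && nsamp > 0 && ncol(mat) < nsamp) {
    stop("signal file ", dat, " shorter than header sample count (",
         ncol(mat), " < ", nsamp, ")")
  }
  if (!is.na(nsamp) && nsamp > 0) mat <- mat[, seq_len(nsamp), drop = FALSE]
  si <- sigs[[channel]]
  signal <- (mat[channel, ] - si$baseline) / si$gain
  atr <- paste0(path, ".atr")
  ann <- if (file.exists(atr)) .read_mit_annotations(atr) else
    data.frame(index = integer(), symbol = character())
  if (nrow(ann) && any(ann$index >= length(signal))) {
    stop("annotation index beyond signal length in ", atr)
  }
  ecg_record(patient_id = record_name, fs = fs, signal = signal,
             annotations = ann, lead_name = si$desc)
}

# Unpack WFDB format 212: 3 bytes hold two 12-bit two's-complement samples.
.decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1, n3, 3)]
  b1 <- b[seq(2, n3, 3)]
  b2 <- b[seq(3, n3, 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s2 <- b2 + bitwShiftL(bitwAnd(bitwShiftR(b1, 4L), 0x0FL), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

# MIT annotation stream reader: 2-byte little-endian words, type code in the
# top 6 bits, time increment in the bottom 10; SKIP(59) carries a 4-byte
# interval (high word first); NUM/SUB/CHN/AUX modifiers are skipped.
.read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  idx <- integer(0)
  sym <- character(0)
  t <- 0
  i <- 1L
  while (i + 1L <= n) {
    lo <- as.integer(raw[i]); hi <- as.integer(raw[i + 1L])
    i <- i + 2L
    code <- bitwShiftR(hi, 2L)
    delta <- bitwAnd(hi, 3L) * 256L + lo
    if (code == 0L && delta == 0L) break            # EOF
    if (code == 59L) {                              # SKIP: 4-byte interval
      if (i + 3L > n) break
      hw <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
      lw <- as.integer(raw[i + 2L]) + 256L * as.integer(raw[i + 3L])
      i <- i + 4L
      t <- t + hw * 65536 + lw
    } else if (code %in% c(60L, 61L, 62L)) {        # NUM/SUB/CHN: no time
      next
    } else if (code == 63L) {                       # AUX: skip payload
      skip <- delta + (delta %% 2L)
      i <- i + skip
    } else {
      t <- t + delta
      s <- .ANN_CODE_TO_SYMBOL[as.character(code)]
      if (is.na(s)) s <- "OTHER"
      idx <- c(idx, as.integer(t))
      sym <- c(sym, unname(s))
    }
  }
  data.frame(index = idx, symbol = sym)
}

#' Write an ECG record in WFDB layout (format 16)
#'
#' Emits `<path>.hea`, `<path>.dat` (16-bit little-endian, gain 200 adu/mV)
#' and `<path>.atr` (MIT annotation format).  Round-trips through
#' [read_wfdb_record()] to within the 16-bit quantization step (1/400 mV
#' worst case); annotation indices and symbols round-trip exactly.
#'
#' @param record an [ecg_record()].
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  gain <- 200
  adc <- as.integer(round(record$signal * gain))
  adc <- pmax(pmin(adc, 32767L), -32768L)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- basename(path)
  hea <- c(sprintf("%s 1 %g %d", name, record$fs, length(adc)),
           sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
                   name, gain, if (length(adc)) adc[1] else 0L,
                   record$lead_name))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(adc, con, size = 2L, endian = "little")
  close(con)
  .write_mit_annotations(record$annotations, paste0(path, ".atr"))
  invisible(path)
}

.write_mit_annotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  t <- 0
  for (k in seq_len(nrow(ann))) {
    delta <- ann$index[k] - t
    t <- ann$index[k]
    code <- .ANN_SYMBOL_TO_CODE[[ann$symbol[k]]]
    if (delta > 1023) {
      # SKIP word, then the 4-byte interval (high word first), then the
      # annotation word with zero increment.
      writeBin(as.raw(c(0L, bitwShiftL(59L, 2L))), con)
      hw <- delta %/% 65536; lw <- delta %% 65536
      writeBin(as.raw(c(hw %% 256, hw %/% 256, lw %% 256, lw %/% 256)), con)
      delta <- 0L
    }
    lo <- delta %% 256L
    hi <- bitwShiftL(code, 2L) + delta %/% 256L
    writeBin(as.raw(c(lo, hi)), con)
  }
  writeBin(as.raw(c(0L, 0L)), con)
  invisible(path)
}

#' Read a labeled 30-s segment table (Simband-style CSV)
#'
#' Expects columns `patient_id`, `class_code`, `s0` ... `s<L-1>`.  Class
#' codes must be 0.0 (NSR), 1.0 (AF), 2.0 (PAC) or 3.0 (PVC); any other code
#' is a validation error naming the offending row.
#'
#' @param path CSV file path.
#' @return an object of class `segment_table`: list with `patient_id`
#'   (character), `class_code` (numeric) and `segments` (n x L matrix).
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("missing segment table: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("patient_id", "class_code") %in% names(df))) {
    stop("segment table needs 'patient_id' and 'class_code' columns")
  }
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (!length(scols)) stop("segment table has no sample columns s0...")
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  seg <- as.matrix(df[, scols, drop = FALSE])
  storage.mode(seg) <- "double"
  dimnames(seg) <- NULL
  segment_table(as.character(df$patient_id), as.numeric(df$class_code), seg)
}

#' @rdname read_segment_table
#' @param patient_id,class_code,segments table components (see return value).
#' @export
segment_table <- function(patient_id, class_code, segments) {
  segments <- as.matrix(segments)
  stopifnot(length(patient_id) == nrow(segments),
            length(class_code) == nrow(segments))
  bad <- which(!(class_code %in% c(0, 1, 2, 3)))
  if (length(bad)) {
    stop("invalid class code(s) ", paste(unique(class_code[bad]),
         collapse = ", "), " in row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  structure(list(patient_id = as.character(patient_id),
                 class_code = as.numeric(class_code),
                 segments = segments),
            class = "segment_table")
}

#' @rdname read_segment_table
#' @param x a `segment_table`.
#' @export
write_segment_table <- function(x, path) {
  stopifnot(inherits(x, "segment_table"))
  seg <- x$segments
  colnames(seg) <- paste0("s", seq_len(ncol(seg)) - 1L)
  df <- data.frame(patient_id = x$patient_id, class_code = x$class_code,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(seg, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d segments x %d samples, %d patient(s)\n",
              nrow(x$segments), ncol(x$segments),
              length(unique(x$patient_id))))
  print(table(class_code = x$class_code))
  invisible(x)
}

#' Construct a preprocessed window set
#'
#' The container carried from preprocessing into training: an n x L matrix
#' of z-scored windows, an n x K one-hot label matrix, per-window patient
#' IDs (used for patient-wise splitting) and the class order.
#'
#' @param windows n x window_len numeric matrix.
#' @param labels_onehot n x K one-hot matrix (each row one 1, rest 0).
#' @param patient_ids character vector of length n.
#' @param class_order character vector of K class names.
#' @return an object of class `window_set`.
#' @export
window_set <- function(windows, labels_onehot, patient_ids, class_order) {
  windows <- as.matrix(windows)
  labels_onehot <- as.matrix(labels_onehot)
  stopifnot(nrow(windows) == nrow(labels_onehot),
            nrow(windows) == length(patient_ids),
            ncol(labels_onehot) == length(class_order))
  ok <- apply(labels_onehot, 1L, function(r) {
    sum(r) == 1 && all(r %in% c(0, 1))
  })
  if (nrow(labels_onehot) && !all(ok)) {
    stop("labels_onehot rows must be one-hot (a single 1, rest 0)")
  }
  structure(list(windows = windows, labels_onehot = labels_onehot,
                 patient_ids = as.character(patient_ids),
                 class_order = as.character(class_order)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples, %d patient(s)\n",
              nrow(x$windows), ncol(x$windows),
              length(unique(x$patient_ids))))
  counts <- colSums(x$labels_onehot)
  cat("  classes:",
      paste(sprintf("%s=%d", x$class_order, counts), collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore a window set
#'
#' Lossless round-trip: windows, one-hot labels, patient IDs and class order
#' are restored bit-identically.
#'
#' @param ws a [window_set()]; must be non-empty.
#' @param path file path (`.rds`).
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  if (nrow(ws$windows) == 0L) stop("refusing to write an empty window set")
  saveRDS(ws, path)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  if (!file.exists(path)) stop("missing window set file: ", path)
  ws <- readRDS(path)
  if (!inherits(ws, "window_set")) stop(path, " does not hold a window_set")
  window_set(ws$windows, ws$labels_onehot, ws$patient_ids, ws$class_order)
}
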