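#' Read a local WFDB record (optional adapter)
#'
#' Minimal reader for WFDB records as distributed with the MIT-BIH
#' arrhythmia database: the plain-text `.hea` header, signal formats 212
#' (packed 12-bit pairs) and 16 (little-endian shorts), and the MIT
#' annotation format for beat (R-peak) annotations. The selected lead is
#' converted to millivolts via the header gain and baseline. Nothing is
#' ever downloaded: if the files are not present locally the call fails
#' with an "external data not available" error.
#'
#' @param record_name record path without extension (e.g. `"mitdb/100"`).
#' @param lead 0-based signal (lead) index to extract.
#' @param annotator annotation file extension holding the R labels
#'   (default `"atr"`); set `NULL` to skip annotations.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(record_name, lead = 0, annotator = "atr") {
  hea_path <- paste0(record_name, ".hea")
  if (!file.exists(hea_path)) {
    stop(sprintf("external data not available: %s not found", hea_path),
         call. = FALSE)
  }
  hdr <- parse_wfdb_header(hea_path)
  if (lead < 0 || lead >= hdr$n_sig) {
    stop(sprintf("lead %d out of range (record has %d signals)", lead, hdr$n_sig),
         call. = FALSE)
  }
  sig <- hdr$signals[[lead + 1L]]
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) {
    stop(sprintf("external data not available: %s not found", dat_path),
         call. = FALSE)
  }
  raw_all <- read_wfdb_signals(dat_path, hdr)
  adc <- raw_all[, lead + 1L]
  mv <- (adc - sig$baseline) / sig$gain

  r_peaks <- integer(0)
  if (!is.null(annotator)) {
    ann_path <- paste0(record_name, ".", annotator)
    if (!file.exists(ann_path)) {
      stop(sprintf("external data not available: %s not found", ann_path),
           call. = FALSE)
    }
    ann <- read_wfdb_annotations(ann_path)
    beat_codes <- c(1:13, 25, 34, 35, 38, 41)
    r_peaks <- ann$sample[ann$code %in% beat_codes]
    r_peaks <- r_peaks[r_peaks >= 0 & r_peaks < length(mv)]
  }
  ecg_record(mv, fs = hdr$fs, r_peaks = r_peaks,
             record_id = basename(record_name))
}

parse_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n_sig <- as.integer(top[2L])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3L])) else 250
  n_samples <- if (length(top) >= 4) as.integer(top[4L]) else NA_integer_
  signals <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", f[2L]))
    gain_field <- f[3L]
    gain <- as.numeric(sub("\\(.*$|/.*$", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200 # WFDB default ADC gain
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5) as.numeric(f[5L]) else 0
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline)
  })
  list(n_sig = n_sig, fs = fs, n_samples = n_samples, signals = signals)
}

read_wfdb_signals <- function(dat_path, hdr) {
  fmt <- hdr$signals[[1L]]$format
  n_sig <- hdr$n_sig
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 212) {
    n_triplets <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n_triplets)]), nrow = 3L)
    s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 0x0F), 8L)
    s2 <- b[3L, ] + bitwShiftL(bitwAnd(b[2L, ], 0xF0), 4L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    flat <- as.vector(rbind(s1, s2))
  } else if (fmt == 16) {
    flat <- readBin(dat_path, "integer", n = length(raw) %/% 2L,
                    size = 2L, signed = TRUE, endian = "little")
  } else {
    stop(sprintf("unsupported WFDB signal format %d (only 212 and 16)", fmt),
         call. = FALSE)
  }
  n_frames <- length(flat) %/% n_sig
  if (!is.na(hdr$n_samples)) n_frames <- min(n_frames, hdr$n_samples)
  matrix(flat[seq_len(n_frames * n_sig)], ncol = n_sig, byrow = TRUE)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n_words <- length(raw) %/% 2L
  sample <- integer(0)
  code <- integer(0)
  t <- 0L
  i <- 1L
  while (i <= n_words) {
    b1 <- as.integer(raw[2L * i - 1L])
    b2 <- as.integer(raw[2L * i])
    a_code <- bitwShiftR(b2, 2L)
    interval <- bitwShiftL(bitwAnd(b2, 0x03), 8L) + b1
    if (a_code == 0L && interval == 0L) break      # end of annotations
    if (a_code == 59L) {                            # SKIP: 4-byte interval
      hi <- as.integer(raw[2L * i + 1L]) + bitwShiftL(as.integer(raw[2L * i + 2L]), 8L)
      lo <- as.integer(raw[2L * i + 3L]) + bitwShiftL(as.integer(raw[2L * i + 4L]), 8L)
      t <- t + bitwShiftL(hi, 16L) + lo
      i <- i + 3L
      next
    }
    if (a_code == 63L) {                            # AUX: skip payload
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
      next
    }
    if (a_code %in% c(60L, 61L, 62L)) {             # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    t <- t + interval
    sample <- c(sample, t)
    code <- c(code, a_code)
    i <- i + 1L
  }
  list(sample = sample, code = code)
}
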