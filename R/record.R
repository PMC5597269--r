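#' Single-lead ECG record
#'
#' Container for a sampled single-lead ECG together with its sampling
#' frequency, the annotated R-peak positions that anchor delineation, and
#' (optionally) reference P/T peak annotations for evaluation. All indices
#' are 0-based sample positions into `samples`.
#'
#' @param samples numeric vector of amplitudes in mV.
#' @param fs sampling frequency in Hz (> 0).
#' @param r_peaks integer vector of R-peak sample indices. Sorted and
#'   deduplicated with a warning if not strictly increasing.
#' @param record_id character label for the record.
#' @param ref_p,ref_t optional reference P / T peak indices (sorted and
#'   deduplicated like `r_peaks`).
#'
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * seq(0, 2, by = 1 / 360)), fs = 360,
#'                   r_peaks = c(90, 450))
#' rec
#' @export
ecg_record <- function(samples, fs, r_peaks = integer(0), record_id = "record",
                       ref_p = NULL, ref_t = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` contains non-finite values", call. = FALSE)
  }
  fs <- check_scalar_number(fs, "fs", positive = TRUE)
  n <- length(samples)
  tidy_idx <- function(idx, name) {
    idx <- check_index_vector(idx, n, name)
    if (is.unsorted(idx, strictly = TRUE)) {
      idx <- sort(unique(idx))
      warning(sprintf("`%s` was not strictly increasing; sorted and deduplicated", name),
              call. = FALSE)
    }
    idx
  }
  structure(
    list(
      record_id = as.character(record_id)[1L],
      samples = as.numeric(samples),
      fs = fs,
      r_peaks = tidy_idx(r_peaks, "r_peaks"),
      ref_p = if (is.null(ref_p)) NULL else tidy_idx(ref_p, "ref_p"),
      ref_t = if (is.null(ref_t)) NULL else tidy_idx(ref_t, "ref_t")
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples at %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  cat(sprintf("  R peaks: %d", length(x$r_peaks)))
  if (!is.null(x$ref_p)) cat(sprintf(", reference P: %d", length(x$ref_p)))
  if (!is.null(x$ref_t)) cat(sprintf(", reference T: %d", length(x$ref_t)))
  cat("\n")
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from_s = 0, to_s = NULL, ...) {
  n <- length(x$samples)
  if (is.null(to_s)) to_s <- min(n / x$fs, from_s + 10)
  i0 <- max(0L, floor(from_s * x$fs))
  i1 <- min(n - 1L, ceiling(to_s * x$fs))
  idx <- i0:i1
  tt <- idx / x$fs
  graphics::plot(tt, x$samples[idx + 1L], type = "l", xlab = "time (s)",
                 ylab = "amplitude (mV)", main = x$record_id, ...)
  rp <- x$r_peaks[x$r_peaks >= i0 & x$r_peaks <= i1]
  if (length(rp)) {
    graphics::points(rp / x$fs, x$samples[rp + 1L], pch = 4, col = "red")
  }
  invisible(x)
}

#' Read an ECG record from plain-text files
#'
#' The signal file holds one amplitude per line (or the first column of a
#' CSV); the R-peak file holds one 0-based integer index per line. The
#' sampling frequency is not stored in either file and must be supplied.
#'
#' @param signal_path path to the signal file.
#' @param fs sampling frequency in Hz.
#' @param rpeak_path optional path to the R-peak index file.
#' @param record_id label; defaults to the signal file name.
#' @return An [ecg_record()].
#' @export
read_ecg_record <- function(signal_path, fs, rpeak_path = NULL,
                            record_id = NULL) {
  samples <- read_numeric_column(signal_path, "signal")
  r_peaks <- if (is.null(rpeak_path)) integer(0) else {
    read_index_column(rpeak_path, "R peak")
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(signal_path))
  }
  ecg_record(samples, fs = fs, r_peaks = r_peaks, record_id = record_id)
}

read_numeric_column <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # accept either a bare column or the first column of comma-separated rows
  first <- vapply(strsplit(lines, ","), `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(trimws(first)))
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric %s value at line %d of %s: '%s'",
                 what, bad[1L], path, lines[bad[1L]]), call. = FALSE)
  }
  vals
}

read_index_column <- function(path, what) {
  vals <- read_numeric_column(path, what)
  if (any(vals != floor(vals))) {
    stop(sprintf("%s file %s contains non-integer indices", what, path),
         call. = FALSE)
  }
  as.integer(vals)
}
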