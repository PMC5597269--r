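#' Write a detection result to a JSON file
#'
#' Serializes the event list (type `P`, `T` or `merged`, 0-based sample
#' index, time in seconds) together with the record id and sampling
#' frequency. The file round-trips losslessly through
#' [read_detections()].
#'
#' @param result a `pt_detection` object (see [detect_pt()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(result, path) {
  ev <- as.data.frame(result)
  payload <- list(
    record_id = result$record_id,
    fs = result$fs,
    events = ev
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a detection file written by [write_detections()]
#'
#' @param path path to the JSON detections file.
#' @return list with `record_id`, `fs`, and an `events` data.frame with
#'   columns `type`, `index`, `time_s`, plus derived `p_peaks` /
#'   `t_peaks` vectors (merged events appear in both).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop(sprintf("detections file not found: %s", path),
                               call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- payload$events
  if (length(ev) == 0L || is.null(ev$type)) {
    ev <- data.frame(type = character(0), index = integer(0), time_s = numeric(0))
  }
  ev$index <- as.integer(ev$index)
  list(
    record_id = payload$record_id,
    fs = payload$fs,
    events = ev,
    p_peaks = sort(ev$index[ev$type %in% c("P", "merged")]),
    t_peaks = sort(ev$index[ev$type %in% c("T", "merged")])
  )
}

#' Write a synthetic record as plain fixture files
#'
#' Emits the one-amplitude-per-line signal file, the one-index-per-line
#' R-peak file, and a JSON ground-truth file (`truth_p`, `truth_t`,
#' `beat_labels`, `fs`).
#'
#' @param record a `synth_ecg` object (see [synth_ecg()]).
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return named character vector of the three paths, invisibly.
#' @export
write_synth_record <- function(record, dir, stem = "synth") {
  stopifnot(inherits(record, "synth_ecg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    signal = file.path(dir, paste0(stem, "_signal.txt")),
    rpeaks = file.path(dir, paste0(stem, "_rpeaks.txt")),
    truth = file.path(dir, paste0(stem, "_truth.json"))
  )
  writeLines(format(record$samples, digits = 10, trim = TRUE, scientific = FALSE),
             paths[["signal"]])
  writeLines(as.character(record$r_peaks), paths[["rpeaks"]])
  jsonlite::write_json(
    list(fs = record$fs, truth_p = record$truth_p, truth_t = record$truth_t,
         beat_labels = record$beat_labels),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write an evaluation report as CSV
#'
#' @param report data.frame from [evaluation_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
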