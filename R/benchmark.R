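#' Published reference counts on ten MIT-BIH arrhythmia records
#'
#' Per-record TP/FP/FN counts and SE/+P percentages reported for the
#' two-moving-average P/T delineator over ten annotated 30-minute MIT-BIH
#' arrhythmia recordings (21,702 beats in total). Shipped so the
#' evaluation arithmetic -- per-record percentages from counts and the
#' record-averaged (macro) overall figures -- can be validated without
#' the external signal data.
#'
#' Note that a few published per-record percentage cells (records 102,
#' 104, 108 and 109) are not exactly `100 * TP / (TP + FN)` of the
#' printed counts of the same row; [compute_metrics()] always computes
#' from counts, so only the self-consistent rows are expected to
#' reproduce cell-for-cell. The overall row is the unweighted mean of the
#' ten per-record percentages and reproduces exactly under
#' `aggregate_metrics(..., mode = "macro")`.
#'
#' @return data.frame with one row per record: `record`, `beats`, and
#'   per-wave `tp`, `fp`, `fn`, `se`, `ppv` columns (`p_` / `t_` prefix).
#' @examples
#' b <- pt_benchmark()
#' mean(b$p_se) # 98.05
#' @export
pt_benchmark <- function() {
  path <- system.file("extdata", "mitbih_pt_benchmark.csv", package = "ptwave",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(record = "character"))
}
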