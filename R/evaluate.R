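#' Match detected peaks to reference annotations
#'
#' One-to-one matching within a sample tolerance: reference peaks are
#' visited in time order and each is paired with the earliest unmatched
#' detection lying within `tol_samples` of it. For equal-width tolerance
#' windows on sorted sequences this earliest-available rule attains the
#' maximum possible number of pairs (ties in distance go to the earlier
#' detection). Matched pairs are true positives, unmatched reference
#' peaks false negatives, unmatched detections false positives.
#'
#' @param detected,reference strictly increasing 0-based index vectors.
#' @param tol_samples non-negative matching tolerance in samples;
#'   `tol_samples = 0` demands exact index equality.
#' @return list of class `pt_counts` with fields `tp`, `fp`, `fn`. Always
#'   satisfies `tp + fn == length(reference)` and
#'   `tp + fp == length(detected)`.
#' @examples
#' match_peaks(c(100, 104), 102, tol_samples = 5) # tp 1, fp 1, fn 0
#' @export
match_peaks <- function(detected, reference, tol_samples) {
  stopifnot(tol_samples >= 0)
  if (is.unsorted(detected, strictly = TRUE) ||
      is.unsorted(reference, strictly = TRUE)) {
    stop("peak index sequences must be strictly increasing", call. = FALSE)
  }
  used <- logical(length(detected))
  tp <- 0L
  for (r in reference) {
    ok <- which(!used & abs(detected - r) <= tol_samples)
    if (length(ok)) {
      used[ok[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(
    list(tp = tp, fp = length(detected) - tp, fn = length(reference) - tp),
    class = "pt_counts"
  )
}

#' @export
print.pt_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Sensitivity and positive predictivity from match counts
#'
#' SE = 100 * TP / (TP + FN), the percentage of reference peaks that were
#' detected; +P = 100 * TP / (TP + FP), the percentage of detections that
#' were correct. A ratio with zero denominator is reported as `NA`
#' (absent), never as zero.
#'
#' @param counts a `pt_counts` object (or list with `tp`, `fp`, `fn`).
#' @param digits decimal places the percentages are rounded to.
#' @return list of class `pt_metrics` with `se_pct` and `ppv_pct`.
#' @examples
#' compute_metrics(match_peaks(c(10, 50), c(10, 50, 90), 2)) # SE 66.67, +P 100
#' @export
compute_metrics <- function(counts, digits = 2) {
  ratio <- function(num, den) if (den > 0) round(100 * num / den, digits) else NA_real_
  structure(
    list(
      se_pct = ratio(counts$tp, counts$tp + counts$fn),
      ppv_pct = ratio(counts$tp, counts$tp + counts$fp)
    ),
    class = "pt_metrics"
  )
}

#' @export
print.pt_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.2f%%", v)
  cat(sprintf("SE %s  +P %s\n", fmt(x$se_pct), fmt(x$ppv_pct)))
  invisible(x)
}

#' Aggregate per-record metrics
#'
#' `macro` averages the per-record percentages with equal weight per
#' record (records with an undefined percentage are dropped from that
#' mean); `pooled` sums the counts over records first and computes the
#' percentages once. The two differ when record sizes differ: a 1-beat
#' record at SE 100 and a 99-beat record at SE 0 give macro 50.00 but
#' pooled 1.00.
#'
#' @param per_record list of `pt_metrics`, one per record.
#' @param counts list of `pt_counts`, one per record.
#' @param mode `"macro"` (default) or `"pooled"`.
#' @param digits decimal places.
#' @return a `pt_metrics` object.
#' @export
aggregate_metrics <- function(per_record, counts, mode = c("macro", "pooled"),
                              digits = 2) {
  mode <- match.arg(mode)
  if (length(per_record) == 0L || length(per_record) != length(counts)) {
    stop("need matching non-empty per-record metric and count lists", call. = FALSE)
  }
  if (mode == "macro") {
    se <- vapply(per_record, `[[`, numeric(1), "se_pct")
    ppv <- vapply(per_record, `[[`, numeric(1), "ppv_pct")
    structure(
      list(se_pct = round(mean(se, na.rm = TRUE), digits),
           ppv_pct = round(mean(ppv, na.rm = TRUE), digits)),
      class = "pt_metrics"
    )
  } else {
    tot <- list(tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
                fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
                fn = sum(vapply(counts, `[[`, numeric(1), "fn")))
    compute_metrics(tot, digits = digits)
  }
}

#' Evaluate a delineation result against reference annotations
#'
#' Scores the P and T peak lists independently over all beats; a merged
#' P-T detection therefore counts once toward each list.
#'
#' @param detection a `pt_detection` object (see [detect_pt()]), or a list
#'   with `p_peaks`, `t_peaks` and `fs`.
#' @param ref_p,ref_t strictly increasing reference peak indices; default
#'   to the record's stored annotations (or a `synth_ecg` ground truth).
#' @param tol_ms matching tolerance in milliseconds (default 40 ms, well
#'   under half the narrowest normal P-wave width).
#' @param span_only drop reference peaks outside the R-anchored span
#'   `[first R, last R]` before scoring. The delineator only works on RR
#'   intervals between annotated R peaks, so waves outside that span are
#'   unreachable by construction; with `span_only = FALSE` (the benchmark
#'   convention) they count as misses.
#' @return list of class `pt_evaluation` with per-wave `counts` and
#'   `metrics`.
#' @export
evaluate_detection <- function(detection, ref_p = NULL, ref_t = NULL, tol_ms = 40,
                               span_only = FALSE) {
  rec <- detection$record
  if (is.null(ref_p)) ref_p <- rec$truth_p %||% rec$ref_p
  if (is.null(ref_t)) ref_t <- rec$truth_t %||% rec$ref_t
  if (is.null(ref_p) || is.null(ref_t)) {
    stop("reference P and T annotations are required for evaluation", call. = FALSE)
  }
  if (span_only && length(rec$r_peaks) >= 2L) {
    lo <- min(rec$r_peaks); hi <- max(rec$r_peaks)
    ref_p <- ref_p[ref_p >= lo & ref_p <= hi]
    ref_t <- ref_t[ref_t >= lo & ref_t <= hi]
  }
  tol <- ms_to_samples(tol_ms, detection$fs)
  cp <- match_peaks(detection$p_peaks, ref_p, tol)
  ct <- match_peaks(detection$t_peaks, ref_t, tol)
  structure(
    list(
      record_id = detection$record_id,
      tol_ms = tol_ms,
      p = list(counts = cp, metrics = compute_metrics(cp)),
      t = list(counts = ct, metrics = compute_metrics(ct))
    ),
    class = "pt_evaluation"
  )
}

#' @export
print.pt_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' (+/- %g ms matching)\n", x$record_id, x$tol_ms))
  for (w in c("p", "t")) {
    m <- x[[w]]$metrics; c <- x[[w]]$counts
    fmt <- function(v) if (is.na(v)) "--" else sprintf("%6.2f", v)
    cat(sprintf("  %s wave: TP %5d  FP %4d  FN %4d  SE %s  +P %s\n",
                toupper(w), c$tp, c$fp, c$fn, fmt(m$se_pct), fmt(m$ppv_pct)))
  }
  invisible(x)
}

#' Tabulate evaluations record by record
#'
#' Builds a report with one row per record and an overall row, with
#' per-wave TP/FP/FN counts and SE/+P percentages in benchmark-table
#' column order. Both aggregation modes are computed; `mode` selects
#' which fills the overall row.
#'
#' @param evaluations list of `pt_evaluation` objects.
#' @param beats optional integer vector of beat counts per record.
#' @param mode aggregation for the overall row, `"macro"` or `"pooled"`.
#' @return data.frame.
#' @export
evaluation_report <- function(evaluations, beats = NULL,
                              mode = c("macro", "pooled")) {
  mode <- match.arg(mode)
  row_of <- function(e, nb) {
    data.frame(
      record = e$record_id, beats = nb,
      p_tp = e$p$counts$tp, p_fp = e$p$counts$fp, p_fn = e$p$counts$fn,
      p_se = e$p$metrics$se_pct, p_ppv = e$p$metrics$ppv_pct,
      t_tp = e$t$counts$tp, t_fp = e$t$counts$fp, t_fn = e$t$counts$fn,
      t_se = e$t$metrics$se_pct, t_ppv = e$t$metrics$ppv_pct
    )
  }
  if (is.null(beats)) beats <- rep(NA_integer_, length(evaluations))
  rows <- do.call(rbind, Map(row_of, evaluations, beats))
  overall <- function(wave) {
    aggregate_metrics(lapply(evaluations, function(e) e[[wave]]$metrics),
                      lapply(evaluations, function(e) e[[wave]]$counts),
                      mode = mode)
  }
  op <- overall("p"); ot <- overall("t")
  total <- data.frame(
    record = "overall", beats = if (all(is.na(beats))) NA else sum(beats),
    p_tp = sum(rows$p_tp), p_fp = sum(rows$p_fp), p_fn = sum(rows$p_fn),
    p_se = op$se_pct, p_ppv = op$ppv_pct,
    t_tp = sum(rows$t_tp), t_fp = sum(rows$t_fp), t_fn = sum(rows$t_fn),
    t_se = ot$se_pct, t_ppv = ot$ppv_pct
  )
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}
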