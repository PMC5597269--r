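#' RR-scaled search gates for one RR interval
#'
#' The T wave is sought in a window measured forward from the current R
#' peak, the P wave in a window measured back from the next R peak. At the
#' 60 bpm reference rhythm (RR = 1 s) the defaults place the P gate
#' 110-560 ms before the next R (minimum PR interval up to PQ + QTc) and
#' the T gate 166-500 ms after the current R. With `rr_scale` on, all four
#' offsets are multiplied by the measured RR interval in seconds before
#' rounding: the faster the heart rate the shorter the PR and RT
#' intervals, so the gates tighten proportionally.
#'
#' @param r_i,r_next 0-based indices of the current and next R peak.
#' @param fs sampling frequency in Hz.
#' @param params a [detector_params()] object.
#' @return list with integer vectors `t_window` and `p_window`, each
#'   `c(lo, hi)` inclusive, clipped to the open interval `(r_i, r_next)`;
#'   a gate that is empty after clipping is returned as `NULL`.
#' @examples
#' gates_for_interval(0, 360, 360, detector_params())
#' @export
gates_for_interval <- function(r_i, r_next, fs, params = detector_params()) {
  if (r_next <= r_i) stop("R peaks must be strictly increasing", call. = FALSE)
  fs <- check_scalar_number(fs, "fs", positive = TRUE)
  rr_s <- (r_next - r_i) / fs
  scale <- if (params$rr_scale) rr_s else 1
  off <- function(ms) round_half_up(ms * scale * fs / 1000)
  clip <- function(lo, hi) {
    lo <- max(lo, r_i + 1L)
    hi <- min(hi, r_next - 1L)
    if (lo > hi) NULL else c(as.integer(lo), as.integer(hi))
  }
  list(
    t_window = clip(r_i + off(params$rt_min_ms), r_i + off(params$rt_max_ms)),
    p_window = clip(r_next - off(params$p_max_ms), r_next - off(params$p_min_ms))
  )
}

in_window <- function(idx, win) {
  !is.null(win) && idx >= win[1L] && idx <= win[2L]
}

#' Delineate a single RR interval
#'
#' Implements the three-scenario thresholding over the candidate blocks
#' whose peak lies strictly inside `(r_i, r_next)`:
#'
#' * no blocks: nothing is reported;
#' * one block: most likely the P and T waves are merged -- its peak is
#'   reported as both P and T with `merged = TRUE`, provided the peak
#'   falls inside the union of the two gates;
#' * several blocks: the T peak is the highest-amplitude T-candidate
#'   peak inside the T gate, and the P peak the highest-amplitude
#'   P-candidate peak inside the P gate. If one block wins both gates
#'   while other blocks exist, it is assigned to the gate whose centre is
#'   nearer its peak and the other gate is re-decided without it.
#'
#' @param blocks classified block data.frame (see [classify_blocks()] and
#'   [locate_block_peaks()]); rejected blocks are ignored.
#' @param r_i,r_next bounding R-peak indices.
#' @param reference amplitude vector used to (re)locate block peaks when
#'   the `peak_index` column is absent.
#' @param fs sampling frequency in Hz.
#' @param params a [detector_params()] object.
#' @return list with `p`, `t` (0-based indices or `NA`), `merged` flag,
#'   `scenario` (one of `"none"`, `"one"`, `"many"`), and `n_blocks`.
#' @export
delineate_interval <- function(blocks, r_i, r_next, reference, fs,
                               params = detector_params()) {
  if (is.null(blocks$peak_index)) {
    blocks <- locate_block_peaks(blocks, reference, use_abs = params$use_abs_peak)
  }
  if (is.null(blocks$rejected)) {
    blocks <- classify_blocks(blocks, ms_to_window(params$w1_ms, fs),
                              params$p_factor, params$t_factor)
  }
  # a candidate must contain an actual wave crest: a block whose extremum is
  # a trough (or lies in a blanked all-zero stretch) is filter ringing, not
  # a P or T wave
  has_crest <- if (params$use_abs_peak) abs(blocks$peak_amp) > 0 else blocks$peak_amp > 0
  blocks <- blocks[!blocks$rejected & has_crest &
                     blocks$peak_index > r_i & blocks$peak_index < r_next, ,
                   drop = FALSE]
  gates <- gates_for_interval(r_i, r_next, fs, params)
  res <- list(p = NA_integer_, t = NA_integer_, merged = FALSE,
              scenario = "none", n_blocks = nrow(blocks))
  if (nrow(blocks) == 0L) {
    return(res)
  }
  if (nrow(blocks) == 1L) {
    res$scenario <- "one"
    pk <- blocks$peak_index[1L]
    if (in_window(pk, gates$t_window) || in_window(pk, gates$p_window)) {
      res$p <- res$t <- as.integer(pk)
      res$merged <- TRUE
    }
    return(res)
  }
  res$scenario <- "many"
  best_in_gate <- function(cand, win, exclude = integer(0)) {
    if (is.null(win)) return(NA_integer_)
    rows <- which(cand &
                    blocks$peak_index >= win[1L] & blocks$peak_index <= win[2L] &
                    !seq_len(nrow(blocks)) %in% exclude)
    if (!length(rows)) return(NA_integer_)
    rows[which.max(blocks$peak_amp[rows])]
  }
  t_row <- best_in_gate(blocks$t_candidate, gates$t_window)
  p_row <- best_in_gate(blocks$p_candidate, gates$p_window)
  if (!is.na(t_row) && !is.na(p_row) && t_row == p_row) {
    # one block claims both gates while others exist: keep it for the gate
    # whose centre is nearer its peak, re-decide the other gate without it
    pk <- blocks$peak_index[t_row]
    d_t <- abs(pk - mean(gates$t_window))
    d_p <- abs(pk - mean(gates$p_window))
    if (d_t <= d_p) {
      p_row <- best_in_gate(blocks$p_candidate, gates$p_window, exclude = t_row)
    } else {
      t_row <- best_in_gate(blocks$t_candidate, gates$t_window, exclude = p_row)
    }
  }
  if (!is.na(t_row)) res$t <- as.integer(blocks$peak_index[t_row])
  if (!is.na(p_row)) res$p <- as.integer(blocks$peak_index[p_row])
  res
}

#' Detect P and T wave peaks in an annotated ECG record
#'
#' Runs the full two-moving-average delineation pipeline: zero-phase
#' band-pass filtering, QRS blanking around the annotated R peaks, fast
#' (W1) and slow (W2) centered moving averages, block-of-interest
#' generation where the fast average exceeds the slow one, width-prior
#' block rejection, and per-RR-interval gating with merged P-T handling.
#' Only the intervals between consecutive annotated R peaks are
#' delineated; the result is deterministic for fixed input and parameters
#' and invariant under positive rescaling of the signal.
#'
#' @param record an [ecg_record()] with at least two R peaks.
#' @param params a [detector_params()] object.
#' @return An object of class `pt_detection`: a list with `record_id`,
#'   `fs`, integer vectors `p_peaks` and `t_peaks` (0-based, strictly
#'   increasing, at most one of each per RR interval), a `merged`
#'   data.frame (`interval`, `index`) of single-block merged P-T events
#'   (their index appears in both peak lists), an `intervals` provenance
#'   data.frame (gates in samples, number of candidate blocks, scenario),
#'   and the `params` used.
#' @examples
#' rec <- synth_ecg(synth_spec(duration_s = 12, noise = noise_spec(0, 0, 0)))
#' det <- detect_pt(rec)
#' det
#' @export
detect_pt <- function(record, params = detector_params()) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$r_peaks) < 2L) {
    stop("delineation needs at least 2 R peaks (no RR interval exists)", call. = FALSE)
  }
  fs <- record$fs
  filtered <- bandpass(record$samples, fs, params$low_hz, params$high_hz, params$order)
  blanked <- remove_qrs(filtered, record$r_peaks, fs, params$pre_s, params$post_s)
  w1 <- ms_to_window(params$w1_ms, fs)
  w2 <- ms_to_window(params$w2_ms, fs)
  ma_peak <- moving_average(blanked, w1)
  ma_pwave <- moving_average(blanked, w2)
  blocks <- generate_blocks(ma_peak, ma_pwave)
  blocks <- locate_block_peaks(blocks, blanked, use_abs = params$use_abs_peak)
  blocks <- classify_blocks(blocks, w1, params$p_factor, params$t_factor)

  rp <- record$r_peaks
  n_int <- length(rp) - 1L
  p_peaks <- integer(0)
  t_peaks <- integer(0)
  merged <- data.frame(interval = integer(0), index = integer(0))
  log <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    r_i <- rp[k]; r_next <- rp[k + 1L]
    gates <- gates_for_interval(r_i, r_next, fs, params)
    res <- delineate_interval(blocks, r_i, r_next, blanked, fs, params)
    if (!is.na(res$p)) p_peaks <- c(p_peaks, res$p)
    if (!is.na(res$t)) t_peaks <- c(t_peaks, res$t)
    if (res$merged) {
      merged <- rbind(merged, data.frame(interval = k, index = res$p))
    }
    log[[k]] <- data.frame(
      interval = k, r_i = r_i, r_next = r_next,
      t_lo = if (is.null(gates$t_window)) NA_integer_ else gates$t_window[1L],
      t_hi = if (is.null(gates$t_window)) NA_integer_ else gates$t_window[2L],
      p_lo = if (is.null(gates$p_window)) NA_integer_ else gates$p_window[1L],
      p_hi = if (is.null(gates$p_window)) NA_integer_ else gates$p_window[2L],
      n_blocks = res$n_blocks, scenario = res$scenario, merged = res$merged
    )
  }
  structure(
    list(
      record_id = record$record_id,
      fs = fs,
      p_peaks = sort(p_peaks),
      t_peaks = sort(t_peaks),
      merged = merged,
      intervals = do.call(rbind, log),
      params = params,
      record = record
    ),
    class = "pt_detection"
  )
}

#' @export
print.pt_detection <- function(x, ...) {
  cat(sprintf("P/T delineation of '%s' (%d RR intervals)\n",
              x$record_id, nrow(x$intervals)))
  cat(sprintf("  P peaks: %d   T peaks: %d   merged P-T events: %d\n",
              length(x$p_peaks), length(x$t_peaks), nrow(x$merged)))
  invisible(x)
}

#' @export
summary.pt_detection <- function(object, ...) {
  sc <- table(factor(object$intervals$scenario, levels = c("none", "one", "many")))
  out <- list(
    record_id = object$record_id,
    n_intervals = nrow(object$intervals),
    n_p = length(object$p_peaks),
    n_t = length(object$t_peaks),
    n_merged = nrow(object$merged),
    scenarios = sc
  )
  class(out) <- "summary.pt_detection"
  out
}

#' @export
print.summary.pt_detection <- function(x, ...) {
  cat(sprintf("Record '%s': %d RR intervals\n", x$record_id, x$n_intervals))
  cat(sprintf("  scenarios: %d empty, %d single-block, %d multi-block\n",
              x$scenarios[["none"]], x$scenarios[["one"]], x$scenarios[["many"]]))
  cat(sprintf("  detections: %d P, %d T (%d merged P-T)\n",
              x$n_p, x$n_t, x$n_merged))
  invisible(x)
}

#' @export
as.data.frame.pt_detection <- function(x, ...) {
  merged_idx <- x$merged$index
  ev <- rbind(
    if (length(x$p_peaks)) data.frame(
      type = ifelse(x$p_peaks %in% merged_idx, "merged", "P"),
      index = x$p_peaks
    ),
    if (length(x$t_peaks)) data.frame(
      type = ifelse(x$t_peaks %in% merged_idx, "merged", "T"),
      index = x$t_peaks
    )
  )
  if (is.null(ev)) {
    return(data.frame(type = character(0), index = integer(0), time_s = numeric(0)))
  }
  # a merged event sits in both lists; keep a single row for it
  ev <- unique(ev)
  ev <- ev[order(ev$index, ev$type), , drop = FALSE]
  ev$time_s <- round(ev$index / x$fs, 6)
  rownames(ev) <- NULL
  ev
}

#' @export
plot.pt_detection <- function(x, from_s = 0, to_s = NULL, ...) {
  rec <- x$record
  plot(rec, from_s = from_s, to_s = to_s, ...)
  sel <- function(idx) idx[idx / x$fs >= from_s &
                             (is.null(to_s) | idx / x$fs <= (to_s %||% Inf))]
  pp <- sel(x$p_peaks); tp <- sel(x$t_peaks)
  if (length(pp)) graphics::points(pp / x$fs, rec$samples[pp + 1L], pch = 3, col = "blue")
  if (length(tp)) graphics::points(tp / x$fs, rec$samples[tp + 1L], pch = 1, col = "darkgreen")
  mi <- sel(x$merged$index)
  if (length(mi)) graphics::points(mi / x$fs, rec$samples[mi + 1L], pch = 8, col = "purple")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
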