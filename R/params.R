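#' Detector tuning parameters
#'
#' Collects every tunable of the delineation pipeline with its default.
#' Defaults encode the duration priors for a healthy adult at 60 bpm:
#' P width 110 +/- 20 ms, PQ/PR 160 +/- 40 ms, QRS 100 +/- 20 ms and
#' QTc 400 +/- 40 ms. The moving-average windows are set from the P wave
#' (W1 = 55 ms, half the P width, so shortened arrhythmic waves are still
#' demarcated; W2 = 110 ms, the full P width, acts as the dynamic
#' threshold). The upper P-gate bound 560 ms is the PQ + QTc total.
#'
#' @param low_hz,high_hz band-pass edges in Hz (default 0.5-10, the band
#'   that carries P/T energy while rejecting baseline wander and powerline
#'   interference).
#' @param order Butterworth order of the band-pass prototype (default 2).
#' @param pre_s,post_s QRS blanking span in seconds before / after each
#'   annotated R peak (defaults 0.083 and 0.166).
#' @param w1_ms,w2_ms widths in ms of the fast (peak) and slow (threshold)
#'   moving averages.
#' @param p_factor,t_factor minimum block width for P-/T-candidacy as a
#'   fraction of the W1 window (defaults 0.75 and 1.25, the 3:5 P:T
#'   duration ratio split around 1).
#' @param p_min_ms,p_max_ms P gate: distance from the block peak back to
#'   the *next* R peak, in ms at a 1 s RR interval.
#' @param rt_min_ms,rt_max_ms T gate: distance from the *current* R peak
#'   forward to the block peak, in ms at a 1 s RR interval.
#' @param rr_scale logical; scale all four gate offsets by the measured RR
#'   interval in seconds (faster rhythm, proportionally tighter gates).
#' @param use_abs_peak logical; locate block peaks by maximum absolute
#'   amplitude instead of maximum signed amplitude (for inverted leads).
#' @param tol_ms evaluation matching tolerance in ms (default 40).
#'
#' @return An object of class `detector_params` (a named list).
#' @seealso [detect_pt()]
#' @examples
#' detector_params()
#' detector_params(rt_max_ms = 450, use_abs_peak = TRUE)
#' @export
detector_params <- function(low_hz = 0.5, high_hz = 10, order = 2,
                            pre_s = 0.083, post_s = 0.166,
                            w1_ms = 55, w2_ms = 110,
                            p_factor = 0.75, t_factor = 1.25,
                            p_min_ms = 110, p_max_ms = 560,
                            rt_min_ms = 166, rt_max_ms = 500,
                            rr_scale = TRUE, use_abs_peak = FALSE,
                            tol_ms = 40) {
  p <- list(
    low_hz = check_scalar_number(low_hz, "low_hz", positive = TRUE),
    high_hz = check_scalar_number(high_hz, "high_hz", positive = TRUE),
    order = as.integer(check_scalar_number(order, "order", positive = TRUE)),
    pre_s = check_scalar_number(pre_s, "pre_s"),
    post_s = check_scalar_number(post_s, "post_s"),
    w1_ms = check_scalar_number(w1_ms, "w1_ms", positive = TRUE),
    w2_ms = check_scalar_number(w2_ms, "w2_ms", positive = TRUE),
    p_factor = check_scalar_number(p_factor, "p_factor", positive = TRUE),
    t_factor = check_scalar_number(t_factor, "t_factor", positive = TRUE),
    p_min_ms = check_scalar_number(p_min_ms, "p_min_ms", positive = TRUE),
    p_max_ms = check_scalar_number(p_max_ms, "p_max_ms", positive = TRUE),
    rt_min_ms = check_scalar_number(rt_min_ms, "rt_min_ms", positive = TRUE),
    rt_max_ms = check_scalar_number(rt_max_ms, "rt_max_ms", positive = TRUE),
    rr_scale = isTRUE(rr_scale),
    use_abs_peak = isTRUE(use_abs_peak),
    tol_ms = check_scalar_number(tol_ms, "tol_ms")
  )
  if (p$low_hz >= p$high_hz) stop("low_hz must be below high_hz", call. = FALSE)
  if (p$pre_s < 0 || p$post_s < 0) stop("blanking spans must be >= 0", call. = FALSE)
  if (p$w1_ms >= p$w2_ms) stop("w1_ms must be below w2_ms", call. = FALSE)
  if (p$p_factor >= p$t_factor) stop("p_factor must be below t_factor", call. = FALSE)
  if (p$p_min_ms >= p$p_max_ms) stop("p_min_ms must be below p_max_ms", call. = FALSE)
  if (p$rt_min_ms >= p$rt_max_ms) stop("rt_min_ms must be below rt_max_ms", call. = FALSE)
  class(p) <- "detector_params"
  p
}

#' @export
print.detector_params <- function(x, ...) {
  cat("Two-moving-average P/T delineator parameters\n")
  cat(sprintf("  band-pass     : %.3g-%.3g Hz, order %d, zero phase\n",
              x$low_hz, x$high_hz, x$order))
  cat(sprintf("  QRS blanking  : %.3f s before R, %.3f s after\n", x$pre_s, x$post_s))
  cat(sprintf("  MA windows    : W1 = %g ms, W2 = %g ms\n", x$w1_ms, x$w2_ms))
  cat(sprintf("  block widths  : P >= %.2f x W1, T >= %.2f x W1\n",
              x$p_factor, x$t_factor))
  cat(sprintf("  P gate        : %g-%g ms before next R%s\n", x$p_min_ms, x$p_max_ms,
              if (x$rr_scale) " (RR-scaled)" else ""))
  cat(sprintf("  T gate        : %g-%g ms after current R%s\n", x$rt_min_ms, x$rt_max_ms,
              if (x$rr_scale) " (RR-scaled)" else ""))
  cat(sprintf("  peak polarity : %s\n",
              if (x$use_abs_peak) "maximum |amplitude|" else "maximum amplitude"))
  cat(sprintf("  eval tolerance: +/- %g ms\n", x$tol_ms))
  invisible(x)
}

# apply a flat named list of "section.key" overrides (CLI config files)
apply_param_overrides <- function(params, overrides) {
  key_map <- c(
    "filter.low_hz" = "low_hz", "filter.high_hz" = "high_hz",
    "filter.order" = "order",
    "blank.pre_s" = "pre_s", "blank.post_s" = "post_s",
    "windows.w1_ms" = "w1_ms", "windows.w2_ms" = "w2_ms",
    "windows.p_factor" = "p_factor", "windows.t_factor" = "t_factor",
    "gates.p_min_ms" = "p_min_ms", "gates.p_max_ms" = "p_max_ms",
    "gates.rt_min_ms" = "rt_min_ms", "gates.rt_max_ms" = "rt_max_ms",
    "gates.rr_scale" = "rr_scale", "gates.use_abs_peak" = "use_abs_peak",
    "eval.tol_ms" = "tol_ms"
  )
  args <- unclass(params)
  for (key in names(overrides)) {
    if (!key %in% names(key_map)) {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
    field <- key_map[[key]]
    val <- overrides[[key]]
    if (field %in% c("rr_scale", "use_abs_peak")) {
      val <- tolower(as.character(val)) %in% c("true", "1", "yes", "on")
    } else {
      val <- as.numeric(val)
    }
    args[[field]] <- val
  }
  do.call(detector_params, args)
}
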