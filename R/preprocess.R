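#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward so
#' the net result has zero phase and the squared magnitude response of the
#' one-way design. The default 0.5-10 Hz band keeps P/T-wave energy while
#' removing baseline wander (below 0.5 Hz, including DC) and powerline /
#' muscle noise above 10 Hz.
#'
#' The signal is extended on both sides with `ceil(3 * fs / low_hz)` zero
#' samples before filtering. The long symmetric padding confines start-up
#' transients of the slow high-pass poles to the extensions, makes the
#' operation exactly invariant under time shifts, and symmetric under time
#' reversal to within floating-point noise.
#'
#' @param samples numeric amplitude vector.
#' @param fs sampling frequency in Hz.
#' @param low_hz,high_hz passband edges; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order filter order of the Butterworth prototype.
#' @return filtered vector, same length as `samples`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 2, by = 1 / 360))
#' y <- bandpass(x, fs = 360)
#' @export
bandpass <- function(samples, fs, low_hz = 0.5, high_hz = 10, order = 2) {
  fs <- check_scalar_number(fs, "fs", positive = TRUE)
  low_hz <- check_scalar_number(low_hz, "low_hz", positive = TRUE)
  high_hz <- check_scalar_number(high_hz, "high_hz", positive = TRUE)
  order <- as.integer(check_scalar_number(order, "order", positive = TRUE))
  if (low_hz >= high_hz || high_hz >= fs / 2) {
    stop(sprintf("passband [%g, %g] Hz invalid for fs = %g Hz (need 0 < low < high < fs/2)",
                 low_hz, high_hz, fs), call. = FALSE)
  }
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  n <- length(samples)
  # band-pass of order k has 2k+1 coefficients; demand a few lengths of slack
  min_len <- 3L * (2L * order + 1L)
  if (n <= min_len) {
    stop(sprintf("signal too short to filter (%d samples; need > %d)", n, min_len),
         call. = FALSE)
  }
  ba <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  pad <- as.integer(ceiling(3 * fs / low_hz))
  xp <- c(numeric(pad), as.numeric(samples), numeric(pad))
  y <- signal::filter(ba$b, ba$a, xp)
  y <- rev(signal::filter(ba$b, ba$a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Blank QRS complexes around annotated R peaks
#'
#' Sets the samples in `[r - round(pre_s * fs), r + round(post_s * fs)]`
#' (inclusive, clipped to the signal) to exactly zero for every R peak, so
#' the dominant ventricular deflection cannot contaminate the moving
#' averages and the P and T waves dominate the residue. The defaults blank
#' 83 ms before and 166 ms after each R peak, covering the QRS and the
#' earliest ST segment. The operation is idempotent.
#'
#' @param filtered numeric amplitude vector (normally the [bandpass()] output).
#' @param r_peaks 0-based R-peak indices.
#' @param fs sampling frequency in Hz.
#' @param pre_s,post_s blanking spans in seconds before / after each R peak.
#' @return vector of the same length with the blanked spans set to zero.
#' @examples
#' x <- rep(1, 400)
#' sum(remove_qrs(x, r_peaks = 100, fs = 360) == 0) # 91 samples blanked
#' @export
remove_qrs <- function(filtered, r_peaks, fs, pre_s = 0.083, post_s = 0.166) {
  fs <- check_scalar_number(fs, "fs", positive = TRUE)
  pre_s <- check_scalar_number(pre_s, "pre_s")
  post_s <- check_scalar_number(post_s, "post_s")
  if (pre_s < 0 || post_s < 0) stop("blanking spans must be >= 0", call. = FALSE)
  n <- length(filtered)
  r_peaks <- check_index_vector(r_peaks, n, "r_peaks")
  out <- as.numeric(filtered)
  before <- round_half_up(pre_s * fs)
  after <- round_half_up(post_s * fs)
  for (r in r_peaks) {
    lo <- max(0L, r - before)
    hi <- min(n - 1L, r + after)
    out[(lo + 1L):(hi + 1L)] <- 0
  }
  out
}
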