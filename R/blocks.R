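#' Convert a window duration to an odd sample count
#'
#' Rounds `duration_ms * fs / 1000` half-up to the nearest integer and
#' bumps even results by one so a symmetric centered window exists. At
#' 360 Hz the default moving-average windows become W1 = 21 samples
#' (55 ms) and W2 = 41 samples (110 ms).
#'
#' @param duration_ms window duration in milliseconds (> 0).
#' @param fs sampling frequency in Hz.
#' @return odd positive integer sample count.
#' @examples
#' ms_to_window(55, 360)  # 21
#' ms_to_window(110, 360) # 41
#' @export
ms_to_window <- function(duration_ms, fs) {
  duration_ms <- check_scalar_number(duration_ms, "duration_ms", positive = TRUE)
  fs <- check_scalar_number(fs, "fs", positive = TRUE)
  w <- round_half_up(duration_ms * fs / 1000)
  if (w < 1L) w <- 1L
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Centered moving average with zero boundary
#'
#' Mean of the `w` samples centered on each position; neighbours that fall
#' outside the signal contribute zero. Computed from a cumulative sum so
#' it matches a brute-force windowed mean to numerical precision.
#'
#' @param samples numeric vector.
#' @param w odd positive window length in samples.
#' @return vector of the same length.
#' @examples
#' moving_average(c(0, 1, 2, 3, 4), 3) # 1/3 1 2 3 7/3
#' @export
moving_average <- function(samples, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != floor(w) || w %% 2 == 0) {
    stop("`w` must be an odd positive integer", call. = FALSE)
  }
  w <- as.integer(w)
  x <- as.numeric(samples)
  n <- length(x)
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h - 1L, 0L)
  (cs[hi + 1L] - cs[lo + 1L]) / w
}

#' Generate blocks of interest from the two moving averages
#'
#' A block is a maximal run of consecutive samples where the fast moving
#' average strictly exceeds the slow one (the slow average acts as a
#' dynamic, event-related threshold). Ties produce no block.
#'
#' @param ma_peak fast moving-average output (W1 window).
#' @param ma_pwave slow moving-average output (W2 window), same length.
#' @return data.frame with 0-based columns `onset`, `offset` (inclusive)
#'   and `width`; zero rows when the condition never holds. Peak columns
#'   are added later by [locate_block_peaks()].
#' @export
generate_blocks <- function(ma_peak, ma_pwave) {
  if (length(ma_peak) != length(ma_pwave)) {
    stop("moving-average inputs must have equal length", call. = FALSE)
  }
  active <- ma_peak > ma_pwave
  if (!any(active)) {
    return(data.frame(onset = integer(0), offset = integer(0), width = integer(0)))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    onset = starts[keep] - 1L,
    offset = ends[keep] - 1L,
    width = r$lengths[keep]
  )
}

#' Fill block peak location and amplitude against a reference signal
#'
#' @param blocks data.frame from [generate_blocks()].
#' @param reference amplitude vector the peaks are read from (normally the
#'   band-passed, QRS-blanked signal).
#' @param use_abs locate peaks by maximum absolute amplitude instead of
#'   maximum signed amplitude.
#' @return `blocks` with `peak_index` (0-based) and `peak_amp` columns.
#' @export
locate_block_peaks <- function(blocks, reference, use_abs = FALSE) {
  n <- length(reference)
  if (nrow(blocks) && (blocks$onset[1L] < 0 || blocks$offset[nrow(blocks)] > n - 1L)) {
    stop("block bounds exceed reference signal", call. = FALSE)
  }
  peak_index <- integer(nrow(blocks))
  peak_amp <- numeric(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    seg <- reference[(blocks$onset[i] + 1L):(blocks$offset[i] + 1L)]
    j <- if (use_abs) which.max(abs(seg)) else which.max(seg)
    peak_index[i] <- blocks$onset[i] + j - 1L
    peak_amp[i] <- seg[j]
  }
  blocks$peak_index <- peak_index
  blocks$peak_amp <- peak_amp
  blocks
}

#' Classify blocks by width against the duration priors
#'
#' Narrow blocks are noise: a block is a P candidate only if at least
#' `round(p_factor * w1)` samples wide, and additionally a T candidate if
#' at least `round(t_factor * w1)` samples wide (T waves are wider than P
#' waves; the prior P:T duration ratio of 3:5 motivates factors 0.75 and
#' 1.25 around W1). A wide block may hold both labels; a block below the P
#' threshold is rejected.
#'
#' @param blocks data.frame of blocks.
#' @param w1 fast-window length in samples (see [ms_to_window()]).
#' @param p_factor,t_factor width thresholds as fractions of `w1`.
#' @return `blocks` with logical columns `p_candidate`, `t_candidate` and
#'   `rejected`.
#' @export
classify_blocks <- function(blocks, w1, p_factor = 0.75, t_factor = 1.25) {
  w1 <- check_scalar_number(w1, "w1", positive = TRUE)
  min_p <- round_half_up(p_factor * w1)
  min_t <- round_half_up(t_factor * w1)
  blocks$p_candidate <- blocks$width >= min_p
  blocks$t_candidate <- blocks$width >= min_t
  blocks$rejected <- !blocks$p_candidate
  blocks
}
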