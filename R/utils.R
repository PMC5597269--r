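#' Round half away from zero
#'
#' Deterministic round-to-nearest with .5 rounded up, used for every
#' millisecond-to-sample conversion in the package. `base::round()` rounds
#' half to even, which would make derived sample counts depend on parity.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Convert a duration in milliseconds to a sample count
#'
#' @param ms duration in milliseconds (may be a vector).
#' @param fs sampling frequency in Hz.
#' @return integer sample counts, rounded half up.
#' @examples
#' ms_to_samples(560, 360) # 202
#' @export
ms_to_samples <- function(ms, fs) {
  stopifnot(is.numeric(ms), is.numeric(fs), length(fs) == 1L, fs > 0)
  round_half_up(ms * fs / 1000)
}

# shared argument checks -----------------------------------------------------

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  as.numeric(x)
}

check_index_vector <- function(idx, n, name, allow_empty = TRUE) {
  if (length(idx) == 0L) {
    if (!allow_empty) stop(sprintf("`%s` must be non-empty", name), call. = FALSE)
    return(integer(0))
  }
  if (any(!is.finite(idx)) || any(idx != floor(idx))) {
    stop(sprintf("`%s` must contain integer sample indices", name), call. = FALSE)
  }
  bad <- which(idx < 0 | idx > n - 1L)
  if (length(bad)) {
    stop(sprintf("`%s` index out of range at position %d (value %s, signal length %d)",
                 name, bad[1L], format(idx[bad[1L]]), n), call. = FALSE)
  }
  as.integer(idx)
}
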