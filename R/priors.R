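#' Sinus-rhythm duration priors
#'
#' Normal values and limits of the ECG event durations for a healthy
#' adult at 60 bpm that parameterize the detector, together with their
#' sample-count equivalents at a given sampling frequency (rounded half
#' up). The upper P-search gate of 560 ms used by [gates_for_interval()]
#' is the PQ normal value plus the QTc normal value.
#'
#' @param fs sampling frequency in Hz used for the sample conversions.
#' @return data.frame with columns `feature`, `normal_ms`, `limit_ms`,
#'   `min_samples`, `max_samples`.
#' @examples
#' sinus_priors(360)
#' @export
sinus_priors <- function(fs = 360) {
  priors <- data.frame(
    feature = c("P width", "PQ/PR interval", "QRS width", "QTc interval"),
    normal_ms = c(110, 160, 100, 400),
    limit_ms = c(20, 40, 20, 40)
  )
  priors$min_samples <- ms_to_samples(priors$normal_ms - priors$limit_ms, fs)
  priors$max_samples <- ms_to_samples(priors$normal_ms + priors$limit_ms, fs)
  priors
}

#' Upper bound of the P-wave search gate
#'
#' The farthest a P peak can plausibly sit before the next R peak at the
#' reference rhythm: the sum of the normal PQ and QTc durations.
#'
#' @return duration in ms (560 at the default priors).
#' @export
p_gate_upper_ms <- function() {
  priors <- sinus_priors()
  sum(priors$normal_ms[priors$feature %in% c("PQ/PR interval", "QTc interval")])
}
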