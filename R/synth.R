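#' Noise specification for the synthetic ECG generator
#'
#' @param baseline_amp,baseline_hz baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz); respiration-like drift defaults 0.05 mV at 0.25 Hz.
#' @param powerline_amp,powerline_hz mains-interference sinusoid (default
#'   0.02 mV at 50 Hz; set 60 Hz for North-American mains).
#' @param white_sd standard deviation of additive white Gaussian noise (mV).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0.05, baseline_hz = 0.25,
                       powerline_amp = 0.02, powerline_hz = 50,
                       white_sd = 0.01) {
  structure(list(baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Specification of a synthetic annotated ECG
#'
#' Describes a single-lead recording built from Gaussian wave primitives:
#' for each beat a Gaussian P wave, a biphasic QRS (tall R spike with an S
#' undershoot), and a Gaussian T wave, placed by the PR and RT offsets.
#' Morphology defaults follow the 60 bpm sinus priors: P 110 ms / 0.15 mV,
#' QRS 100 ms / 1 mV, T 160 ms / 0.3 mV, PR 160 ms, RT 300 ms. Gaussians
#' (rather than a dynamical-system ECG model) keep the ground-truth peak
#' locations exact while giving realistic timing, width and amplitude
#' structure.
#'
#' `beat_pattern` is a character vector cycled over beats:
#' * `"N"` normal sinus beat;
#' * `"PVC"` premature ventricular complex: no P wave, widened
#'   higher-amplitude QRS, 20% premature with a compensatory pause;
#' * `"PAC"` premature atrial complex: 15% premature, its distorted P
#'   wave superimposed on the previous beat's T wave (one composite bump
#'   carrying both the P and the preceding T ground truth);
#' * `"MERGED"` the beat's T wave and the following beat's P wave are
#'   fused into one wide wave (one truth index shared by that T and P).
#'
#' @param fs sampling frequency in Hz (default 360).
#' @param duration_s recording length in seconds.
#' @param hr_bpm heart rate in beats per minute (default 60).
#' @param amp_p,amp_r,amp_t wave amplitudes in mV.
#' @param width_p_ms,width_qrs_ms,width_t_ms wave widths in ms (total
#'   support of about six Gaussian standard deviations).
#' @param pr_ms P-peak to R-peak interval in ms.
#' @param rt_ms R-peak to T-peak interval in ms.
#' @param beat_pattern character vector over N / PVC / PAC / MERGED.
#' @param noise a [noise_spec()].
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   samples.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 360, duration_s = 60, hr_bpm = 60,
                       amp_p = 0.15, amp_r = 1.0, amp_t = 0.3,
                       width_p_ms = 110, width_qrs_ms = 100, width_t_ms = 160,
                       pr_ms = 160, rt_ms = 300,
                       beat_pattern = "N",
                       noise = noise_spec(),
                       seed = 1L) {
  s <- list(fs = check_scalar_number(fs, "fs", positive = TRUE),
            duration_s = check_scalar_number(duration_s, "duration_s", positive = TRUE),
            hr_bpm = check_scalar_number(hr_bpm, "hr_bpm", positive = TRUE),
            amp_p = amp_p, amp_r = amp_r, amp_t = amp_t,
            width_p_ms = check_scalar_number(width_p_ms, "width_p_ms", positive = TRUE),
            width_qrs_ms = check_scalar_number(width_qrs_ms, "width_qrs_ms", positive = TRUE),
            width_t_ms = check_scalar_number(width_t_ms, "width_t_ms", positive = TRUE),
            pr_ms = check_scalar_number(pr_ms, "pr_ms", positive = TRUE),
            rt_ms = check_scalar_number(rt_ms, "rt_ms", positive = TRUE),
            beat_pattern = toupper(as.character(beat_pattern)),
            noise = noise,
            seed = as.integer(seed))
  if (!all(s$beat_pattern %in% c("N", "PVC", "PAC", "MERGED"))) {
    stop("beat_pattern entries must be N, PVC, PAC or MERGED", call. = FALSE)
  }
  rr_s <- 60 / s$hr_bpm
  # each cycle must hold lead-in P and trailing T support
  span <- (s$pr_ms + s$width_p_ms / 2 + s$rt_ms + s$width_t_ms / 2) / 1000
  if (span > rr_s) {
    stop(sprintf("wave supports (%.0f ms) do not fit in one RR interval at %g bpm",
                 span * 1000, s$hr_bpm), call. = FALSE)
  }
  class(s) <- "synth_spec"
  s
}

gauss_wave <- function(t, center, sigma, amp) {
  amp * exp(-0.5 * ((t - center) / sigma)^2)
}

# sigma so that ~6 standard deviations span the stated wave width
width_to_sigma <- function(width_ms) width_ms / 6000

# component waves of one beat, centers in seconds relative to the R peak
beat_waves <- function(beat_type, spec) {
  sig_p <- width_to_sigma(spec$width_p_ms)
  sig_t <- width_to_sigma(spec$width_t_ms)
  sig_r <- width_to_sigma(spec$width_qrs_ms) * 0.55
  sig_s <- width_to_sigma(spec$width_qrs_ms) * 0.8
  qrs_gain <- if (beat_type == "PVC") 1.15 else 1
  qrs_widen <- if (beat_type == "PVC") 1.8 else 1
  w <- list(
    list(label = "R", center = 0, sigma = sig_r * qrs_widen,
         amp = spec$amp_r * qrs_gain),
    list(label = "S", center = spec$width_qrs_ms / 4000 * qrs_widen,
         sigma = sig_s * qrs_widen, amp = -0.25 * spec$amp_r * qrs_gain)
  )
  if (beat_type != "PVC") {
    w <- c(w, list(list(label = "P", center = -spec$pr_ms / 1000,
                        sigma = sig_p, amp = spec$amp_p)))
  }
  t_gain <- if (beat_type == "PVC") 1.2 else 1
  w <- c(w, list(list(label = "T", center = spec$rt_ms / 1000,
                      sigma = sig_t * (if (beat_type == "PVC") 1.15 else 1),
                      amp = spec$amp_t * t_gain)))
  w
}

#' Render one synthetic beat
#'
#' Builds the waveform of a single cardiac cycle in isolation, with its
#' local ground truth. `N` yields Gaussian P, biphasic QRS and Gaussian T;
#' `PVC` omits the P wave and widens the QRS; `PAC` renders like a normal
#' beat (its P-on-T distortion only exists in context and is applied by
#' [synth_ecg()]); `MERGED` replaces the separate T and following P by one
#' fused wide bump whose extremum carries both the P and T truth.
#'
#' @param beat_type one of `"N"`, `"PVC"`, `"PAC"`, `"MERGED"`.
#' @param spec a [synth_spec()].
#' @return list with `segment` (numeric waveform), `fs`, `r_index` (0-based
#'   index of the R peak within the segment), and `truth` -- a list with
#'   0-based local indices `p` and `t` (`NULL` where the beat emits none;
#'   identical for a merged bump).
#' @export
make_beat <- function(beat_type, spec = synth_spec()) {
  beat_type <- toupper(beat_type)
  if (!beat_type %in% c("N", "PVC", "PAC", "MERGED")) {
    stop(sprintf("unknown beat type '%s'", beat_type), call. = FALSE)
  }
  fs <- spec$fs
  rr_s <- 60 / spec$hr_bpm
  lead <- spec$pr_ms / 1000 + 4 * width_to_sigma(spec$width_p_ms)
  tail <- if (beat_type == "MERGED") rr_s - lead else
    spec$rt_ms / 1000 + 4 * width_to_sigma(spec$width_t_ms)
  tt <- seq(-lead, tail, by = 1 / fs)
  waves <- beat_waves(beat_type, spec)
  if (beat_type == "MERGED") {
    waves <- Filter(function(w) w$label != "T", waves)
    centre <- (spec$rt_ms / 1000 + (rr_s - spec$pr_ms / 1000)) / 2
    waves <- c(waves, list(list(
      label = "PT", center = centre,
      sigma = width_to_sigma(spec$width_p_ms) + width_to_sigma(spec$width_t_ms),
      amp = max(spec$amp_p, spec$amp_t)
    )))
  }
  seg <- numeric(length(tt))
  for (w in waves) seg <- seg + gauss_wave(tt, w$center, w$sigma, w$amp)
  argmax_near <- function(center, half_s) {
    win <- which(tt >= center - half_s & tt <= center + half_s)
    win[which.max(seg[win])] - 1L
  }
  truth <- list(p = NULL, t = NULL)
  if (beat_type %in% c("N", "PAC")) {
    truth$p <- argmax_near(-spec$pr_ms / 1000, 0.025)
    truth$t <- argmax_near(spec$rt_ms / 1000, 0.025)
  } else if (beat_type == "PVC") {
    truth$t <- argmax_near(spec$rt_ms / 1000, 0.025)
  } else { # MERGED
    centre <- (spec$rt_ms / 1000 + (rr_s - spec$pr_ms / 1000)) / 2
    shared <- argmax_near(centre, 0.06)
    truth$p <- truth$t <- shared
  }
  list(segment = seg, fs = fs, r_index = which.min(abs(tt))[1L] - 1L,
       truth = truth)
}

#' Generate a synthetic annotated ECG record
#'
#' Lays the requested beat pattern on a regular RR grid (premature beats
#' arrive early; the following on-grid beat supplies the compensatory
#' pause), sums the Gaussian wave components into a noise-free signal,
#' reads the exact ground-truth peak positions off that signal, and adds
#' seeded baseline-wander, powerline and white noise.
#'
#' @param spec a [synth_spec()].
#' @return An object of classes `synth_ecg` and [`ecg_record`][ecg_record()]
#'   whose `r_peaks` are the true R positions, with extra fields
#'   `truth_p`, `truth_t` (0-based ground-truth peak indices),
#'   `beat_labels`, `clean` (the noise-free copy) and `spec`.
#' @examples
#' rec <- synth_ecg(synth_spec(duration_s = 10, noise = noise_spec(0, 0, 0)))
#' length(rec$r_peaks)
#' @export
synth_ecg <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  rr <- 60 / spec$hr_bpm
  n_beats <- floor(spec$duration_s / rr)
  if (n_beats < 2) stop("duration must cover at least 2 beats", call. = FALSE)
  lead_in <- spec$pr_ms / 1000 + 4 * width_to_sigma(spec$width_p_ms) + 0.01
  types <- rep(spec$beat_pattern, length.out = n_beats)

  r_times <- lead_in + (seq_len(n_beats) - 1) * rr
  r_times[types == "PVC"] <- r_times[types == "PVC"] - 0.2 * rr
  r_times[types == "PAC"] <- r_times[types == "PAC"] - 0.15 * rr
  if (types[1L] %in% c("PVC", "PAC")) r_times[1L] <- lead_in

  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  clean <- numeric(n)
  sig_p <- width_to_sigma(spec$width_p_ms)
  sig_t <- width_to_sigma(spec$width_t_ms)

  add_wave <- function(center, sigma, amp) {
    lo <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
    if (lo <= hi) {
      idx <- lo:hi
      clean[idx] <<- clean[idx] + gauss_wave(tt[idx], center, sigma, amp)
    }
  }

  # nominal centers of the truth-bearing waves, NA where a beat emits none
  p_center <- rep(NA_real_, n_beats)
  t_center <- rep(NA_real_, n_beats)
  p_shared_with_prev_t <- logical(n_beats)

  for (k in seq_len(n_beats)) {
    for (w in beat_waves(types[k], spec)) {
      if (w$label == "P") {
        if (k > 1 && types[k - 1L] == "MERGED") next # fused into previous bump
        if (types[k] == "PAC" && k > 1 && !is.na(t_center[k - 1L])) {
          # distorted P superimposed on the previous T wave
          center <- r_times[k - 1L] + spec$rt_ms / 1000 + 0.02
          add_wave(center, sig_p * 1.2, w$amp)
          p_center[k] <- center
          p_shared_with_prev_t[k] <- TRUE
          next
        }
        add_wave(r_times[k] + w$center, w$sigma, w$amp)
        p_center[k] <- r_times[k] + w$center
      } else if (w$label == "T") {
        if (types[k] == "MERGED" && k < n_beats) {
          centre <- (r_times[k] + spec$rt_ms / 1000 +
                       r_times[k + 1L] - spec$pr_ms / 1000) / 2
          add_wave(centre, sig_p + sig_t, max(spec$amp_p, spec$amp_t))
          t_center[k] <- centre
          p_center[k + 1L] <- centre
        } else {
          add_wave(r_times[k] + w$center, w$sigma, w$amp)
          t_center[k] <- r_times[k] + w$center
        }
      } else {
        add_wave(r_times[k] + w$center, w$sigma, w$amp)
      }
    }
  }

  argmax_near <- function(center, half_s) {
    lo <- max(1L, floor((center - half_s) * fs) + 1L)
    hi <- min(n, ceiling((center + half_s) * fs) + 1L)
    idx <- lo:hi
    idx[which.max(clean[idx])] - 1L
  }
  r_idx <- round_half_up(r_times * fs)
  truth_p <- integer(0)
  truth_t <- integer(0)
  for (k in seq_len(n_beats)) {
    if (!is.na(t_center[k])) {
      half <- if (types[k] == "MERGED" || (k < n_beats && p_shared_with_prev_t[k + 1L]))
        0.06 else 0.025
      truth_t <- c(truth_t, argmax_near(t_center[k], half))
    }
    if (!is.na(p_center[k])) {
      half <- if (p_shared_with_prev_t[k] ||
                  (k > 1 && types[k - 1L] == "MERGED")) 0.06 else 0.025
      truth_p <- c(truth_p, argmax_near(p_center[k], half))
    }
  }

  noisy <- clean
  ns <- spec$noise
  has_noise <- ns$baseline_amp > 0 || ns$powerline_amp > 0 || ns$white_sd > 0
  if (has_noise) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    if (ns$baseline_amp > 0) {
      noisy <- noisy + ns$baseline_amp *
        sin(2 * pi * ns$baseline_hz * tt + stats::runif(1, 0, 2 * pi))
    }
    if (ns$powerline_amp > 0) {
      noisy <- noisy + ns$powerline_amp *
        sin(2 * pi * ns$powerline_hz * tt + stats::runif(1, 0, 2 * pi))
    }
    if (ns$white_sd > 0) {
      noisy <- noisy + stats::rnorm(n, sd = ns$white_sd)
    }
  }

  rec <- ecg_record(noisy, fs = fs, r_peaks = r_idx,
                    record_id = sprintf("synth-%dbpm-%s", round(spec$hr_bpm),
                                        paste(unique(types), collapse = "+")))
  rec$truth_p <- sort(unique(truth_p))
  rec$truth_t <- sort(unique(truth_t))
  rec$beat_labels <- types
  rec$clean <- clean
  rec$spec <- spec
  class(rec) <- c("synth_ecg", class(rec))
  rec
}

#' @export
print.synth_ecg <- function(x, ...) {
  NextMethod()
  cat(sprintf("  synthetic: %d beats (%s), truth P: %d, truth T: %d\n",
              length(x$beat_labels),
              paste(unique(x$beat_labels), collapse = "/"),
              length(x$truth_p), length(x$truth_t)))
  invisible(x)
}
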