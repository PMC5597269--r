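# Independent reference implementations used to cross-check the package.

# windowed mean by explicit double loop, out-of-range neighbours = 0
oracle_moving_average <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in (i - h):(i + h)) {
      if (j >= 1 && j <= n) s <- s + x[j]
    }
    out[i] <- s / w
  }
  out
}

# maximal runs of TRUE by linear scan (0-based inclusive bounds)
oracle_runs <- function(active) {
  onsets <- integer(0); offsets <- integer(0)
  inside <- FALSE
  for (i in seq_along(active)) {
    if (active[i] && !inside) { onsets <- c(onsets, i - 1L); inside <- TRUE }
    if (!active[i] && inside) { offsets <- c(offsets, i - 2L); inside <- FALSE }
  }
  if (inside) offsets <- c(offsets, length(active) - 1L)
  data.frame(onset = onsets, offset = offsets, width = offsets - onsets + 1L)
}

# maximum-cardinality one-to-one matching within tolerance, by exhaustive
# search over all injective assignments (feasible for <= 6 peaks per side)
oracle_best_tp <- function(detected, reference, tol) {
  best <- 0L
  recurse <- function(ri, used, tp) {
    if (tp + (length(reference) - ri + 1L) <= best) return()
    if (ri > length(reference)) { best <<- max(best, tp); return() }
    recurse(ri + 1L, used, tp) # leave this reference unmatched
    for (di in seq_along(detected)) {
      if (!used[di] && abs(detected[di] - reference[ri]) <= tol) {
        used[di] <- TRUE
        recurse(ri + 1L, used, tp + 1L)
        used[di] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(detected)), 0L)
  best
}

# squared magnitude response of the digital order-n Butterworth band-pass
# (bilinear transform with prewarped edges), in closed form
oracle_butter_gain2 <- function(f, fs, low, high, n = 2) {
  u <- tan(pi * f / fs)
  u1 <- tan(pi * low / fs)
  u2 <- tan(pi * high / fs)
  1 / (1 + ((u^2 - u1 * u2) / ((u2 - u1) * u))^(2 * n))
}

clean_noise <- function() noise_spec(0, 0, 0)
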