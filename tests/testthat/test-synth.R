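test_that("single-beat rendering honours each beat class", {
  spec <- synth_spec(noise = clean_noise())

  nb <- make_beat("N", spec)
  seg <- nb$segment
  crests <- which(diff(sign(diff(seg))) == -2) + 1L
  crests <- crests[seg[crests] > 0.05]
  expect_length(crests, 3) # P, R and T crests, all positive
  expect_false(is.null(nb$truth$p))
  expect_false(is.null(nb$truth$t))
  # truth indices sit on the P and T crests
  expect_true(all(c(nb$truth$p, nb$truth$t) %in% (crests - 1L)))

  pvc <- make_beat("PVC", spec)
  expect_null(pvc$truth$p) # no atrial wave on a ventricular ectopic
  expect_false(is.null(pvc$truth$t))

  mg <- make_beat("MERGED", spec)
  expect_identical(mg$truth$p, mg$truth$t) # one fused bump carries both truths
  expect_equal(which.max(mg$segment[-seq_len(mg$r_index + 60)]),
               mg$truth$p + 1L - (mg$r_index + 60))

  expect_error(make_beat("XX", spec), "unknown beat type")
})

test_that("records are deterministic for a fixed spec and seed", {
  spec <- synth_spec(duration_s = 10, seed = 9)
  r1 <- synth_ecg(spec)
  r2 <- synth_ecg(spec)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth_p, r2$truth_p)
  r3 <- synth_ecg(synth_spec(duration_s = 10, seed = 10))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("truth counts follow the beat pattern", {
  rec <- synth_ecg(synth_spec(duration_s = 10, noise = clean_noise()))
  expect_length(rec$r_peaks, 10)
  expect_length(rec$truth_p, 10)
  expect_length(rec$truth_t, 10)

  pvc <- synth_ecg(synth_spec(duration_s = 20, beat_pattern = c("N", "PVC"),
                              noise = clean_noise()))
  n_pvc <- sum(pvc$beat_labels == "PVC")
  expect_length(pvc$truth_p, 20 - n_pvc) # PVC beats contribute no P truth
  expect_length(pvc$truth_t, 20)

  mg <- synth_ecg(synth_spec(duration_s = 12, beat_pattern = c("N", "MERGED"),
                             noise = clean_noise()))
  # every fused bump index appears in both truth lists
  shared <- intersect(mg$truth_p, mg$truth_t)
  n_fused <- sum(mg$beat_labels == "MERGED" &
                   seq_along(mg$beat_labels) < length(mg$beat_labels))
  expect_gte(length(shared), n_fused)
})

test_that("noise-free truth peaks sit on the signal extrema at their nominal centers", {
  rec <- synth_ecg(synth_spec(duration_s = 10, noise = clean_noise()))
  fs <- rec$fs
  half <- round(0.010 * fs)
  for (p in rec$truth_p) {
    win <- (p - half):(p + half)
    expect_identical(which.max(rec$clean[win + 1L]) - 1L + win[1L], p)
  }
  # ground truth coincides with the noise-free copy even for a noisy record
  noisy <- synth_ecg(synth_spec(duration_s = 10, seed = 3))
  expect_false(identical(noisy$samples, noisy$clean))
  expect_identical(noisy$truth_p, synth_ecg(synth_spec(duration_s = 10,
                                                       noise = clean_noise()))$truth_p)
})

test_that("premature beats are early and followed by a compensatory pause", {
  rec <- synth_ecg(synth_spec(duration_s = 20, beat_pattern = c("N", "N", "PVC", "N"),
                              noise = clean_noise()))
  rr <- diff(rec$r_peaks) / rec$fs
  pvc_pos <- which(rec$beat_labels == "PVC")
  pvc_pos <- pvc_pos[pvc_pos > 1 & pvc_pos < length(rec$beat_labels)]
  expect_true(all(rr[pvc_pos - 1] < 0.9))  # premature arrival
  expect_true(all(rr[pvc_pos] > 1.1))      # longer following interval
})

test_that("generator rejects specs whose waves cannot fit the RR interval", {
  expect_error(synth_spec(hr_bpm = 200), "do not fit")
  expect_error(synth_ecg(synth_spec(duration_s = 1)), "at least 2 beats")
})
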