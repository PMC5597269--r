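fs <- 360

test_that("gate windows follow the RR-scaled offsets of the duration priors", {
  g <- gates_for_interval(0, 360, fs, detector_params())
  expect_identical(g$p_window, c(158L, 320L)) # 360-round(.560*360), 360-round(.110*360)
  expect_identical(g$t_window, c(60L, 180L))  # round(.166*360), round(.500*360)

  # halving RR halves all four offsets before rounding
  gh <- gates_for_interval(0, 180, fs, detector_params())
  expect_identical(gh$t_window, c(30L, 90L))
  expect_identical(gh$p_window, c(180L - 101L, 180L - 20L))

  # without RR scaling the offsets are fixed
  gf <- gates_for_interval(0, 180, fs, detector_params(rr_scale = FALSE))
  expect_identical(gf$t_window, c(60L, 179L)) # upper end clipped into the interval

  expect_error(gates_for_interval(100, 100, fs), "strictly increasing")
})

test_that("three-scenario logic resolves empty, merged and multi-block intervals", {
  params <- detector_params()
  empty <- data.frame(onset = integer(0), offset = integer(0), width = integer(0))
  res0 <- delineate_interval(empty, 0, 360, numeric(400), fs, params)
  expect_identical(res0$scenario, "none")
  expect_true(is.na(res0$p) && is.na(res0$t))

  # lone block with its crest inside the T gate: merged P-T
  ref <- numeric(400); ref[91] <- 1 # peak at index 90
  one <- data.frame(onset = 80L, offset = 110L, width = 31L)
  res1 <- delineate_interval(one, 0, 360, ref, fs, params)
  expect_identical(res1$scenario, "one")
  expect_true(res1$merged)
  expect_identical(res1$p, 90L)
  expect_identical(res1$t, 90L)

  # lone block outside both gates: nothing
  ref2 <- numeric(400); ref2[31] <- 1
  out <- data.frame(onset = 20L, offset = 50L, width = 31L)
  res2 <- delineate_interval(out, 0, 360, ref2, fs, params)
  expect_true(is.na(res2$p) && is.na(res2$t) && !res2$merged)

  # two blocks: T from the T gate, P from the P gate
  ref3 <- numeric(400); ref3[91] <- 1; ref3[201] <- 0.5 # peaks at 90 and 200
  two <- data.frame(onset = c(80L, 185L), offset = c(110L, 215L), width = c(31L, 31L))
  res3 <- delineate_interval(two, 0, 360, ref3, fs, params)
  expect_identical(res3$scenario, "many")
  expect_identical(res3$t, 90L)
  expect_identical(res3$p, 200L)
  expect_false(res3$merged)
})

test_that("amplitude ties in a gate go to the higher crest and troughs are ignored", {
  params <- detector_params()
  # two T-candidates in the T gate: higher amplitude wins
  ref <- numeric(400); ref[81] <- 0.4; ref[151] <- 0.9; ref[201] <- 0.5
  blocks <- data.frame(onset = c(70L, 140L, 185L), offset = c(100L, 170L, 215L),
                       width = c(31L, 31L, 31L))
  res <- delineate_interval(blocks, 0, 360, ref, fs, params)
  expect_identical(res$t, 150L)
  expect_identical(res$p, 200L)

  # a block whose extremum is a trough is never reported: with the trough in
  # the T gate and two crests in the P gate, no T is found and the higher
  # crest wins the P gate
  ref2 <- numeric(400); ref2[91] <- -0.8; ref2[201] <- 0.5; ref2[241] <- 0.3
  blocks2 <- data.frame(onset = c(70L, 185L, 230L), offset = c(100L, 215L, 260L),
                        width = c(31L, 31L, 31L))
  res2 <- delineate_interval(blocks2, 0, 360, ref2, fs, params)
  expect_identical(res2$scenario, "many")
  expect_true(is.na(res2$t))
  expect_identical(res2$p, 200L)

  # when the trough block is the only companion, the surviving crest is a
  # lone block again and falls back to the merged rule
  res2b <- delineate_interval(blocks2[c(1, 2), ], 0, 360, ref2, fs, params)
  expect_true(res2b$merged)
  expect_identical(res2b$p, 200L)
  expect_identical(res2b$t, 200L)
})

test_that("full pipeline recovers every wave on a clean sinus record", {
  rec <- synth_ecg(synth_spec(duration_s = 20, noise = clean_noise()))
  det <- detect_pt(rec)
  n_int <- length(rec$r_peaks) - 1L
  expect_identical(nrow(det$intervals), n_int)
  expect_length(det$p_peaks, n_int) # one P and one T per complete interval
  expect_length(det$t_peaks, n_int)
  # each detection within half the true wave width of its ground truth
  half_p <- ms_to_samples(110 / 2, fs)
  half_t <- ms_to_samples(160 / 2, fs)
  tp_in_span <- rec$truth_p[rec$truth_p > min(rec$r_peaks) & rec$truth_p < max(rec$r_peaks)]
  tt_in_span <- rec$truth_t[rec$truth_t > min(rec$r_peaks) & rec$truth_t < max(rec$r_peaks)]
  expect_true(all(abs(det$p_peaks - tp_in_span) <= half_p))
  expect_true(all(abs(det$t_peaks - tt_in_span) <= half_t))
})

test_that("detection is invariant under positive gain and exact under time shifts", {
  rec <- synth_ecg(synth_spec(duration_s = 15, seed = 5)) # default (noisy) conditions
  det <- detect_pt(rec)

  scaled <- rec
  scaled$samples <- 10 * rec$samples
  det_scaled <- detect_pt(scaled)
  expect_identical(det_scaled$p_peaks, det$p_peaks)
  expect_identical(det_scaled$t_peaks, det$t_peaks)
  expect_identical(det_scaled$merged, det$merged)

  k <- 137L
  shifted <- ecg_record(c(numeric(k), rec$samples), fs = rec$fs,
                        r_peaks = rec$r_peaks + k, record_id = "shifted")
  det_shift <- detect_pt(shifted)
  expect_identical(det_shift$p_peaks, det$p_peaks + k)
  expect_identical(det_shift$t_peaks, det$t_peaks + k)
})

test_that("degenerate inputs are rejected or yield empty results", {
  expect_error(detect_pt(ecg_record(rnorm(1000), fs, r_peaks = 500)),
               "at least 2 R peaks")
  flat <- ecg_record(rep(0, 2000), fs, r_peaks = c(400, 1500))
  det <- detect_pt(flat)
  expect_length(det$p_peaks, 0)
  expect_length(det$t_peaks, 0)
  expect_identical(det$intervals$scenario, "none")
})

test_that("per-interval provenance log records gates and scenarios", {
  rec <- synth_ecg(synth_spec(duration_s = 12, noise = clean_noise()))
  det <- detect_pt(rec)
  iv <- det$intervals
  expect_true(all(iv$t_lo > iv$r_i & iv$t_hi < iv$r_next))
  expect_true(all(iv$p_lo > iv$r_i & iv$p_hi < iv$r_next))
  expect_true(all(iv$scenario %in% c("none", "one", "many")))
  expect_true(all(iv$n_blocks >= 0))
})
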