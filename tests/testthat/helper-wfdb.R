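# Writes a tiny synthetic WFDB record (format 212 header/signal/annotation
# triplet) at test run time so the adapter can be exercised without any
# external download. adc is an n x n_sig integer matrix of raw ADC units.
write_wfdb_fixture <- function(dir, name = "tst", adc, fs = 360,
                               gain = 200, baseline = 0, r_peaks = integer(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sig <- ncol(adc)
  hea <- c(
    sprintf("%s %d %g %d", name, n_sig, fs, nrow(adc)),
    vapply(seq_len(n_sig), function(i) {
      sprintf("%s.dat 212 %g(%d) 12 0 0 0 0 lead%d", name, gain, baseline, i)
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(name, ".hea")))

  flat <- as.integer(t(adc)) # frame-interleaved
  if (length(flat) %% 2L) flat <- c(flat, 0L)
  flat[flat < 0] <- flat[flat < 0] + 4096L
  s1 <- flat[seq(1, length(flat), by = 2)]
  s2 <- flat[seq(2, length(flat), by = 2)]
  bytes <- as.raw(rbind(
    bitwAnd(s1, 0xFF),
    bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L)),
    bitwAnd(s2, 0xFF)
  ))
  writeBin(bytes, file.path(dir, paste0(name, ".dat")))

  # MIT annotation stream: NORMAL (code 1) beats at the given samples
  words <- raw(0)
  prev <- 0L
  for (s in r_peaks) {
    interval <- s - prev
    stopifnot(interval >= 0, interval < 1024) # keep fixtures SKIP-free
    words <- c(words, as.raw(bitwAnd(interval, 0xFF)),
               as.raw(bitwOr(bitwShiftL(1L, 2L), bitwShiftR(interval, 8L))))
    prev <- s
  }
  words <- c(words, as.raw(c(0, 0)))
  writeBin(words, file.path(dir, paste0(name, ".atr")))
  file.path(dir, name)
}
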