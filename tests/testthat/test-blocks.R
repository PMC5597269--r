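test_that("ms-to-window conversion rounds half up and enforces oddness", {
  expect_identical(ms_to_window(55, 360), 21L)  # 19.8 -> 20 -> 21
  expect_identical(ms_to_window(110, 360), 41L) # 39.6 -> 40 -> 41
  expect_identical(ms_to_window(12.5, 400), 5L) # exactly 5, already odd
  expect_error(ms_to_window(0, 360), "positive")
  expect_error(ms_to_window(-5, 360), "positive")
})

test_that("moving average equals the brute-force oracle for all odd windows <= 101", {
  expect_identical(moving_average(c(3, 1, 4), 1), c(3, 1, 4))
  expect_equal(moving_average(c(0, 1, 2, 3, 4), 3), c(1 / 3, 1, 2, 3, 7 / 3),
               tolerance = 1e-12)
  const <- rep(2.5, 50)
  expect_equal(moving_average(const, 7)[4:47], const[4:47], tolerance = 1e-12)

  set.seed(101)
  x <- rnorm(300)
  for (w in seq(1, 101, by = 2)) {
    expect_equal(moving_average(x, w), oracle_moving_average(x, w),
                 tolerance = 1e-12)
  }
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 0), "odd")
})

test_that("blocks are the maximal runs where the fast average strictly exceeds the slow", {
  expect_identical(nrow(generate_blocks(rep(0, 10), rep(0, 10))), 0L) # ties: no block
  ma1 <- rep(0, 12); ma1[4:8] <- 1
  b <- generate_blocks(ma1, rep(0.5, 12))
  expect_identical(b$onset, 3L)
  expect_identical(b$offset, 7L)
  expect_identical(b$width, 5L)

  ma2 <- rep(0, 12); ma2[c(3, 4, 10)] <- 1
  b2 <- generate_blocks(ma2, rep(0.5, 12))
  expect_identical(b2$width, c(2L, 1L))
  expect_error(generate_blocks(1:3, 1:4), "equal length")
})

test_that("block index-union equals the pointwise comparison set on random inputs", {
  set.seed(202)
  for (rep_i in 1:20) {
    n <- sample(50:300, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    blocks <- generate_blocks(a, b)
    # sorted and pairwise disjoint
    if (nrow(blocks) > 1) {
      expect_true(all(diff(blocks$onset) > 0))
      expect_true(all(blocks$onset[-1] > blocks$offset[-nrow(blocks)]))
    }
    union_idx <- unlist(Map(seq, blocks$onset, blocks$offset))
    expect_identical(sort(as.integer(union_idx)), which(a > b) - 1L)
    expect_identical(blocks, oracle_runs(a > b))
    # scale invariance for positive gain
    expect_identical(generate_blocks(3.2 * a, 3.2 * b), blocks)
  }
})

test_that("width classification applies the rounded P and T thresholds", {
  mk <- function(widths) data.frame(onset = cumsum(c(0, head(widths, -1) + 5)),
                                    offset = cumsum(c(0, head(widths, -1) + 5)) + widths - 1,
                                    width = widths)
  cl <- classify_blocks(mk(c(1, 15, 16, 26, 27)), w1 = 21)
  expect_identical(cl$rejected, c(TRUE, TRUE, FALSE, FALSE, FALSE)) # min P width 16
  expect_identical(cl$p_candidate, !cl$rejected)
  expect_identical(cl$t_candidate, c(FALSE, FALSE, FALSE, TRUE, TRUE)) # min T width 26
})

test_that("classification is monotonic in width", {
  set.seed(303)
  for (rep_i in 1:10) {
    widths <- sample(1:60, 12, replace = TRUE)
    cl <- classify_blocks(data.frame(onset = 0L, offset = widths - 1L, width = widths),
                          w1 = sample(5:41, 1),
                          p_factor = runif(1, 0.3, 1), t_factor = runif(1, 1, 2))
    ord <- order(cl$width)
    expect_true(all(diff(!cl$rejected[ord]) >= 0)) # wider never rejected below a narrower accept
    expect_true(all(diff(cl$t_candidate[ord]) >= 0))
  }
})

test_that("block peaks locate the extremum of the reference signal", {
  ref <- c(0, 1, 5, 2, 0, -7, 3, 0)
  b <- data.frame(onset = c(0L, 4L), offset = c(3L, 7L), width = c(4L, 4L))
  pk <- locate_block_peaks(b, ref)
  expect_identical(pk$peak_index, c(2L, 6L))
  expect_identical(pk$peak_amp, c(5, 3))
  pk_abs <- locate_block_peaks(b, ref, use_abs = TRUE)
  expect_identical(pk_abs$peak_index, c(2L, 5L))
  expect_identical(pk_abs$peak_amp, c(5, -7))
})
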