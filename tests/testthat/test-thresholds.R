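# Yen and Triangle automatic thresholds.  Expected values on the
# deterministic fixtures were computed with an independent reference
# implementation (integer-binned histograms) and frozen here.

test_that("Yen and Triangle match the reference implementation on frozen fixtures", {
  x1 <- threshold_fixture(1)
  x2 <- threshold_fixture(2)
  expect_equal(threshold_yen(x1), 123)
  expect_equal(threshold_triangle(x1), 129)
  expect_equal(threshold_yen(x2), 64)
  expect_equal(threshold_triangle(x2), 67)
})

test_that("thresholds separate well-separated bimodal mixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    lo <- rnorm(3000, 80, 8)
    hi <- rnorm(800, 1200, 60)
    x <- round(pmax(c(lo, hi), 0))
    for (thr in c(threshold_yen(x), threshold_triangle(x))) {
      expect_gt(thr, max(0, mean(lo)))
      expect_lt(thr, min(hi))
    }
  }
})

test_that("degenerate single-level input raises an error", {
  expect_error(threshold_yen(rep(5, 100)), "single intensity")
  expect_error(threshold_triangle(matrix(0, 4, 4)), "single intensity")
})
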