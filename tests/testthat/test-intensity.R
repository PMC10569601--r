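# integrated patch intensity, 0-100 normalization, percent depletion and
# the relative-SD texture metric

test_that("patch measurement recovers planted sums within tolerance", {
  spec <- synthetic_spec(patches = list(planted_patch(30, 16)), n_frames = 2,
                         seed = 9)
  gen <- make_patch_series(spec)
  truth <- gen$truth$integrated_per_frame[1]
  res <- patch_intensity(gen$movie, matrix(TRUE, 128, 128), 1:2)
  expect_equal(res$per_frame$integrated[1], truth, tolerance = 0.01)
  expect_equal(res$total, sum(res$per_frame$integrated))
})

test_that("patches overlapping the chromosome mask contribute nothing", {
  spec <- synthetic_spec(patches = list(planted_patch(55, 14, 20, 40)),
                         n_frames = 2, seed = 9)
  # patch covers the chromosome blob (centred near row 64, col 33)
  gen <- make_patch_series(spec)
  res <- patch_intensity(gen$movie, matrix(TRUE, 128, 128), 1)
  expect_equal(res$total, 0)
  # the same patch far from the chromosomes is measured
  spec2 <- synthetic_spec(patches = list(planted_patch(10, 80, 20, 40)),
                          n_frames = 2, seed = 9)
  gen2 <- make_patch_series(spec2)
  res2 <- patch_intensity(gen2$movie, matrix(TRUE, 128, 128), 1)
  expect_gt(res2$total, 0)
})

test_that("empty images and empty ROIs behave as specified", {
  spec <- synthetic_spec(patches = list(), n_frames = 2, seed = 9)
  gen <- make_patch_series(spec)
  res <- patch_intensity(gen$movie, matrix(TRUE, 128, 128), 1,
                         chrom_exclude = FALSE, channel = "patch")
  expect_equal(res$total, 0)
  expect_error(patch_intensity(gen$movie, matrix(FALSE, 128, 128), 1),
               "empty ROI")
})

test_that("the 16-timepoint variant is additive and window-consistent", {
  spec <- synthetic_spec(patches = list(planted_patch(10, 16)), n_frames = 16,
                         seed = 4)
  gen <- make_patch_series(spec)
  roi <- matrix(TRUE, 128, 128)
  ml <- microtubule_level(gen$movie, roi, start = 1, n_timepoints = 16)
  per <- patch_intensity(gen$movie, roi, 1)$per_frame$integrated[1]
  expect_equal(ml$total, 16 * per, tolerance = 1e-10)
  p5 <- microtubule_level(gen$movie, roi, start = 3, n_timepoints = 5)
  expect_equal(p5$total, patch_intensity(gen$movie, roi, 3:7)$total)
  expect_error(microtubule_level(gen$movie, roi, start = 5, n_timepoints = 16),
               "fewer frames")
})

test_that("patch window defaults to five frames from -200 s", {
  expect_equal(patch_window(25), 5:9)
  expect_equal(patch_window(25, n_timepoints = 16), 5:20)
})

test_that("score normalization maps the group onto [0, 100] exactly", {
  expect_equal(normalize_scores(c(10, 30, 50)), c(0, 50, 100))
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(2:20, 1), 100, 30)
    z <- normalize_scores(x)
    expect_identical(min(z), 0)
    expect_identical(max(z), 100)
    expect_equal(order(z), order(x))
    expect_equal(normalize_scores(x + 17.3), z, tolerance = 1e-12)
  }
  expect_error(normalize_scores(c(5, 5, 5)), "degenerate")
})

test_that("percent depletion is the distance from the group maximum", {
  expect_equal(percent_depletion(100), 0)
  expect_equal(percent_depletion(0), 100)
  expect_equal(percent_depletion(75), 25)
  expect_error(percent_depletion(120), "\\[0, 100\\]")
})

test_that("relative SD: estimator, invariances, exclusion circle", {
  expect_equal(relative_sd(matrix(c(1, 3), 2, 1))$rsd, sqrt(2) / 2)
  expect_equal(relative_sd(matrix(5, 10, 10))$rsd, 0)
  set.seed(12)
  img <- matrix(runif(400, 10, 50), 20, 20)
  r1 <- relative_sd(img)
  expect_equal(relative_sd(img * 3.7)$rsd, r1$rsd, tolerance = 1e-12)
  # adding a constant lowers the RSD (translation sensitivity)
  expect_lt(relative_sd(img + 100)$rsd, r1$rsd)
  # a bright blob inside the exclusion circle does not affect the metric
  img2 <- img
  img2[9:11, 9:11] <- 1e4
  expect_equal(relative_sd(img2, center = c(10, 10), radius_px = 5)$rsd,
               relative_sd(img, center = c(10, 10), radius_px = 5)$rsd)
  expect_error(relative_sd(matrix(0, 5, 5)), "zero mean")
})
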