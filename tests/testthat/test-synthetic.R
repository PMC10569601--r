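# the generators: determinism, echo fidelity, containment, validation

test_that("generators are deterministic for a fixed spec and seed", {
  spec <- synthetic_spec(ingressions = list(planted_ingression(90, 1.5)),
                         n_frames = 3, noise_sd = 40, seed = 21)
  a <- make_ingression_movie(spec)
  b <- make_ingression_movie(spec)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
  specp <- synthetic_spec(patches = list(planted_patch(20, 20)), n_frames = 2,
                          noise_sd = 25, seed = 22)
  expect_identical(make_patch_series(specp)$movie$data,
                   make_patch_series(specp)$movie$data)
})

test_that("ground truth echoes the planted ingressions exactly", {
  ings <- list(planted_ingression(90, 2.0, width_px = 5),
               planted_ingression(200, 1.2, frames = 2:3))
  spec <- synthetic_spec(ingressions = ings, n_frames = 4, seed = 1)
  tr <- make_ingression_movie(spec)$truth
  expect_equal(nrow(tr$ingressions), 2)
  expect_equal(tr$ingressions$angle_deg, c(90, 200))
  expect_equal(tr$ingressions$depth_um, c(2.0, 1.2))
  expect_equal(tr$ingressions$width_px, c(5, 4))
  expect_equal(tr$ingressions$frame_start, c(1L, 2L))
  expect_equal(tr$ingressions$frame_end, c(4L, 3L))
  expect_equal(tr$ingressions$depth_px, c(2.0, 1.2) / spec$pixel_size_um)
})

test_that("a spec with no ingressions yields a convex ring and empty truth", {
  spec <- synthetic_spec(n_frames = 2, seed = 2)
  gen <- make_ingression_movie(spec)
  expect_equal(nrow(gen$truth$ingressions), 0)
  img <- movie_volume(gen$movie, 1, "membrane")[, , gen$truth$central_plane]
  ct <- extract_contour(segment_cortex(img))
  href <- hull_reference(ct)
  ev <- find_ingressions(href, pixel_size_um = spec$pixel_size_um)
  expect_equal(nrow(ev), 0)
})

test_that("the rendered chromosome area attains a unique planted minimum", {
  spec <- synthetic_spec(n_frames = 9, seed = 3)
  gen <- make_ingression_movie(spec)
  areas <- vapply(1:9, function(t)
    sum(chromosome_objects(movie_volume(gen$movie, t, "chromosomes"))),
    numeric(1))
  expect_equal(which.min(areas), gen$truth$anaphase_onset_frame)
  expect_equal(sum(areas == min(areas)), 1L)
})

test_that("scmf ground truth echoes foci, classes and exclusion flags", {
  spec <- scmf_spec(foci = list(planted_focus(1000), planted_focus(1000),
                                planted_focus(1000), planted_focus(2500),
                                planted_focus(5000)),
                    n_frames = 2, seed = 3)
  tr <- make_scmf_movie(spec)$truth
  expect_equal(unname(tr$class_counts), c(3L, 1L, 1L))
  expect_equal(tr$total, 5L)
  expect_equal(tr$foci$target_mean, c(1000, 1000, 1000, 2500, 5000))
  # a focus 0.05 um from the spindle surface is flagged excluded
  spec2 <- scmf_spec(foci = list(planted_focus(2500,
                                               distance_to_spindle_um = 0.05)),
                     n_frames = 2, seed = 4)
  tr2 <- make_scmf_movie(spec2)$truth
  expect_true(tr2$foci$excluded_spindle[1])
  expect_lte(tr2$foci$dist_spindle_um[1], 0.1)
  expect_equal(tr2$total, 0L)
})

test_that("planted foci lie inside the oocyte mask (containment)", {
  spec <- scmf_spec(foci = list(planted_focus(1000), planted_focus(5000)),
                    n_frames = 2, seed = 6)
  gen <- make_scmf_movie(spec)
  oomask <- movie_volume(gen$movie, 1, "mask") > 0
  for (k in seq_len(nrow(gen$truth$foci))) {
    fc <- gen$truth$foci[k, ]
    expect_true(oomask[fc$cy, fc$cx, fc$cz])
  }
})

test_that("invalid planted objects are rejected", {
  expect_error(synthetic_spec(foci = list(planted_focus(1000,
                                                        center = c(8, 5, 5)))),
               "outside the oocyte")
  expect_error(synthetic_spec(foci = list(planted_focus(1000,
                                                        center = c(99, 5, 5)))),
               "outside the image")
  expect_error(synthetic_spec(patches = list(planted_patch(120, 120, 30, 30))),
               "outside the image")
  expect_error(synthetic_spec(ingressions = list(planted_ingression(0, 8))),
               "ring closure")
  expect_error(planted_focus(1000, intended_class = "strong"),
               "inconsistent")
  expect_error(planted_ingression(10, -1))
})

test_that("drift tracks are validated against the registration caps", {
  bad <- matrix(0L, 3, 3); bad[2, 2] <- 11L
  expect_error(synthetic_spec(n_frames = 3, drift_track = bad), "caps")
  bad2 <- matrix(0L, 3, 3); bad2[1, 3] <- 1L
  expect_error(synthetic_spec(n_frames = 3, drift_track = bad2), "frame 1")
  big_z <- matrix(0L, 3, 3); big_z[3, 1] <- 50L  # z cap is 90: allowed
  expect_silent(synthetic_spec(n_frames = 3, drift_track = big_z))
  expect_error(synthetic_spec(n_frames = 5, drift_track = big_z),
               "n_frames x 3")
})

test_that("patch truth is exact arithmetic and additive", {
  one <- synthetic_spec(patches = list(planted_patch(20, 20, 10, 10, 50)),
                        n_frames = 3, seed = 1)
  tr <- make_patch_series(one)$truth
  expect_equal(tr$integrated_per_frame, rep(5000, 3))
  zero <- synthetic_spec(patches = list(), n_frames = 2, seed = 1)
  expect_equal(make_patch_series(zero)$truth$integrated_per_frame, c(0, 0))
  two <- synthetic_spec(patches = list(planted_patch(20, 20, 10, 10, 50),
                                       planted_patch(70, 80, 8, 12, 30)),
                        n_frames = 2, seed = 1)
  expect_equal(make_patch_series(two)$truth$integrated_per_frame[1],
               5000 + 8 * 12 * 30)
})

test_that("measured focus means land on the calibration targets", {
  spec <- scmf_spec(foci = list(planted_focus(2500)), n_frames = 2, seed = 7)
  gen <- make_scmf_movie(spec)
  res <- analyze_scmf(gen$movie, drift = FALSE, frames = 1L)
  expect_equal(nrow(res$foci), 1)
  expect_equal(res$foci$mean_intensity, 2500, tolerance = 0.05)
  expect_equal(as.character(res$foci$scmf_class), "medium")
})
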