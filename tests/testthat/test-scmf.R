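# filter chains, masks, detection, classification, tracking and drift
# correction of the sub-cortical foci pipeline

test_that("H2B expansion preserves constants, expands support, is monotone", {
  u <- matrix(7, 30, 30)
  expect_equal(filter_h2b(u)[, , 1], u, tolerance = 1e-8)
  # a compact blob (large enough to survive the median) gains support
  pt <- matrix(0, 61, 61)
  pt[(row(pt) - 31)^2 + (col(pt) - 31)^2 <= 36] <- 1000
  out <- filter_h2b(pt)[, , 1]
  expect_gt(sum(out > 1e-6), sum(pt > 0))
  set.seed(11)
  for (i in 1:5) {
    a <- matrix(runif(15 * 15, 0, 100), 15, 15)
    b <- a; idx <- sample(length(b), 1); b[idx] <- b[idx] + 50
    expect_true(all(filter_h2b(b)[, , 1] - filter_h2b(a)[, , 1] >= -1e-8))
  }
})

test_that("tubulin isolation removes flat background and keeps bright spots", {
  u <- matrix(123, 50, 50)
  expect_true(all(filter_tubulin(u) == 0))
  img <- matrix(40, 60, 60)
  img[30:37, 30:37] <- 4000
  iso <- filter_tubulin(img)[, , 1]
  expect_gt(iso[33, 33], 3000)
  expect_lt(max(iso[1:20, 1:20]), 1)
  # adding a constant offset leaves the output unchanged
  iso2 <- filter_tubulin(img + 500)[, , 1]
  expect_equal(iso2, iso, tolerance = 1e-8)
})

test_that("classifier boundaries are inclusive for medium", {
  expect_equal(as.character(classify_scmf(c(1000, 2302, 2303, 2999, 3000, 5000))),
               c("weak", "weak", "medium", "medium", "strong", "strong"))
  expect_error(classify_scmf(-5), "negative")
  # configurable thresholds
  expect_equal(as.character(classify_scmf(10, thresholds = c(5, 20))), "medium")
})

test_that("oocyte mask applies the voxel size filter", {
  big <- array(0, c(86, 86, 34))
  rows <- matrix(seq_len(86), 86, 86)
  cols <- matrix(seq_len(86), 86, 86, byrow = TRUE)
  for (z in 1:34)
    big[, , z] <- 1000 * (((z - 17.5) / 16)^2 + ((rows - 43) / 40)^2 +
                          ((cols - 43) / 40)^2 <= 1)
  expect_gt(sum(big > 0), 1e5)
  mask <- make_oocyte_mask(big, min_voxels = 6.34e4)
  expect_gt(sum(mask), 6.34e4)
  small <- array(0, c(40, 40, 12))
  small[10:30, 10:30, 4:9] <- 1000    # ~2.6e3 voxels
  expect_error(make_oocyte_mask(small, min_voxels = 6.34e4), "size filter")
  # two components, only the large one passes
  both <- big
  both[1:4, 1:4, 1:4] <- 1000
  m2 <- make_oocyte_mask(both, min_voxels = 6.34e4)
  expect_false(any(m2[1:4, 1:4, 1:4]))
  expect_true(any(m2))
})

test_that("spindle mask is the tubulin component contiguous with chromosomes", {
  iso <- array(0, c(50, 50, 5))
  iso[20:30, 10:25, 2:4] <- 500    # spindle blob
  iso[5:9, 40:44, 2] <- 500        # distant focus
  chrom <- array(FALSE, c(50, 50, 5))
  chrom[22:28, 8:15, 2:4] <- TRUE  # overlaps the spindle blob only
  sp <- make_spindle_mask(iso, chrom)
  expect_true(sp[25, 20, 3])
  expect_false(any(sp[5:9, 40:44, ]))
  none <- make_spindle_mask(iso, array(FALSE, c(50, 50, 5)))
  expect_false(any(none))
  # containment in the oocyte mask
  oo <- array(FALSE, c(50, 50, 5)); oo[15:35, 5:30, ] <- TRUE
  sp2 <- make_spindle_mask(iso, chrom, oo)
  expect_true(all(which(sp2) %in% which(oo)))
})

test_that("detection cutoff, exclusion masks and spindle distance apply", {
  d <- c(90, 90, 5)
  iso <- array(0, d)
  raw <- array(0, d)
  centers <- list(c(15, 15), c(15, 45), c(15, 75), c(45, 15), c(75, 75))
  dim2 <- function(ctr, r) {
    m <- matrix(FALSE, d[1], d[2])
    m[(row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= r^2] <- TRUE
    m
  }
  for (ctr in centers) { pl <- iso[, , 3]; pl[dim2(ctr, 5)] <- 200; iso[, , 3] <- pl }
  for (ctr in list(c(45, 45), c(45, 75))) {  # below-cutoff foci
    pl <- iso[, , 3]; pl[dim2(ctr, 5)] <- 100; iso[, , 3] <- pl
  }
  raw <- iso * 10
  oo <- array(TRUE, d)
  foci <- detect_scmf(iso, raw, oo)
  expect_equal(nrow(foci), 5)
  expect_true(all(foci$n_voxels >= 1))
  # monotonicity: raising the cutoff never increases the count
  expect_lte(nrow(detect_scmf(iso, raw, oo, cutoff = 300)), 5)
  # h2b exclusion swallows one focus
  h2b <- array(FALSE, d); h2b[1:30, 1:30, ] <- TRUE
  foci2 <- detect_scmf(iso, raw, oo, h2b_mask = h2b)
  expect_equal(nrow(foci2), 4)
  # spindle proximity: a mask touching one focus removes it
  sp <- array(FALSE, d); sp[70:80, 70:80, 3] <- TRUE
  foci3 <- detect_scmf(iso, raw, oo, spindle_mask = sp)
  expect_equal(nrow(foci3), 4)
  expect_true(all(foci3$dist_spindle_um > 0.1))
})

test_that("tracking links stationary foci, splits jumps, bridges gaps", {
  mk <- function(frame, cy, cx) data.frame(frame = frame, cz = 1, cy = cy,
                                           cx = cx)
  still <- do.call(rbind, lapply(1:10, function(f) mk(f, 40, 40)))
  tr <- track_scmf(still)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  # a jump beyond 5 um (= 34 px at 0.1468 um/px) starts a new track
  jump <- rbind(mk(1, 10, 10), mk(2, 10, 80))
  expect_equal(length(unique(track_scmf(jump)$track_id)), 2)
  # a 2-frame disappearance is bridged (gap <= 3)
  gap <- rbind(mk(1, 20, 20), mk(4, 20, 22))
  expect_equal(length(unique(track_scmf(gap)$track_id)), 1)
  # beyond the gap limit: separate tracks
  far <- rbind(mk(1, 20, 20), mk(6, 20, 20))
  expect_equal(length(unique(track_scmf(far)$track_id)), 2)
})

test_that("per-bin counts average per-frame class counts and sum correctly", {
  foci <- do.call(rbind, lapply(2:10, function(f)
    data.frame(frame = f,
               scmf_class = factor(c("weak", "weak", "weak", "medium", "strong"),
                                   levels = c("weak", "medium", "strong")))))
  ct <- count_scmf(foci, t0 = 2, t_end = 10)
  expect_true(all(ct$per_bin$n_weak == 3))
  expect_true(all(ct$per_bin$n_medium == 1))
  expect_true(all(ct$per_bin$n_strong == 1))
  expect_true(all(ct$per_bin$n_total == 5))
  expect_equal(ct$per_frame$n_total,
               ct$per_frame$n_weak + ct$per_frame$n_medium + ct$per_frame$n_strong)
  empty <- count_scmf(foci[0, ], 2, 10)
  expect_true(all(empty$per_bin$n_total == 0))
})

test_that("drift correction recovers planted drift and is idempotent", {
  dr <- matrix(0L, 4, 3)
  dr[2, ] <- c(0L, 3L, 2L)
  dr[3, ] <- c(1L, -4L, 5L)
  dr[4, ] <- c(0L, 8L, -9L)
  spec <- scmf_spec(foci = list(planted_focus(1000), planted_focus(5000)),
                    n_frames = 4, drift_track = dr, seed = 5)
  gen <- make_scmf_movie(spec)
  dc <- drift_correct(gen$movie)
  # recovered offsets compensate the planted drift exactly
  expect_equal(as.matrix(dc$offsets[, c("dz", "dy", "dx")]),
               -dr, ignore_attr = TRUE)
  ref <- movie_volume(dc$movie, 1, "tubulin")
  for (t in 2:4)
    expect_identical(movie_volume(dc$movie, t, "tubulin"), ref)
  dc2 <- drift_correct(dc$movie)
  expect_true(all(as.matrix(dc2$offsets[, c("dz", "dy", "dx")]) == 0))
  # zero planted drift -> zero offsets
  spec0 <- scmf_spec(foci = list(planted_focus(1000)), n_frames = 2, seed = 5)
  gen0 <- make_scmf_movie(spec0)
  dc0 <- drift_correct(gen0$movie)
  expect_true(all(as.matrix(dc0$offsets[, c("dz", "dy", "dx")]) == 0))
})

test_that("featureless frames yield zero shift with a warning", {
  arr <- array(0, c(16, 16, 2, 1, 2))
  arr[4:6, 4:6, , , 1] <- 100
  m <- movie(arr, channel_roles = c(chromosomes = 1L))
  expect_warning(dc <- drift_correct(m, channel = 1L), "featureless")
  expect_true(all(as.matrix(dc$offsets[, c("dz", "dy", "dx")]) == 0))
})
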