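# contour/hull geometry: convex hull, point-line distance, distance
# profiles and 1-D peak detection

test_that("convex hull matches the brute-force oracle on random point sets", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    pts <- cbind(round(runif(n, 0, 100), 3), round(runif(n, 0, 100), 3))
    pts <- unique(pts)
    expect_setequal(sort(convex_hull_indices(pts)), brute_hull_vertices(pts))
  }
})

test_that("hull of a square with an interior point is the four corners", {
  pts <- cbind(c(0, 0, 4, 4, 2), c(0, 4, 0, 4, 2))
  expect_setequal(sort(convex_hull_indices(pts)), 1:4)
})

test_that("collinear input raises an error", {
  pts <- cbind(0:5, 0:5)
  expect_error(convex_hull_indices(pts), "collinear")
})

test_that("point-line distance equals the cross-product formula values", {
  expect_equal(point_line_distance(c(0, 0), c(4, 0), c(2, 3)), 3.0)
  expect_equal(point_line_distance(c(0, 0), c(4, 4), c(2, 2)), 0.0)
  expect_equal(point_line_distance(c(0, 0), c(3, 4), c(3, 0)), 2.4)
  expect_error(point_line_distance(c(1, 1), c(1, 1), c(0, 0)), "distinct")
})

test_that("cross-product distance agrees with a projection-formula oracle", {
  set.seed(7)
  for (i in 1:1000) {
    A <- runif(2, -50, 50); C <- runif(2, -50, 50); B <- runif(2, -50, 50)
    if (all(A == C)) next
    expect_equal(point_line_distance(A, C, B), projection_distance(A, C, B),
                 tolerance = 1e-9)
  }
})

test_that("distance profile of a convex contour is within tolerance of zero", {
  ct <- extract_contour(disk_mask(61, c(31, 31), 22))
  href <- hull_reference(ct)
  for (seg in href$segments) {
    prof <- distance_profile(href, seg)
    expect_true(all(prof$dist <= 1.0))
  }
})

test_that("V-notch depth is recovered in the distance profile", {
  # square with a triangular notch of depth 5 cut into the top edge
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  for (d in 0:4) m[10 + d, (20 - (4 - d)):(20 + (4 - d))] <- FALSE
  ct <- extract_contour(m)
  href <- hull_reference(ct)
  expect_gte(length(href$segments), 1)
  peak <- max(vapply(href$segments, function(s)
    max(c(0, distance_profile(href, s)$dist)), numeric(1)))
  expect_true(abs(peak - 5) <= 0.5)
})

test_that("distance profile is invariant under rigid rotation", {
  set.seed(3)
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  r <- 30 - 6 * exp(-((th - pi) / 0.2)^2)   # ring with one notch
  ct <- cbind(50 + r * sin(th), 50 + r * cos(th))
  depth_of <- function(ct) {
    href <- hull_reference(ct)
    max(vapply(href$segments, function(s)
      max(c(0, distance_profile(href, s)$dist)), numeric(1)))
  }
  a <- 30 * pi / 180
  rot <- cbind(50 + cos(a) * (ct[, 1] - 50) - sin(a) * (ct[, 2] - 50),
               50 + sin(a) * (ct[, 1] - 50) + cos(a) * (ct[, 2] - 50))
  expect_equal(depth_of(rot), depth_of(ct), tolerance = 1e-6)
})

test_that("find_peaks handles flat, single, multiple and shallow peaks", {
  expect_length(find_peaks(rep(0, 20)), 0)
  expect_equal(find_peaks(c(0, 1, 3, 5, 3, 1, 0)), 4L)
  two <- c(0, 2, 4, 2, 1, 2, 6, 2, 0)
  expect_equal(find_peaks(two), c(3L, 7L))
  # prominence gate: a 0.5-high wiggle on a shoulder is not a peak
  wig <- c(0, 3, 2.8, 3.1, 2.8, 5, 0)
  expect_equal(find_peaks(wig, min_prominence = 1), 6L)
})
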