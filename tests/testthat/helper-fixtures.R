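# shared fixtures and independent oracles, built in code at test time

# filled disk mask
disk_mask <- function(n, center, radius) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - center[1])^2 + (col(m) - center[2])^2 <= radius^2] <- TRUE
  m
}

# membrane-style ring image: bright band around a filled disk boundary
ring_image <- function(n, center, radius, thickness = 3, value = 3000) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rho <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  img <- matrix(0, n, n)
  img[abs(rho - radius) <= thickness / 2] <- value
  img
}

# brute-force convex hull oracle: a directed pair (a, b) is a hull edge iff
# every other point lies strictly on its left or on the segment; O(n^3)
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  is_vertex <- rep(FALSE, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ok <- TRUE
    for (c in seq_len(n)) {
      if (c == a || c == b) next
      cr <- (pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[a, 2]) -
            (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[a, 1])
      if (cr < 0) { ok <- FALSE; break }
      if (cr == 0) {
        # collinear: must lie within the segment ab
        d <- sum((pts[b, ] - pts[a, ])^2)
        tt <- sum((pts[c, ] - pts[a, ]) * (pts[b, ] - pts[a, ])) / d
        if (tt < 0 || tt > 1) { ok <- FALSE; break }
      }
    }
    if (ok) { is_vertex[a] <- TRUE; is_vertex[b] <- TRUE }
  }
  # drop points interior to a hull edge (collinear non-extreme points)
  v <- which(is_vertex)
  keep <- vapply(v, function(i) {
    others <- setdiff(v, i)
    for (a in others) for (b in others) {
      if (a == b) next
      cr <- (pts[b, 1] - pts[a, 1]) * (pts[i, 2] - pts[a, 2]) -
            (pts[b, 2] - pts[a, 2]) * (pts[i, 1] - pts[a, 1])
      if (abs(cr) > 1e-9) next
      d <- sum((pts[b, ] - pts[a, ])^2)
      tt <- sum((pts[i, ] - pts[a, ]) * (pts[b, ] - pts[a, ])) / d
      if (tt > 1e-9 && tt < 1 - 1e-9) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(v[keep])
}

# projection-formula distance oracle (independent of the cross-product path)
projection_distance <- function(A, C, B) {
  ac <- C - A
  t <- sum((B - A) * ac) / sum(ac^2)
  foot <- A + t * ac
  sqrt(sum((B - foot)^2))
}

# deterministic threshold fixtures; skimage (threshold_yen/threshold_triangle
# at integer binning) gives 123/129 and 64/67 on these exact samples
threshold_fixture <- function(which = 1) {
  set.seed(101)
  x1 <- round(pmax(c(rnorm(6000, 100, 10), rnorm(1500, 900, 50)), 0))
  x2 <- round(pmax(c(rnorm(7600, 50, 5), rnorm(400, 300, 30)), 0))
  if (which == 1) x1 else x2
}

# small movie whose chromosome-mask area follows a given radius schedule
schedule_movie <- function(radii, n = 64) {
  nt <- length(radii)
  arr <- array(0, dim = c(n, n, 1, 1, nt))
  for (t in seq_len(nt)) {
    if (radii[t] > 0) {
      m <- disk_mask(n, c(n / 2, n / 2), radii[t])
      pl <- matrix(0, n, n); pl[m] <- 3000
      arr[, , 1, 1, t] <- pl
    }
  }
  movie(arr, channel_roles = c(chromosomes = 1L))
}
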