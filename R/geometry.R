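#' Contour and convex-hull geometry
#'
#' The cortex of the oocyte is modelled as an ordered closed contour in one
#' focal plane; its convex hull provides the measurement reference for
#' furrow depth.  Measurements are made piece-wise between adjacent
#' contour/hull intersection points, transforming the 2-D boundary into a
#' 1-D profile of perpendicular distances to the hull chord.
#'
#' @name geometry
NULL

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

#' Convex hull of a point set (monotone chain)
#'
#' Returns the indices of the hull vertices in counter-clockwise order
#' (standard orientation, y up).  Collinear points on hull edges are not
#' vertices.
#'
#' @param pts n x 2 numeric matrix of (x, y) or (col, row) coordinates.
#' @return integer vector of row indices into `pts`, CCW.
#' @export
convex_hull_indices <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  u <- unique(pts)
  if (nrow(u) < 3) stop("convex hull requires at least 3 distinct points")
  # degenerate (all collinear)?
  o <- u[1, ]; spread <- FALSE
  for (k in 2:nrow(u)) {
    for (m in 2:nrow(u)) {
      if (abs(cross2(o, u[k, ], u[m, ])) > 1e-12) { spread <- TRUE; break }
    }
    if (spread) break
  }
  if (!spread) stop("convex hull undefined: points are collinear")
  ord <- order(pts[, 1], pts[, 2])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross2(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 1e-12)
        h <- h[-length(h)]
      # skip exact duplicates of the last point
      if (length(h) >= 1 && all(pts[h[length(h)], ] == pts[i, ])) next
      h <- c(h, i)
    }
    h
  }
  lower <- build(ord)
  upper <- build(rev(ord))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' Perpendicular distance from a point to a line
#'
#' Distance from point B to the infinite line through A and C, computed as
#' the length of the cross product of the vectors AB and AC normalised by
#' the length of AC.
#'
#' @param A,C two distinct points defining the line, numeric length-2.
#' @param B query point (or an n x 2 matrix of query points).
#' @return non-negative distance(s) in the units of the coordinates.
#' @export
point_line_distance <- function(A, C, B) {
  A <- as.numeric(A); C <- as.numeric(C)
  ac <- C - A
  nac <- sqrt(sum(ac^2))
  if (nac == 0) stop("A and C must be distinct points")
  if (is.matrix(B)) {
    ab1 <- B[, 1] - A[1]; ab2 <- B[, 2] - A[2]
    return(abs(ab1 * ac[2] - ab2 * ac[1]) / nac)
  }
  B <- as.numeric(B)
  ab <- B - A
  abs(ab[1] * ac[2] - ab[2] * ac[1]) / nac
}

point_segment_distance <- function(P, A, C) {
  # distance from P to the closed segment AC
  ac <- C - A
  L2 <- sum(ac^2)
  if (L2 == 0) return(sqrt(sum((P - A)^2)))
  t <- ((P[1] - A[1]) * ac[1] + (P[2] - A[2]) * ac[2]) / L2
  t <- min(1, max(0, t))
  q <- A + t * ac
  sqrt(sum((P - q)^2))
}

#' Hull reference for a closed contour
#'
#' Computes the convex hull of the contour, marks the contour points that
#' coincide with the hull boundary (within tolerance `eps`), and derives the
#' measurement segments: maximal runs of off-hull contour points bracketed
#' by the adjacent on-hull intersection points A and C.
#'
#' @param contour n x 2 matrix of ordered closed boundary points (row, col).
#' @param eps coincidence tolerance in pixels (default 0.5).
#' @return an object of class `hull_reference`: list with `hull_idx`
#'   (indices of hull vertices in `contour`), `on_hull` (logical per contour
#'   point), and `segments` (list of `list(a, c, interior)` index triples).
#' @export
hull_reference <- function(contour, eps = 0.5) {
  stopifnot(is.matrix(contour), ncol(contour) == 2, nrow(contour) >= 3)
  xy <- cbind(contour[, 2], -contour[, 1])  # x = col, y = -row (y up)
  hull_idx <- convex_hull_indices(xy)
  hv <- xy[hull_idx, , drop = FALSE]
  nh <- nrow(hv)
  n <- nrow(contour)
  # distance from each contour point to the hull polygon boundary
  dists <- rep(Inf, n)
  for (k in seq_len(nh)) {
    A <- hv[k, ]; C <- hv[if (k == nh) 1L else k + 1L, ]
    for (i in seq_len(n)) {
      d <- point_segment_distance(xy[i, ], A, C)
      if (d < dists[i]) dists[i] <- d
    }
  }
  on_hull <- dists <= eps
  if (!any(on_hull)) stop("no contour point lies on the convex hull")
  segments <- list()
  if (any(!on_hull)) {
    # walk the closed contour; each maximal run of off-hull points yields a
    # segment from the preceding on-hull point (A) to the following one (C)
    idx_on <- which(on_hull)
    i <- 1L
    visited <- rep(FALSE, n)
    for (start in which(!on_hull)) {
      if (visited[start]) next
      # expand the run around `start` cyclically
      a <- start
      repeat {
        prv <- if (a == 1L) n else a - 1L
        if (on_hull[prv] || prv == start) break
        a <- prv
      }
      b <- start
      repeat {
        nxt <- if (b == n) 1L else b + 1L
        if (on_hull[nxt] || nxt == start) break
        b <- nxt
      }
      run <- if (a <= b) a:b else c(a:n, 1:b)
      visited[run] <- TRUE
      A_idx <- if (a == 1L) n else a - 1L
      C_idx <- if (b == n) 1L else b + 1L
      if (!on_hull[A_idx] || !on_hull[C_idx]) next  # fully off-hull contour
      segments[[length(segments) + 1L]] <-
        list(a = A_idx, c = C_idx, interior = run)
    }
  }
  structure(list(contour = contour, hull_idx = hull_idx, on_hull = on_hull,
                 segments = segments, eps = eps),
            class = "hull_reference")
}

#' @export
print.hull_reference <- function(x, ...) {
  cat("<hull_reference>", nrow(x$contour), "contour points,",
      length(x$hull_idx), "hull vertices,",
      length(x$segments), "measurement segment(s)\n")
  invisible(x)
}

#' Distance profile of a measurement segment
#'
#' For each contour point strictly between the intersection points A and C
#' of one segment, the perpendicular distance to the chord AC.
#'
#' @param href a `hull_reference`.
#' @param segment one element of `href$segments`.
#' @return list with `indices` (contour indices) and `dist` (pixels).
#' @export
distance_profile <- function(href, segment) {
  contour <- href$contour
  A <- contour[segment$a, ]
  C <- contour[segment$c, ]
  idx <- segment$interior
  if (!length(idx)) return(list(indices = integer(0), dist = numeric(0)))
  d <- point_line_distance(A, C, contour[idx, , drop = FALSE])
  list(indices = idx, dist = as.numeric(d))
}

#' Local maxima of a 1-D profile with a prominence requirement
#'
#' Strict local maxima (plateaus contribute their centre point) whose
#' topographic prominence is at least `min_prominence`.
#'
#' @param y numeric profile.
#' @param min_prominence minimum prominence in the units of `y`.
#' @return integer vector of peak positions in `y`.
#' @export
find_peaks <- function(y, min_prominence = 1) {
  n <- length(y)
  if (n < 1) return(integer(0))
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1L
    left_ok <- (i == 1L) || (y[i - 1] < y[i])
    right_ok <- (j == n) || (y[j + 1] < y[i])
    # profile endpoints sit at the hull chord (depth ~ 0); treat interior
    # plateaus touching the ends as peaks only if they rise above both ends
    if (left_ok && right_ok && !(i == 1L && j == n)) {
      peaks <- c(peaks, as.integer(floor((i + j) / 2)))
    }
    i <- j + 1L
  }
  if (!length(peaks)) return(peaks)
  keep <- vapply(peaks, function(p) {
    h <- y[p]
    # walk left/right until a higher point; track the minimum on each side
    lmin <- h
    k <- p
    while (k > 1) {
      k <- k - 1L
      if (y[k] > h) break
      if (y[k] < lmin) lmin <- y[k]
    }
    if (y[k] <= h) lmin <- min(lmin, y[k])
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (y[k] > h) break
      if (y[k] < rmin) rmin <- y[k]
    }
    if (y[k] <= h) rmin <- min(rmin, y[k])
    (h - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  peaks[keep]
}
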