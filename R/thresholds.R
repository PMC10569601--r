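#' Automatic histogram thresholds
#'
#' Yen's maximum-correlation criterion and the Triangle geometric method,
#' computed on an integer-binned intensity histogram.  Both return a
#' threshold value on the intensity scale of the input; foreground is the
#' set of pixels strictly above the threshold is not assumed -- callers in
#' this package treat pixels `> threshold` as foreground.
#'
#' @name thresholds
NULL

intensity_histogram <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities to threshold")
  lo <- floor(min(x))
  hi <- ceiling(max(x))
  levels <- lo:hi
  counts <- tabulate(pmin(pmax(round(x) - lo + 1, 1L), length(levels)),
                     nbins = length(levels))
  list(levels = levels, counts = counts)
}

#' Yen automatic threshold
#'
#' Maximises Yen's maximum-correlation criterion over candidate split
#' points of the integer-binned histogram.  Degenerate (single-level)
#' inputs raise an error.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @return threshold on the intensity scale; pixels above it are foreground.
#' @export
threshold_yen <- function(x) {
  h <- intensity_histogram(x)
  counts <- h$counts
  if (sum(counts > 0) < 2) stop("cannot threshold: image has a single intensity level")
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  n <- length(p)
  # criterion over split after bin i (foreground = bins > i)
  i <- seq_len(n - 1)
  num <- P1[i] * (1 - P1[i])
  den <- P1sq[i] * P2sq[i]
  crit <- rep(-Inf, n - 1)
  ok <- den > 0 & num > 0
  crit[ok] <- log(num[ok]^2 / den[ok])
  h$levels[which.max(crit)]
}

#' Triangle automatic threshold
#'
#' Draws a line from the histogram peak to the far end of the histogram tail
#' and selects the level whose histogram point is farthest (perpendicular)
#' from that line.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @return threshold on the intensity scale; pixels above it are foreground.
#' @export
threshold_triangle <- function(x) {
  h <- intensity_histogram(x)
  counts <- as.numeric(h$counts)
  if (sum(counts > 0) < 2) stop("cannot threshold: image has a single intensity level")
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # use the longer tail from the peak
  if ((peak - lo) >= (hi - peak)) {
    a <- lo; b <- peak; flip <- TRUE
  } else {
    a <- peak; b <- hi; flip <- FALSE
  }
  if (a == b) return(h$levels[peak])
  # perpendicular distance of each histogram point to the peak-tail chord
  xs <- a:b
  x1 <- if (flip) b else a; y1 <- counts[x1]
  x2 <- if (flip) a else b; y2 <- counts[x2]
  dx <- x2 - x1; dy <- y2 - y1
  dist <- abs(dy * (xs - x1) - dx * (counts[xs] - y1)) / sqrt(dx^2 + dy^2)
  h$levels[xs[which.max(dist)]]
}
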