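#' Image filters
#'
#' Thin wrappers around the compiled rank, Gaussian, morphology and
#' background-modelling primitives used by the segmentation and foci
#' pipelines.  All operate on plain numeric matrices (2-D, row = y) or 3-D
#' arrays with dims (y, x, z).
#'
#' @name filters
NULL

#' Median filter with a small rectangular kernel
#'
#' The kernel is anchored at the pixel (the pixel is the top-left element of
#' the window), matching how even-sized footprints are anchored in common
#' image libraries.  Used with a 2x2 kernel to despeckle the membrane channel
#' before thresholding.
#'
#' @param img numeric matrix.
#' @param kh,kw kernel height and width in pixels.
#' @return filtered matrix of the same size.
#' @export
median_filter_rect <- function(img, kh = 2L, kw = 2L) {
  stopifnot(is.matrix(img), kh >= 1, kw >= 1)
  cpp_median_rect(img, as.integer(kh), as.integer(kw))
}

#' Disk rank filters (median / maximum / minimum)
#'
#' The footprint is the set of pixels whose centre distance is at most
#' `radius`; at the image border only the in-bounds part of the disk is used.
#'
#' @param img numeric matrix.
#' @param radius disk radius in pixels.
#' @return filtered matrix.
#' @export
median_filter_disk <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_rank_disk(img, as.integer(radius), 0L)
}

#' @rdname median_filter_disk
#' @export
maximum_filter_disk <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_rank_disk(img, as.integer(radius), 1L)
}

#' @rdname median_filter_disk
#' @export
minimum_filter_disk <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_rank_disk(img, as.integer(radius), 2L)
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur (2-D or 3-D, separable, reflect boundary)
#'
#' @param img numeric matrix or 3-D array (y, x, z).
#' @param sigma standard deviation in pixels; for 3-D input either one value
#'   or a vector `c(y, x, z)` of per-axis sigmas (z in voxel units).
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (is.matrix(img)) {
    d <- c(dim(img), 1L)
    sigma <- rep_len(sigma, 2)
    arr <- array(img, dim = d)
    out <- cpp_conv3d_axis(arr, d, gaussian_kernel(sigma[1]), 1L)
    out <- cpp_conv3d_axis(out, d, gaussian_kernel(sigma[2]), 2L)
    return(matrix(out, dim(img)[1], dim(img)[2]))
  }
  stopifnot(length(dim(img)) == 3)
  d <- dim(img)
  sigma <- rep_len(sigma, 3)
  out <- as.numeric(img)
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      out <- cpp_conv3d_axis(out, d, gaussian_kernel(sigma[ax]), as.integer(ax))
    }
  }
  array(out, d)
}

#' Local outlier replacement (background modelling)
#'
#' Replaces a pixel by the median of its `(2*block_radius+1)^2` neighbourhood
#' when it deviates from that median by more than `sd_factor` local standard
#' deviations.  Bright puncta are flattened to the local background while
#' smooth structure passes through, so the result can serve as a background
#' model to subtract from the original.
#'
#' @param img numeric matrix.
#' @param block_radius half-width of the square block in pixels.
#' @param sd_factor deviation threshold in units of the local SD.
#' @return matrix with outliers replaced.
#' @export
remove_outliers <- function(img, block_radius = 20L, sd_factor = 0.90) {
  stopifnot(is.matrix(img), block_radius >= 1, sd_factor >= 0)
  cpp_remove_outliers(img, as.integer(block_radius), sd_factor)
}

#' Rolling-ball background estimate (2-D)
#'
#' Grayscale opening with a ball-height structuring element: the background
#' is the upper envelope of a ball of the given radius rolled under the
#' intensity surface.  Subtract the result from the image to remove smooth
#' background while keeping objects smaller than the ball.
#'
#' @param img numeric matrix.
#' @param radius ball radius in pixels.
#' @return background matrix (same size).
#' @export
rolling_ball_background <- function(img, radius = 20L) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_rolling_ball(img, as.integer(radius))
}

#' Flat morphological opening of a 3-D array with a box structuring element
#'
#' Used as the large-scale ("sphere of diameter d") background model in the
#' foci pipeline: erosion then dilation with a box whose half-widths are
#' given per axis in voxels.  Structures smaller than the box are removed
#' from the background estimate.
#'
#' @param arr 3-D numeric array (y, x, z).
#' @param half_width integer vector `c(y, x, z)` of box half-widths (voxels).
#' @return background array of the same shape.
#' @export
box_open_background <- function(arr, half_width) {
  stopifnot(length(dim(arr)) == 3, length(half_width) == 3)
  d <- dim(arr)
  hw <- as.integer(half_width)
  ero <- cpp_morph3d_rect(as.numeric(arr), d, hw[1], hw[2], hw[3], 2L)
  dil <- cpp_morph3d_rect(ero, d, hw[1], hw[2], hw[3], 1L)
  array(dil, d)
}

#' Binary dilation by one pixel (8-connected) of a 2-D mask
#' @param mask logical matrix.
#' @return dilated logical matrix.
#' @export
dilate1 <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  maximum_filter_disk(m, 1L) > 0
}

#' Connected-component labelling
#'
#' @param mask logical matrix (2-D) or 3-D logical array.
#' @param connectivity 4 or 8 for 2-D; 6 or 26 for 3-D.
#' @return integer label array, 0 = background; attribute `n_labels`.
#' @export
label_components <- function(mask, connectivity = if (is.matrix(mask)) 8L else 26L) {
  if (is.matrix(mask)) {
    m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
    lab <- cpp_label2d(m, as.integer(connectivity))
    attr(lab, "n_labels") <- max(lab)
    return(lab)
  }
  stopifnot(length(dim(mask)) == 3)
  cpp_label3d(as.integer(mask), dim(mask), as.integer(connectivity))
}
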