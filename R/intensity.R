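#' Patch and microtubule intensity quantification
#'
#' Threshold-based integrated-intensity measurements of sub-cortical
#' kinetochore-protein patches and of microtubule levels, 0-100
#' normalization across conditions, percent depletion, and the relative
#' standard deviation texture metric.
#'
#' @name intensity_metrics
NULL

#' Integrated patch intensity over a window of timepoints
#'
#' Per timepoint: maximum intensity z-projection, median filter (disk
#' radius 3), rolling-ball background subtraction (radius 20), Triangle
#' threshold within the ROI, and the sum of intensity over
#' threshold-passing particles; particles overlapping the chromosome mask
#' are excluded (chromosome-associated signal subtraction).  The returned
#' value is the sum over the window.
#'
#' @param m a `cq_movie`; the measured channel needs a role (see
#'   `channel`).
#' @param roi_mask logical (y, x) matrix, or (y, x, t)-indexed list of
#'   matrices; the oocyte region of interest.
#' @param timepoints integer vector of frame indices; the default window is
#'   5 frames starting 200 s before anaphase onset at a 10 s interval.
#' @param channel measured channel role or index (default `"patch"` if
#'   present, else `"tubulin"`).
#' @param chrom_exclude exclude particles overlapping the thresholded
#'   chromosome projection (default TRUE when a `chromosomes` role exists).
#' @param median_radius,ball_radius filter parameters in pixels.
#' @return list with `total` (integrated sum over the window) and
#'   `per_frame` data.frame.
#' @export
patch_intensity <- function(m, roi_mask, timepoints,
                            channel = NULL, chrom_exclude = NULL,
                            median_radius = 3L, ball_radius = 20L) {
  stopifnot(inherits(m, "cq_movie"))
  d <- movie_dim(m)
  if (is.null(channel)) {
    channel <- if ("patch" %in% names(m$channel_roles)) "patch" else "tubulin"
  }
  if (is.null(chrom_exclude))
    chrom_exclude <- "chromosomes" %in% names(m$channel_roles)
  if (any(timepoints < 1 | timepoints > d[["t"]]))
    stop("timepoints outside the movie")
  get_roi <- function(t) {
    r <- if (is.list(roi_mask)) roi_mask[[t]] else roi_mask
    if (!any(r)) stop("empty ROI")
    r
  }
  per <- vapply(timepoints, function(t) {
    mip <- project_max(m, t, channel, "all")
    f <- median_filter_disk(mip, median_radius)
    f <- f - rolling_ball_background(f, ball_radius)
    f[f < 0] <- 0
    roi <- get_roi(t)
    vals <- f[roi]
    thr <- tryCatch(threshold_triangle(vals), error = function(e) NA_real_)
    if (is.na(thr)) return(0)
    fg <- f > thr & roi
    if (!any(fg)) return(0)
    lab <- label_components(fg, 8L)
    drop <- integer(0)
    if (chrom_exclude) {
      cm <- chromosome_objects(movie_volume(m, t, "chromosomes"))
      drop <- unique(lab[cm & lab > 0])
    }
    keep <- lab > 0 & !(lab %in% drop)
    sum(f[keep])
  }, numeric(1))
  list(total = sum(per),
       per_frame = data.frame(frame = timepoints, integrated = per))
}

#' Default patch-quantification window
#'
#' Five frames starting 200 s before anaphase onset (10 s interval):
#' -200, -190, -180, -170, -160 s.
#'
#' @param t0 anaphase onset frame (1-based).
#' @param frame_interval_s frame interval.
#' @param n_timepoints number of frames in the window.
#' @param start_offset_s offset of the first frame relative to onset.
#' @return integer frame vector.
#' @export
patch_window <- function(t0, frame_interval_s = 10, n_timepoints = 5L,
                         start_offset_s = -200) {
  start <- t0 + round(start_offset_s / frame_interval_s)
  as.integer(seq.int(start, length.out = n_timepoints))
}

#' Microtubule-level quantification (16-timepoint window)
#'
#' Identical procedure to [patch_intensity()] with a 16-frame window, used
#' for drug-treated oocytes with more variable microtubule levels.
#'
#' @inheritParams patch_intensity
#' @param n_timepoints window length (default 16).
#' @param start first frame of the window.
#' @export
microtubule_level <- function(m, roi_mask, start = 1L, n_timepoints = 16L,
                              channel = NULL, chrom_exclude = NULL) {
  d <- movie_dim(m)
  tp <- seq.int(start, length.out = n_timepoints)
  if (max(tp) > d[["t"]])
    stop("movie has fewer frames than the requested window")
  patch_intensity(m, roi_mask, tp, channel = channel,
                  chrom_exclude = chrom_exclude)
}

#' Normalize values onto a 0-100 scale within a group
#'
#' `z_i = (x_i - min(x)) / (max(x) - min(x)) * 100`: the group minimum maps
#' to 0 and the group maximum to 100.
#'
#' @param x numeric vector with at least two distinct values.
#' @return numeric vector of normalized scores in [0, 100].
#' @export
normalize_scores <- function(x) {
  stopifnot(length(x) >= 2)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate group: max equals min")
  (x - rng[1]) / (rng[2] - rng[1]) * 100
}

#' Percent depletion from a normalized score
#'
#' Reported as the magnitude `100 - z`: a score at the group maximum is 0%
#' depleted, a score at the minimum 100%.
#'
#' @param z normalized scores in [0, 100].
#' @return percent depletion in [0, 100].
#' @export
percent_depletion <- function(z) {
  if (any(z < 0 | z > 100)) stop("normalized scores must lie in [0, 100]")
  100 - z
}

#' Relative standard deviation of pixel intensity
#'
#' Sample SD divided by the mean over ROI pixels outside an exclusion
#' circle (default radius 80 px = 11.75 um, centred on the spindle),
#' typically computed on the maximum projection of the five surface-most
#' focal planes 10 s after anaphase-B onset.
#'
#' @param mip_image 2-D numeric matrix.
#' @param roi_mask logical matrix (oocyte ROI).
#' @param center exclusion-circle centre, `c(row, col)`; `NULL` for no
#'   exclusion.
#' @param radius_px exclusion radius in pixels.
#' @return list with `mean`, `sd` (sample, n-1), `rsd`, `n_pixels`.
#' @export
relative_sd <- function(mip_image, roi_mask = NULL, center = NULL,
                        radius_px = 80) {
  stopifnot(is.matrix(mip_image))
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(mip_image), ncol(mip_image))
  sel <- roi_mask
  if (!is.null(center)) {
    rows <- matrix(seq_len(nrow(mip_image)), nrow(mip_image), ncol(mip_image))
    cols <- matrix(seq_len(ncol(mip_image)), nrow(mip_image), ncol(mip_image),
                   byrow = TRUE)
    sel <- sel & ((rows - center[1])^2 + (cols - center[2])^2 > radius_px^2)
  }
  vals <- mip_image[sel]
  if (length(vals) < 2) stop("fewer than 2 pixels in the measurement region")
  mu <- mean(vals)
  if (mu == 0) stop("zero mean intensity: RSD undefined")
  s <- stats::sd(vals)
  list(mean = mu, sd = s, rsd = s / mu, n_pixels = length(vals))
}
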