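#' Cortical membrane ingression analysis
#'
#' Measures local inward deformations (furrows) of the oocyte plasma
#' membrane in a single central focal plane.  The cortex is segmented from
#' the membrane channel, modelled as a closed contour, and compared against
#' its convex hull: piece-wise between adjacent contour/hull intersection
#' points, the perpendicular distance from the contour to the hull chord is
#' profiled, and profile peaks deeper than the recording threshold are
#' recorded as ingression events.  Events near the chromosome mass
#' (spindle-associated) are flagged and excluded from summaries, events are
#' filtered to a minimum physical length, and summaries are reported over
#' four equal bins of normalized anaphase-B time.
#'
#' @name ingression
NULL

#' Segment the oocyte interior from a membrane-channel image
#'
#' Median filter (2x2 kernel), Yen automatic threshold, 1-pixel dilation of
#' the binary cortex, inversion, and removal of the object touching the
#' image border.  The returned interior keeps narrow deep furrows open so
#' the contour model can capture their full extent.
#'
#' @param frame_image 2-D numeric matrix (membrane channel, oocyte not
#'   touching the image border).
#' @param min_area minimum interior object area in pixels.
#' @return logical matrix: the oocyte interior.
#' @export
segment_cortex <- function(frame_image, min_area = 50L) {
  stopifnot(is.matrix(frame_image))
  sm <- median_filter_rect(frame_image, 2L, 2L)
  thr <- threshold_yen(sm)
  cortex <- sm > thr
  if (!any(cortex)) stop("segmentation failed: no cortex signal above threshold")
  inv <- !dilate1(cortex)
  lab <- label_components(inv, 8L)
  if (max(lab) == 0) stop("segmentation failed: no interior object")
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  interior_labels <- setdiff(which(sizes >= min_area), border_labels)
  if (length(interior_labels) == 0)
    stop("segmentation failed: no interior object above minimum area")
  if (length(interior_labels) > 1)
    stop("segmentation failed: multiple interior objects above minimum area")
  lab == interior_labels
}

#' Extract the ordered closed boundary of a mask as a contour
#'
#' @param mask logical matrix containing one connected object.
#' @param min_area minimum object area in pixels.
#' @return n x 2 integer matrix of (row, col) boundary points, ordered
#'   counter-clockwise, closed (last point adjacent to first).
#' @export
extract_contour <- function(mask, min_area = 10L) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  lab <- cpp_label2d(m, 8L)
  nlab <- max(lab)
  if (nlab == 0) stop("empty mask")
  if (nlab > 1) stop("mask is disconnected: ", nlab, " objects")
  if (sum(m) < min_area) stop("object below minimum area")
  cpp_trace_boundary(m)
}

#' Convex hull reference of a contour
#'
#' Convenience wrapper: see [hull_reference()].
#' @param contour n x 2 matrix of (row, col) points.
#' @param eps hull/contour coincidence tolerance in pixels.
#' @export
convex_hull <- function(contour, eps = 0.5) hull_reference(contour, eps)

#' Detect ingression events from segment distance profiles
#'
#' Local profile maxima (prominence at least `min_prominence` px) whose
#' depth exceeds `min_record_px` pixels are recorded as events; several
#' peaks per segment are allowed.
#'
#' @param href a `hull_reference` for one frame.
#' @param pixel_size_um lateral calibration.
#' @param min_record_px recording threshold in pixels (strictly greater).
#' @param min_prominence peak prominence in pixels.
#' @param frame frame index stored on the events.
#' @return data.frame with one row per event: `frame`, `contour_index`,
#'   `row`, `col`, `length_px`, `length_um`, `seg_a`, `seg_c`,
#'   `spindle_associated` (initialised `FALSE`).
#' @export
find_ingressions <- function(href, pixel_size_um = default_pixel_size(),
                             min_record_px = 3, min_prominence = 1,
                             frame = 1L) {
  stopifnot(inherits(href, "hull_reference"))
  out <- list()
  for (seg in href$segments) {
    prof <- distance_profile(href, seg)
    if (!length(prof$dist)) next
    pk <- find_peaks(prof$dist, min_prominence = min_prominence)
    pk <- pk[prof$dist[pk] > min_record_px]
    for (p in pk) {
      ci <- prof$indices[p]
      out[[length(out) + 1L]] <- data.frame(
        frame = as.integer(frame),
        contour_index = ci,
        row = href$contour[ci, 1],
        col = href$contour[ci, 2],
        length_px = prof$dist[p],
        length_um = prof$dist[p] * pixel_size_um,
        seg_a = seg$a, seg_c = seg$c,
        spindle_associated = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), contour_index = integer(0),
                      row = integer(0), col = integer(0),
                      length_px = numeric(0), length_um = numeric(0),
                      seg_a = integer(0), seg_c = integer(0),
                      spindle_associated = logical(0)))
  }
  do.call(rbind, out)
}

#' Chromosome object mask from the chromosome channel
#'
#' Yen threshold of the maximum intensity projection along z.  An all-empty
#' mask is allowed (no signal; no spindle exclusion will be applied).
#'
#' @param chrom_volume (y, x, z) array of the chromosome channel at one
#'   frame, or a 2-D matrix already projected.
#' @return logical matrix of chromosome object pixels.
#' @export
chromosome_objects <- function(chrom_volume) {
  mip <- if (is.matrix(chrom_volume)) chrom_volume else {
    out <- chrom_volume[, , 1]
    if (dim(chrom_volume)[3] > 1)
      for (z in 2:dim(chrom_volume)[3]) out <- pmax(out, chrom_volume[, , z])
    out
  }
  thr <- tryCatch(threshold_yen(mip), error = function(e) NA_real_)
  if (is.na(thr)) return(matrix(FALSE, nrow(mip), ncol(mip)))
  mip > thr
}

#' Flag spindle-associated ingression events
#'
#' An event is flagged when the Euclidean distance from its peak point to
#' the nearest chromosome-object pixel (object edge) is at most `radius_px`.
#'
#' @param events event data.frame from [find_ingressions()].
#' @param chrom_mask logical chromosome mask for the same frame.
#' @param radius_px exclusion radius in pixels (default 22 = 3.23 um at the
#'   default calibration).
#' @return `events` with `spindle_associated` set.
#' @export
flag_spindle_associated <- function(events, chrom_mask, radius_px = 22) {
  if (!nrow(events) || !any(chrom_mask)) return(events)
  obj <- which(chrom_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(events))) {
    d2 <- (obj[, 1] - events$row[i])^2 + (obj[, 2] - events$col[i])^2
    events$spindle_associated[i] <- min(d2) <= radius_px^2
  }
  events
}

#' Keep events at or above a minimum physical length
#'
#' The kept set is `length_um >= min_um` (inclusive).
#'
#' @param events event data.frame.
#' @param min_um minimum length in micrometres.
#' @export
filter_min_length <- function(events, min_um = 1.0) {
  events[events$length_um >= min_um, , drop = FALSE]
}

chromosome_area_series <- function(m) {
  d <- movie_dim(m)
  vapply(seq_len(d[["t"]]), function(t) {
    sum(chromosome_objects(movie_volume(m, t, "chromosomes")))
  }, numeric(1))
}

#' Anaphase-B onset: frame of maximal chromosome-mass compaction
#'
#' The onset is the frame minimising the area of the Yen-thresholded
#' maximum-intensity-projected chromosome mask; ties break to the earliest
#' frame.
#'
#' @param m a `cq_movie` with a `chromosomes` channel role.
#' @return frame index (1-based).
#' @export
detect_anaphase_onset <- function(m) {
  areas <- chromosome_area_series(m)
  if (all(areas == 0)) stop("no chromosome signal in any frame")
  which.min(areas)
}

#' End of anaphase B / meiosis I: first decondensation frame
#'
#' First frame after onset where the chromosome mask area exceeds
#' `factor` times its minimum for at least `persist` consecutive frames
#' (decondensation).  Falls back to the last frame when no such frame
#' exists.
#'
#' @param m a `cq_movie`.
#' @param t0 onset frame (default: detected).
#' @param factor area expansion factor relative to the minimum.
#' @param persist number of consecutive frames required.
#' @return frame index.
#' @export
detect_anaphase_end <- function(m, t0 = detect_anaphase_onset(m),
                                factor = 1.5, persist = 2L) {
  areas <- chromosome_area_series(m)
  n <- length(areas)
  amin <- areas[t0]
  if (t0 >= n) return(n)
  above <- areas > factor * amin
  for (t in (t0 + 1):n) {
    idx <- t:min(n, t + persist - 1L)
    if (length(idx) >= persist && all(above[idx])) return(t)
  }
  n
}

#' Map event frames to normalized anaphase-B bins
#'
#' The interval `[t0, t_end]` (frames) is divided into `n_bins` equal
#' parts; bins are half-open `[a, b)` with the last bin closed so an event
#' exactly at `t_end` falls in the final bin.  Events outside the interval
#' are dropped with a warning.
#'
#' @param events event data.frame with a `frame` column.
#' @param t0,t_end onset and end frames (t0 < t_end).
#' @param n_bins number of bins (default 4).
#' @return `events` with an integer `bin` column.
#' @export
normalize_anaphase_time <- function(events, t0, t_end, n_bins = 4L) {
  stopifnot(t0 < t_end)
  frac <- (events$frame - t0) / (t_end - t0)
  bin <- ifelse(frac >= 1, n_bins, floor(frac * n_bins) + 1L)
  outside <- frac < 0 | frac > 1
  if (any(outside)) {
    warning(sum(outside), " event(s) outside the anaphase window were dropped")
    events <- events[!outside, , drop = FALSE]
    bin <- bin[!outside]
  }
  events$bin <- as.integer(bin)
  events
}

#' Summarise ingression events per oocyte and normalized-time bin
#'
#' Per oocyte-bin: mean length, summed length, and event count over events
#' that passed the minimum-length filter and are not spindle-associated.
#' Per condition-bin: the mean across oocytes.  Bins with zero events
#' contribute sum 0 and count 0; their undefined per-oocyte mean length is
#' omitted from the cross-oocyte average rather than imputed as zero.
#'
#' @param events event data.frame with columns `oocyte`, `bin`,
#'   `length_um`, `spindle_associated`.
#' @param n_bins number of normalized-time bins.
#' @return list with `per_oocyte` and `per_bin` data.frames.
#' @export
summarize_ingressions <- function(events, n_bins = 4L) {
  stopifnot(all(c("oocyte", "bin", "length_um", "spindle_associated") %in%
                names(events)))
  if (!nrow(events)) {
    empty <- data.frame(oocyte = character(0), bin = integer(0),
                        mean_length_um = numeric(0), sum_length_um = numeric(0),
                        n_ingressions = integer(0))
    return(list(per_oocyte = empty,
                per_bin = data.frame(bin = seq_len(n_bins),
                                     mean_length_um = NA_real_,
                                     mean_sum_um = 0, mean_count = 0,
                                     n_oocytes = 0L)))
  }
  use <- events[!events$spindle_associated, , drop = FALSE]
  oocytes <- unique(events$oocyte)
  grid <- expand.grid(oocyte = oocytes, bin = seq_len(n_bins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- use$oocyte == grid$oocyte[i] & use$bin == grid$bin[i]
    len <- use$length_um[sel]
    data.frame(oocyte = grid$oocyte[i], bin = grid$bin[i],
               mean_length_um = if (length(len)) mean(len) else NA_real_,
               sum_length_um = sum(len),
               n_ingressions = length(len))
  })
  per_oocyte <- do.call(rbind, per)
  per_bin <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sub <- per_oocyte[per_oocyte$bin == b, , drop = FALSE]
    data.frame(bin = b,
               mean_length_um = if (any(!is.na(sub$mean_length_um)))
                 mean(sub$mean_length_um, na.rm = TRUE) else NA_real_,
               mean_sum_um = mean(sub$sum_length_um),
               mean_count = mean(sub$n_ingressions),
               n_oocytes = nrow(sub))
  }))
  list(per_oocyte = per_oocyte, per_bin = per_bin)
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Thin delegation to the standard rank-sum routine (normal approximation
#' with continuity correction in the presence of ties).
#'
#' @param values_a,values_b numeric samples (each non-empty).
#' @return two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  stats::wilcox.test(values_a, values_b, exact = FALSE)$p.value
}

#' Select the focal plane with the strongest membrane ring contrast
#'
#' Default central-plane rule: the z index maximising the standard
#' deviation of the membrane channel at the first frame (the bright closed
#' ring has the highest contrast where the section is equatorial).
#'
#' @param m a `cq_movie` with a `membrane` channel role.
#' @param frame frame used for the choice.
#' @return z index.
#' @export
select_central_plane <- function(m, frame = 1L) {
  vol <- movie_volume(m, frame, "membrane")
  contr <- apply(vol, 3, stats::sd)
  which.max(contr)
}

#' Run the full ingression pipeline on a movie
#'
#' Segments each frame's central plane, measures ingression events against
#' the convex hull, flags chromosome-proximal events, applies the minimum
#' length filter, and assigns normalized anaphase-B bins.
#'
#' @param m a `cq_movie` with `membrane` and `chromosomes` channel roles.
#' @param plane z index of the central plane or `"auto"`.
#' @param min_length_um minimum kept length in micrometres.
#' @param chrom_radius_px chromosome exclusion radius in pixels.
#' @param onset onset frame or `"auto"`.
#' @param t_end end frame or `"auto"`.
#' @param oocyte oocyte identifier stored on the events.
#' @param frames frames to analyse (default all).
#' @return list with `events` (all recorded events with flags and bins),
#'   `kept` (filtered, unflagged), `t0`, `t_end`, `plane`, and `summary`.
#' @export
analyze_ingressions <- function(m, plane = "auto", min_length_um = 1.0,
                                chrom_radius_px = 22, onset = "auto",
                                t_end = "auto", oocyte = "oocyte1",
                                frames = NULL) {
  stopifnot(inherits(m, "cq_movie"))
  d <- movie_dim(m)
  if (identical(plane, "auto")) plane <- select_central_plane(m)
  t0 <- if (identical(onset, "auto")) detect_anaphase_onset(m) else as.integer(onset)
  tE <- if (identical(t_end, "auto")) detect_anaphase_end(m, t0) else as.integer(t_end)
  if (is.null(frames)) frames <- seq_len(d[["t"]])
  evs <- list()
  for (t in frames) {
    img <- movie_volume(m, t, "membrane")[, , plane]
    interior <- segment_cortex(img)
    contour <- extract_contour(interior)
    href <- hull_reference(contour)
    ev <- find_ingressions(href, pixel_size_um = m$pixel_size_um, frame = t)
    if (nrow(ev)) {
      cm <- chromosome_objects(movie_volume(m, t, "chromosomes"))
      ev <- flag_spindle_associated(ev, cm, radius_px = chrom_radius_px)
    }
    evs[[length(evs) + 1L]] <- ev
  }
  events <- do.call(rbind, evs)
  events$oocyte <- rep(oocyte, nrow(events))
  events <- normalize_anaphase_time(events, t0, tE)
  kept <- filter_min_length(events[!events$spindle_associated, , drop = FALSE],
                            min_length_um)
  summary <- if (nrow(events)) {
    summarize_ingressions(filter_min_length(events, min_length_um))
  } else NULL
  list(events = events, kept = kept, t0 = t0, t_end = tE,
       plane = plane, summary = summary,
       anaphase_duration_s = (tE - t0) * m$frame_interval_s)
}
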