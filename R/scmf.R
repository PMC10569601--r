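#' Sub-cortical microtubule foci (sCMF) pipeline
#'
#' Detects punctate tubulin foci near the oocyte surface in 3-D, excludes
#' sperm/chromosome-adjacent and spindle-proximal signal, classifies each
#' focus as weak / medium / strong by its mean raw-channel intensity, links
#' foci across frames, and reports per-class counts over normalized
#' anaphase-B time.
#'
#' @name scmf
NULL

#' Expand the chromosome (H2B) channel for adjacency exclusion
#'
#' Median (disk radius 5), Gaussian blur (sigma 10 px) and maximum filter
#' (disk radius 5), applied per z plane.  The expansion grows the isolated
#' H2B signal to encompass adjacent tubulin signal so sperm- and
#' chromosome-associated foci can be excluded.
#'
#' @param vol (y, x, z) array of the raw chromosome channel at one frame.
#' @param median_radius,gauss_sigma,max_radius filter parameters in pixels.
#' @return filtered array of the same shape.
#' @export
filter_h2b <- function(vol, median_radius = 5L, gauss_sigma = 10,
                       max_radius = 5L) {
  if (is.matrix(vol)) vol <- array(vol, c(dim(vol), 1L))
  out <- vol
  for (z in seq_len(dim(vol)[3])) {
    pl <- median_filter_disk(vol[, , z], median_radius)
    pl <- gaussian_blur(pl, gauss_sigma)
    out[, , z] <- maximum_filter_disk(pl, max_radius)
  }
  out
}

#' Isolate locally strong tubulin signal
#'
#' Per z plane: the local-outlier-replacement result (block radius 20,
#' 0.90 SD) models the background, which is subtracted from the original
#' channel (clipped at zero); a median filter (disk radius 5) then removes
#' small or sparse residue.  The output contains the isolated, locally
#' strong signal: sCMFs, spindle and sperm-associated microtubules.
#'
#' @param vol (y, x, z) array of the raw tubulin channel at one frame.
#' @param block_radius,sd_factor outlier-replacement parameters.
#' @param median_radius radius of the final median filter.
#' @return array of the same shape.
#' @export
filter_tubulin <- function(vol, block_radius = 20L, sd_factor = 0.90,
                           median_radius = 5L) {
  if (is.matrix(vol)) vol <- array(vol, c(dim(vol), 1L))
  out <- vol
  for (z in seq_len(dim(vol)[3])) {
    bg <- remove_outliers(vol[, , z], block_radius, sd_factor)
    iso <- pmax(vol[, , z] - bg, 0)
    out[, , z] <- median_filter_disk(iso, median_radius)
  }
  out
}

roll3d <- function(arr, shift) {
  # integer circular-free shift with zero fill; shift = c(dy, dx, dz)
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- list()
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { src[[k]] <- 1:(d[k] - s); dst[[k]] <- (1 + s):d[k] }
    else        { src[[k]] <- (1 - s):d[k]; dst[[k]] <- 1:(d[k] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

xcorr_shift <- function(ref, img, max_shift) {
  # integer shift (dy, dx, dz) maximising circular cross-correlation,
  # searched within the per-axis caps
  d <- dim(ref)
  F1 <- stats::fft(ref)
  F2 <- stats::fft(img)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  offs <- function(n) { v <- 0:(n - 1); ifelse(v > n / 2, v - n, v) }
  oy <- offs(d[1]); ox <- offs(d[2]); oz <- offs(d[3])
  peak <- arrayInd(which.max(cc), d)
  best_global <- c(oy[peak[1]], ox[peak[2]], oz[peak[3]])
  oky <- abs(oy) <= max_shift[1]; okx <- abs(ox) <= max_shift[2]
  okz <- abs(oz) <= max_shift[3]
  sub <- cc[oky, okx, okz, drop = FALSE]
  p <- arrayInd(which.max(sub), dim(sub))
  best <- c(oy[oky][p[1]], ox[okx][p[2]], oz[okz][p[3]])
  list(shift = best, global = best_global)
}

#' Drift correction by cross-correlation against the first frame
#'
#' Estimates a per-frame integer translation of a registration channel
#' relative to frame 1 by 3-D cross-correlation, caps it at the stated
#' maxima per axis, and applies the compensating shift to every channel.
#' A drift estimate beyond a cap is clipped to the cap with a warning;
#' featureless (constant) frames get zero shift with a warning.
#'
#' @param m a `cq_movie`.
#' @param channel registration channel index or role (default: `tubulin`
#'   if present, else channel 1).
#' @param max_shift per-axis caps in pixels, order `c(x, y, z)`.
#' @return list with `movie` (registered) and `offsets` (data.frame of the
#'   applied shifts per frame, columns `frame`, `dz`, `dy`, `dx`).
#' @export
drift_correct <- function(m, channel = NULL,
                          max_shift = c(x = 10, y = 10, z = 90)) {
  stopifnot(inherits(m, "cq_movie"))
  d <- movie_dim(m)
  if (d[["t"]] < 2) stop("drift correction requires at least 2 frames")
  if (is.null(channel)) {
    channel <- if ("tubulin" %in% names(m$channel_roles)) "tubulin" else 1L
  }
  caps <- c(max_shift[["y"]], max_shift[["x"]], min(max_shift[["z"]], d[["z"]] - 1))
  ref <- movie_volume(m, 1L, channel)
  out <- m
  offsets <- data.frame(frame = seq_len(d[["t"]]), dz = 0L, dy = 0L, dx = 0L)
  for (t in 2:d[["t"]]) {
    img <- movie_volume(m, t, channel)
    if (stats::sd(img) == 0 || stats::sd(ref) == 0) {
      warning("featureless frame ", t, ": zero shift applied")
      next
    }
    est <- xcorr_shift(ref, img, caps)
    if (any(est$global != est$shift))
      warning("frame ", t, ": drift estimate beyond cap; clipped")
    sh <- est$shift  # (dy, dx, dz) to apply to the drifting frame
    offsets$dy[t] <- sh[1]; offsets$dx[t] <- sh[2]; offsets$dz[t] <- sh[3]
    if (any(sh != 0)) {
      for (cc in seq_len(d[["c"]])) {
        out$data[, , , cc, t] <- roll3d(m$data[, , , cc, t, drop = FALSE][, , , 1, 1], sh)
      }
    }
  }
  list(movie = out, offsets = offsets)
}

#' Oocyte mask from a segmentation channel
#'
#' Gaussian smoothing at a physical scale (default 0.294 um), absolute
#' threshold at half the mask amplitude, and retention of 26-connected
#' components of at least `min_voxels` voxels.
#'
#' @param vol (y, x, z) array: the mask/segmentation channel at one frame
#'   (non-zero inside the oocyte).
#' @param pixel_size_um,z_step_um calibration.
#' @param smooth_um smoothing scale in micrometres.
#' @param min_voxels component size filter (default 6.34e4 voxels).
#' @return logical (y, x, z) array.
#' @export
make_oocyte_mask <- function(vol, pixel_size_um = default_pixel_size(),
                             z_step_um = 1.0, smooth_um = 0.294,
                             min_voxels = 6.34e4) {
  if (is.matrix(vol)) vol <- array(vol, c(dim(vol), 1L))
  sig <- c(smooth_um / pixel_size_um, smooth_um / pixel_size_um,
           smooth_um / z_step_um)
  sm <- gaussian_blur(vol, sig)
  thr <- max(sm) / 2
  if (max(vol) == 0) stop("empty segmentation channel")
  mask <- sm > thr
  lab <- label_components(mask, 26L)
  nlab <- attr(lab, "n_labels")
  if (nlab == 0) stop("no oocyte component found")
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= min_voxels)
  if (!length(keep))
    stop("no component passes the ", format(min_voxels), "-voxel size filter")
  array(lab %in% keep, dim(vol))
}

#' Spindle mask: tubulin signal contiguous with the chromosome mass
#'
#' Thresholds the isolated tubulin channel at the detection cutoff and
#' returns the union of 26-connected components that overlap the expanded
#' chromosome mask, restricted to the oocyte.  An empty mask is allowed.
#'
#' @param tbb_isolated (y, x, z) isolated tubulin array at one frame.
#' @param chrom_mask logical (y, x, z) expanded chromosome mask.
#' @param oocyte_mask optional logical (y, x, z) oocyte mask.
#' @param cutoff absolute intensity cutoff.
#' @return logical (y, x, z) array.
#' @export
make_spindle_mask <- function(tbb_isolated, chrom_mask, oocyte_mask = NULL,
                              cutoff = 150) {
  mask <- tbb_isolated >= cutoff
  if (!is.null(oocyte_mask)) mask <- mask & oocyte_mask
  if (!any(mask) || !any(chrom_mask)) return(array(FALSE, dim(tbb_isolated)))
  lab <- label_components(mask, 26L)
  nlab <- attr(lab, "n_labels")
  touching <- unique(lab[chrom_mask & lab > 0])
  array(lab %in% touching, dim(tbb_isolated))
}

#' Classify sCMFs by mean raw intensity
#'
#' Weak below the first boundary, medium between the boundaries
#' (inclusive on both ends), strong above the second.
#'
#' @param mean_intensity numeric vector of mean raw-channel intensities.
#' @param thresholds length-2 numeric: class boundaries (default 2303 and
#'   2999, calibrated on control movies and reused for all genotypes).
#' @return factor with levels weak, medium, strong.
#' @export
classify_scmf <- function(mean_intensity, thresholds = c(2303, 2999)) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  if (any(mean_intensity < 0)) stop("negative mean intensity")
  cls <- ifelse(mean_intensity < thresholds[1], "weak",
         ifelse(mean_intensity <= thresholds[2], "medium", "strong"))
  factor(cls, levels = c("weak", "medium", "strong"))
}

#' Detect sub-cortical microtubule foci in one frame
#'
#' The isolated tubulin channel is Gaussian-smoothed at a physical scale
#' (default 0.294 um), a large-scale background (10 um) is subtracted, and
#' 26-connected components of voxels at or above the detection cutoff are
#' taken inside the oocyte mask and outside the expanded chromosome mask.
#' Components closer than `min_spindle_dist_um` to the spindle mask are
#' dropped.  Mean intensity is computed on the raw tubulin channel over the
#' component voxels.
#'
#' @param tbb_isolated (y, x, z) isolated tubulin array (one frame).
#' @param tbb_raw (y, x, z) raw tubulin array (same frame).
#' @param oocyte_mask logical (y, x, z) array.
#' @param h2b_mask logical (y, x, z) expanded chromosome exclusion mask.
#' @param spindle_mask logical (y, x, z) spindle mask.
#' @param cutoff detection cutoff on voxel intensity (default 150).
#' @param pixel_size_um,z_step_um calibration.
#' @param smooth_um detection smoothing scale.
#' @param background_um large-scale background size.
#' @param min_spindle_dist_um retention requires a spindle distance
#'   strictly greater than this (default 0.1 um).
#' @param class_thresholds passed to [classify_scmf()].
#' @param frame frame index stored on the foci.
#' @return data.frame with one row per focus: `frame`, `cz`, `cy`, `cx`
#'   (centroid, voxels), `n_voxels`, `mean_intensity`, `scmf_class`,
#'   `dist_spindle_um`.
#' @export
detect_scmf <- function(tbb_isolated, tbb_raw, oocyte_mask,
                        h2b_mask = NULL, spindle_mask = NULL, cutoff = 150,
                        pixel_size_um = default_pixel_size(), z_step_um = 1.0,
                        smooth_um = 0.294, background_um = 10,
                        min_spindle_dist_um = 0.1,
                        class_thresholds = c(2303, 2999), frame = 1L) {
  if (is.matrix(tbb_isolated)) {
    tbb_isolated <- array(tbb_isolated, c(dim(tbb_isolated), 1L))
    tbb_raw <- array(tbb_raw, c(dim(tbb_raw), 1L))
    oocyte_mask <- array(oocyte_mask, dim(tbb_isolated))
  }
  d <- dim(tbb_isolated)
  sig <- c(smooth_um / pixel_size_um, smooth_um / pixel_size_um,
           smooth_um / z_step_um)
  sm <- gaussian_blur(tbb_isolated, sig)
  hw <- pmax(1L, as.integer(round(c(background_um / pixel_size_um,
                                    background_um / pixel_size_um,
                                    background_um / z_step_um) / 2)))
  bg <- box_open_background(sm, hw)
  proc <- pmax(sm - bg, 0)
  det <- proc >= cutoff & oocyte_mask
  if (!is.null(h2b_mask)) det <- det & !h2b_mask
  empty <- data.frame(frame = integer(0), cz = numeric(0), cy = numeric(0),
                      cx = numeric(0), n_voxels = integer(0),
                      mean_intensity = numeric(0),
                      scmf_class = factor(character(0),
                                          levels = c("weak", "medium", "strong")),
                      dist_spindle_um = numeric(0))
  if (!any(det)) return(empty)
  lab <- label_components(det, 26L)
  nlab <- attr(lab, "n_labels")
  sp_coords <- NULL
  if (!is.null(spindle_mask) && any(spindle_mask)) {
    w <- which(spindle_mask)
    ai <- arrayInd(w, d)
    sp_coords <- cbind(ai[, 3], ai[, 1], ai[, 2])  # (z, y, x)
  }
  spacing <- c(z_step_um, pixel_size_um, pixel_size_um)
  rows <- list()
  for (l in seq_len(nlab)) {
    w <- which(lab == l)
    ai <- arrayInd(w, d)
    coords <- cbind(ai[, 3], ai[, 1], ai[, 2])
    dist_sp <- if (is.null(sp_coords)) Inf else
      cpp_min_pair_dist(coords, sp_coords, spacing)
    if (dist_sp <= min_spindle_dist_um) next
    mi <- mean(tbb_raw[w])
    rows[[length(rows) + 1L]] <- data.frame(
      frame = as.integer(frame),
      cz = mean(coords[, 1]), cy = mean(coords[, 2]), cx = mean(coords[, 3]),
      n_voxels = length(w),
      mean_intensity = mi,
      scmf_class = classify_scmf(mi, class_thresholds),
      dist_spindle_um = dist_sp)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Link foci across frames (greedy nearest-neighbour with gap closing)
#'
#' A simplification of an autoregressive-motion tracker: each focus links
#' to the nearest unassigned track whose last position is within
#' `max_dist_um` and whose last frame is at most `max_gap + 1` frames back.
#' Per-frame counts are unaffected by tracking.
#'
#' @param foci data.frame from [detect_scmf()] over several frames.
#' @param max_dist_um linking distance cap (default 5 um).
#' @param max_gap maximum number of missed frames bridged (default 3).
#' @param pixel_size_um,z_step_um calibration.
#' @return `foci` with an integer `track_id` column.
#' @export
track_scmf <- function(foci, max_dist_um = 5, max_gap = 3L,
                       pixel_size_um = default_pixel_size(), z_step_um = 1.0) {
  if (!nrow(foci)) { foci$track_id <- integer(0); return(foci) }
  foci <- foci[order(foci$frame), , drop = FALSE]
  foci$track_id <- NA_integer_
  tracks <- list()  # each: list(last_pos, last_frame, id)
  next_id <- 0L
  for (f in sort(unique(foci$frame))) {
    idx <- which(foci$frame == f)
    # candidate (track, focus) pairs sorted by distance, greedy assignment
    cand <- list()
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      if (f - tr$last_frame > max_gap + 1L) next
      for (i in idx) {
        dd <- sqrt(((foci$cz[i] - tr$last_pos[1]) * z_step_um)^2 +
                   ((foci$cy[i] - tr$last_pos[2]) * pixel_size_um)^2 +
                   ((foci$cx[i] - tr$last_pos[3]) * pixel_size_um)^2)
        if (dd <= max_dist_um)
          cand[[length(cand) + 1L]] <- c(ti, i, dd)
      }
    }
    used_tracks <- integer(0); used_foci <- integer(0)
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(cm))) {
        ti <- cm[r, 1]; i <- cm[r, 2]
        if (ti %in% used_tracks || i %in% used_foci) next
        foci$track_id[i] <- tracks[[ti]]$id
        tracks[[ti]]$last_pos <- c(foci$cz[i], foci$cy[i], foci$cx[i])
        tracks[[ti]]$last_frame <- f
        used_tracks <- c(used_tracks, ti); used_foci <- c(used_foci, i)
      }
    }
    for (i in setdiff(idx, used_foci)) {
      next_id <- next_id + 1L
      foci$track_id[i] <- next_id
      tracks[[length(tracks) + 1L]] <-
        list(last_pos = c(foci$cz[i], foci$cy[i], foci$cx[i]),
             last_frame = f, id = next_id)
    }
  }
  foci
}

#' Per-frame and per-bin sCMF class counts
#'
#' Counts weak / medium / strong / total foci per frame, then averages the
#' per-frame counts within each of the four normalized anaphase-B bins.
#'
#' @param foci classified foci data.frame (columns `frame`, `scmf_class`).
#' @param t0,t_end anaphase onset and end frames.
#' @param n_bins number of normalized bins.
#' @param frames full frame range analysed (default `t0:t_end`); frames
#'   with no foci count as zero.
#' @return list with `per_frame` and `per_bin` data.frames; in both,
#'   `n_total = n_weak + n_medium + n_strong`.
#' @export
count_scmf <- function(foci, t0, t_end, n_bins = 4L, frames = NULL) {
  stopifnot(t0 < t_end)
  if (is.null(frames)) frames <- t0:t_end
  per_frame <- do.call(rbind, lapply(frames, function(f) {
    cls <- foci$scmf_class[foci$frame == f]
    data.frame(frame = f,
               n_weak = sum(cls == "weak"),
               n_medium = sum(cls == "medium"),
               n_strong = sum(cls == "strong"),
               n_total = length(cls))
  }))
  tmp <- per_frame
  tmp$bin <- {
    frac <- (tmp$frame - t0) / (t_end - t0)
    as.integer(ifelse(frac >= 1, n_bins, floor(frac * n_bins) + 1L))
  }
  tmp <- tmp[tmp$frame >= t0 & tmp$frame <= t_end, , drop = FALSE]
  per_bin <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sub <- tmp[tmp$bin == b, , drop = FALSE]
    data.frame(bin = b,
               n_weak = mean(sub$n_weak), n_medium = mean(sub$n_medium),
               n_strong = mean(sub$n_strong), n_total = mean(sub$n_total),
               n_frames = nrow(sub))
  }))
  list(per_frame = per_frame, per_bin = per_bin)
}

#' Run the full sCMF pipeline on a movie
#'
#' Drift-corrects the movie, builds the filtered channels and masks, and
#' detects, classifies and tracks foci on every frame.
#'
#' @param m a `cq_movie` with `chromosomes`, `tubulin` and optionally
#'   `mask` channel roles.
#' @param cutoff detection cutoff.
#' @param class_thresholds classifier boundaries.
#' @param min_spindle_dist_um spindle exclusion distance.
#' @param min_voxels oocyte-mask size filter.
#' @param drift apply drift correction first (default TRUE).
#' @param frames frames to analyse (default all).
#' @return list with `foci`, `offsets`, `t0`, `t_end`, `counts`.
#' @export
analyze_scmf <- function(m, cutoff = 150, class_thresholds = c(2303, 2999),
                         min_spindle_dist_um = 0.1, min_voxels = 6.34e4,
                         drift = TRUE, frames = NULL) {
  stopifnot(inherits(m, "cq_movie"))
  d <- movie_dim(m)
  offsets <- NULL
  if (drift && d[["t"]] >= 2) {
    dc <- drift_correct(m)
    m <- dc$movie
    offsets <- dc$offsets
  }
  if (is.null(frames)) frames <- seq_len(d[["t"]])
  t0 <- detect_anaphase_onset(m)
  tE <- detect_anaphase_end(m, t0)
  all_foci <- list()
  for (t in frames) {
    h2b <- filter_h2b(movie_volume(m, t, "chromosomes"))
    iso <- filter_tubulin(movie_volume(m, t, "tubulin"))
    oomask <- if ("mask" %in% names(m$channel_roles)) {
      make_oocyte_mask(movie_volume(m, t, "mask"),
                       pixel_size_um = m$pixel_size_um,
                       z_step_um = m$z_step_um, min_voxels = min_voxels)
    } else array(TRUE, dim(iso))
    h2b_thr <- tryCatch(threshold_yen(h2b), error = function(e) Inf)
    h2b_mask <- h2b > h2b_thr
    spindle <- make_spindle_mask(iso, h2b_mask, oomask, cutoff)
    foci <- detect_scmf(iso, movie_volume(m, t, "tubulin"), oomask,
                        h2b_mask = h2b_mask, spindle_mask = spindle,
                        cutoff = cutoff,
                        pixel_size_um = m$pixel_size_um,
                        z_step_um = m$z_step_um,
                        min_spindle_dist_um = min_spindle_dist_um,
                        class_thresholds = class_thresholds, frame = t)
    all_foci[[length(all_foci) + 1L]] <- foci
  }
  foci <- do.call(rbind, all_foci)
  foci <- track_scmf(foci, pixel_size_um = m$pixel_size_um,
                     z_step_um = m$z_step_um)
  counts <- if (t0 < tE) count_scmf(foci, t0, tE) else NULL
  list(foci = foci, offsets = offsets, t0 = t0, t_end = tE, counts = counts)
}
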