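#' Synthetic oocyte movies with planted ground truth
#'
#' Generates multi-channel time-lapse z-stacks that emulate the geometric
#' and statistical structure the measurement pipelines assume: an
#' ellipsoidal oocyte with a bright membrane shell deformed by planted
#' ingressions of known depth, a compact chromosome mass whose area
#' contracts to a unique minimum at anaphase-B onset, punctate sub-cortical
#' tubulin foci spanning the weak/medium/strong intensity classes next to a
#' bright spindle, rectangular patches of known integrated intensity,
#' optional integer frame-to-frame drift, and additive Gaussian noise
#' (clipped at zero).  Every generator returns the movie together with a
#' ground-truth record echoing the planted objects exactly.
#'
#' @name synthetic_data
NULL

#' Planted membrane ingression
#'
#' An inward radial notch of the membrane ring with a super-Gaussian
#' (quartic) profile: at boundary arc distance `s` from the anchor angle
#' the ring radius is reduced by `depth * exp(-(s / width_px)^4)`.  The
#' steep walls and rounded bottom keep the furrow opening wider than the
#' membrane thickness, so the measured contour can reach the planted
#' bottom.
#'
#' @param angle_deg angular position on the boundary (0 = +x axis,
#'   90 = up).
#' @param depth_um notch depth in micrometres (>= 0).
#' @param width_px Gaussian sigma of the notch along the boundary arc, in
#'   pixels (>= 1).
#' @param frames integer range of active frames (`NULL` = all frames).
#' @param near_chromosomes place the notch on the boundary nearest the
#'   chromosome mass (overrides `angle_deg`) so it becomes
#'   spindle-associated.
#' @return a `planted_ingression` list.
#' @export
planted_ingression <- function(angle_deg, depth_um, width_px = 4,
                               frames = NULL, near_chromosomes = FALSE) {
  stopifnot(depth_um >= 0, width_px >= 1)
  structure(list(angle_deg = angle_deg, depth_um = depth_um,
                 width_px = width_px, frames = frames,
                 near_chromosomes = isTRUE(near_chromosomes)),
            class = "planted_ingression")
}

#' Planted sub-cortical microtubule focus
#'
#' A uniform disk-shaped focus (radius `radius_px`, one z plane) whose
#' drawn amplitude is calibrated so that the detection pipeline's measured
#' mean raw intensity lands at `intensity` (the target mean used for
#' classification).
#'
#' @param intensity target mean raw intensity of the detected focus.
#' @param center voxel `c(z, y, x)` centre, or `NULL` to auto-place on the
#'   sub-cortical shell (or relative to the spindle when
#'   `distance_to_spindle_um` is given).
#' @param radius_px lateral radius in pixels.
#' @param intended_class `"weak"`, `"medium"` or `"strong"`; default
#'   derived from `intensity` via [classify_scmf()].
#' @param distance_to_spindle_um requested distance from the spindle
#'   surface; distances at or below the 0.1 um exclusion rule are rendered
#'   as touching the spindle and flagged excluded in the ground truth.
#' @return a `planted_focus` list.
#' @export
planted_focus <- function(intensity, center = NULL, radius_px = 6,
                          intended_class = NULL,
                          distance_to_spindle_um = NULL) {
  stopifnot(intensity >= 0, radius_px >= 1)
  if (is.null(intended_class))
    intended_class <- as.character(classify_scmf(intensity))
  intended_class <- match.arg(intended_class, c("weak", "medium", "strong"))
  if (as.character(classify_scmf(intensity)) != intended_class)
    stop("intended_class is inconsistent with the classifier boundaries")
  structure(list(intensity = intensity, center = center,
                 radius_px = radius_px, intended_class = intended_class,
                 distance_to_spindle_um = distance_to_spindle_um),
            class = "planted_focus")
}

#' Planted rectangular intensity patch
#'
#' @param row,col top-left corner (1-based).
#' @param height,width patch extent in pixels.
#' @param value constant intensity.
#' @export
planted_patch <- function(row, col, height = 20L, width = 96L, value = 2000) {
  stopifnot(height >= 1, width >= 1, value >= 0)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width),
                 value = value),
            class = "planted_patch")
}

#' Specification of a synthetic movie
#'
#' Defaults encode the acquisition this package targets: 16 focal planes at
#' 1 um z spacing, 10 s frame interval, 0.1468 um lateral pixels, and an
#' oocyte comfortably inside a 128 x 128 field.
#'
#' @param image_shape named integer vector `c(z, y, x)` of voxel counts.
#' @param n_frames number of frames.
#' @param pixel_size_um,z_step_um,frame_interval_s calibration.
#' @param oocyte_axes_um named semi-axes `c(z, y, x)` of the ellipsoid, um.
#' @param membrane_thickness_px thickness of the membrane ring.
#' @param ingressions list of [planted_ingression()].
#' @param foci list of [planted_focus()].
#' @param patches list of [planted_patch()].
#' @param chromosome_track `NULL` for the default V-shaped compaction
#'   schedule, or a list with `center` (row, col), `r_max_px`, `r_min_px`,
#'   `min_frame`.
#' @param drift_track `NULL` (no drift) or an `n_frames` x 3 integer matrix
#'   of per-frame (dz, dy, dx) offsets, frame 1 zero.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed.
#' @return a validated `synthetic_spec`.
#' @export
synthetic_spec <- function(image_shape = c(z = 16L, y = 128L, x = 128L),
                           n_frames = 12L,
                           pixel_size_um = default_pixel_size(),
                           z_step_um = 1.0, frame_interval_s = 10.0,
                           oocyte_axes_um = c(z = 6.5, y = 6.8, x = 8.2),
                           membrane_thickness_px = 3L,
                           ingressions = list(), foci = list(),
                           patches = list(), chromosome_track = NULL,
                           drift_track = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(pixel_size_um > 0, z_step_um > 0, frame_interval_s > 0,
            n_frames >= 1, noise_sd >= 0)
  shape <- c(z = as.integer(image_shape[["z"]]),
             y = as.integer(image_shape[["y"]]),
             x = as.integer(image_shape[["x"]]))
  if (any(shape < 1)) stop("invalid image shape")
  if (is.null(chromosome_track)) {
    ax_px <- oocyte_axes_um[["x"]] / pixel_size_um
    chromosome_track <- list(
      center = c(row = shape[["y"]] / 2,
                 col = shape[["x"]] / 2 - 0.55 * ax_px),
      r_max_px = 13, r_min_px = 7,
      min_frame = as.integer(max(1, ceiling(n_frames / 3))),
      decondense_frame = as.integer(min(n_frames,
        max(ceiling(n_frames / 3) + 2, floor(0.8 * n_frames)))))
  }
  if (is.null(chromosome_track$decondense_frame))
    chromosome_track$decondense_frame <-
      as.integer(min(n_frames, chromosome_track$min_frame + 2L))
  mf <- chromosome_track$min_frame
  if (mf < 1 || mf > n_frames) stop("chromosome minimum-area frame outside movie")
  if (chromosome_track$decondense_frame <= mf && n_frames > mf)
    stop("decondense_frame must lie after the minimum-area frame")
  if (is.null(drift_track)) drift_track <- matrix(0L, n_frames, 3)
  if (!is.matrix(drift_track) || nrow(drift_track) != n_frames ||
      ncol(drift_track) != 3)
    stop("drift_track must be an n_frames x 3 (dz, dy, dx) matrix")
  drift_track <- matrix(as.integer(drift_track), n_frames, 3)
  if (any(abs(drift_track[, 1]) > 90) || any(abs(drift_track[, 2:3]) > 10))
    stop("drift offsets exceed the registration caps (z 90, y/x 10 px)")
  if (any(drift_track[1, ] != 0)) stop("frame 1 must have zero drift")
  spec <- structure(list(
    image_shape = shape, n_frames = as.integer(n_frames),
    pixel_size_um = pixel_size_um, z_step_um = z_step_um,
    frame_interval_s = frame_interval_s,
    oocyte_axes_um = oocyte_axes_um,
    membrane_thickness_px = as.integer(membrane_thickness_px),
    ingressions = ingressions, foci = foci, patches = patches,
    chromosome_track = chromosome_track, drift_track = drift_track,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' Synthetic-movie specification sized for the foci pipeline
#'
#' Convenience wrapper around [synthetic_spec()] with a wider field
#' (192 x 192) and a full-size oocyte (26 um equatorial diameter), leaving
#' room for several well-separated sub-cortical foci outside the
#' chromosome/spindle exclusion zones.
#'
#' @param ... passed to [synthetic_spec()].
#' @export
scmf_spec <- function(...) {
  args <- list(...)
  if (is.null(args$image_shape))
    args$image_shape <- c(z = 16L, y = 192L, x = 192L)
  if (is.null(args$oocyte_axes_um))
    args$oocyte_axes_um <- c(z = 6.5, y = 11, x = 13)
  do.call(synthetic_spec, args)
}

oocyte_axes_px <- function(spec) {
  c(z = spec$oocyte_axes_um[["z"]] / spec$z_step_um,
    y = spec$oocyte_axes_um[["y"]] / spec$pixel_size_um,
    x = spec$oocyte_axes_um[["x"]] / spec$pixel_size_um)
}

validate_synthetic_spec <- function(spec) {
  shape <- spec$image_shape
  cy <- shape[["y"]] / 2; cx <- shape[["x"]] / 2
  ax <- oocyte_axes_px(spec)
  if (ax[["y"]] + 4 > shape[["y"]] / 2 || ax[["x"]] + 4 > shape[["x"]] / 2)
    stop("oocyte does not fit inside the image with margin")
  for (ing in spec$ingressions) {
    if (ing$depth_um / spec$pixel_size_um >=
        min(ax[["y"]], ax[["x"]]) - spec$membrane_thickness_px - 4)
      stop("ingression too deep: ring closure would break")
  }
  # combined deformation at the deepest point must keep the ring closed
  if (length(spec$ingressions) >= 2) {
    th <- seq(0, 2 * pi, length.out = 721)
    r0 <- ellipse_radius(th, ax[["y"]], ax[["x"]])
    defo <- rep(0, length(th))
    for (ing in spec$ingressions) {
      th0 <- ing$angle_deg * pi / 180
      s <- r0 * pmin(abs(th - th0), 2 * pi - abs(th - th0))
      defo <- defo + (ing$depth_um / spec$pixel_size_um) *
        exp(-(s / ing$width_px)^4)
    }
    if (any(r0 - defo < spec$membrane_thickness_px + 4))
      stop("overlapping ingressions break ring closure")
  }
  for (fc in spec$foci) {
    if (!is.null(fc$center)) {
      zc <- fc$center[1]; yc <- fc$center[2]; xc <- fc$center[3]
      if (zc < 1 || zc > shape[["z"]] || yc < 1 || yc > shape[["y"]] ||
          xc < 1 || xc > shape[["x"]])
        stop("planted focus outside the image")
      cz <- (shape[["z"]] + 1) / 2
      inside <- ((zc - cz) / ax[["z"]])^2 + ((yc - cy) / ax[["y"]])^2 +
        ((xc - cx) / ax[["x"]])^2
      if (inside > 1) stop("planted focus outside the oocyte")
    }
  }
  for (p in spec$patches) {
    if (p$row < 1 || p$col < 1 ||
        p$row + p$height - 1 > shape[["y"]] ||
        p$col + p$width - 1 > shape[["x"]])
      stop("patch outside the image")
  }
  invisible(spec)
}

ellipse_radius <- function(theta, a_row, a_col) {
  # boundary radius of an axis-aligned ellipse at polar angle theta
  (a_row * a_col) / sqrt((a_row * cos(theta))^2 + (a_col * sin(theta))^2)
}

chromosome_radius_at <- function(track, t) {
  # compaction to a unique minimum at min_frame, a near-flat condensed
  # plateau through anaphase B, then decondensation after decondense_frame
  mf <- track$min_frame
  dec <- if (!is.null(track$decondense_frame)) track$decondense_frame else mf + 2L
  if (t < mf) {
    span <- max(mf - 1, 1)
    track$r_min_px + (track$r_max_px - track$r_min_px) * (mf - t) / span
  } else if (t == mf) {
    track$r_min_px
  } else if (t <= dec) {
    track$r_min_px + 0.35
  } else {
    track$r_min_px + 0.35 +
      (track$r_max_px - track$r_min_px) * (t - dec) / 2
  }
}

disk_image <- function(ny, nx, center, radius, value) {
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  img <- matrix(0, ny, nx)
  img[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- value
  img
}

add_noise <- function(arr, sd) {
  if (sd <= 0) return(round(arr))
  pmax(round(arr + stats::rnorm(length(arr), 0, sd)), 0)
}

apply_drift <- function(data5, drift_track) {
  # data5: (y, x, z, c, t); drift rows are (dz, dy, dx)
  for (t in seq_len(dim(data5)[5])) {
    sh <- drift_track[t, ]
    if (all(sh == 0)) next
    for (cc in seq_len(dim(data5)[4])) {
      vol <- data5[, , , cc, t, drop = FALSE][, , , 1, 1]
      data5[, , , cc, t] <- roll3d(vol, c(sh[2], sh[3], sh[1]))
    }
  }
  data5
}

#' Generate a membrane-ingression movie
#'
#' Channel 1 holds a compact chromosome disk following the V-shaped
#' compaction schedule (drawn in the three central planes); channel 2 holds
#' a bright closed membrane ring in the central plane, deformed inward by
#' each active planted ingression.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `movie` (a `cq_movie`, roles chromosomes = 1,
#'   membrane = 2) and `truth` (ground-truth record: planted ingressions
#'   with expected peak positions and depths in px/um, the
#'   anaphase-onset frame, the drift track and the central plane).
#' @export
make_ingression_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  ny <- shape[["y"]]; nx <- shape[["x"]]; nz <- shape[["z"]]
  nt <- spec$n_frames
  ax <- oocyte_axes_px(spec)
  cy <- ny / 2; cx <- nx / 2
  z_mid <- as.integer(ceiling(nz / 2))
  track <- spec$chromosome_track

  # resolve near-chromosome anchors to the boundary angle facing the blob
  chrom_angle <- atan2(cy - track$center[["row"]], track$center[["col"]] - cx)
  ingressions <- lapply(spec$ingressions, function(ing) {
    if (ing$near_chromosomes) ing$angle_deg <- chrom_angle * 180 / pi
    ing
  })

  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  theta <- atan2(cy - rows, cols - cx)
  rho <- sqrt((rows - cy)^2 + (cols - cx)^2)
  r_base <- ellipse_radius(theta, ax[["y"]], ax[["x"]])

  data5 <- array(0, dim = c(ny, nx, nz, 2, nt))
  truth_rows <- list()
  for (t in seq_len(nt)) {
    defo <- matrix(0, ny, nx)
    for (k in seq_along(ingressions)) {
      ing <- ingressions[[k]]
      fr <- if (is.null(ing$frames)) c(1L, nt) else range(ing$frames)
      active <- t >= fr[1] && t <= fr[2]
      th0 <- ing$angle_deg * pi / 180
      r0 <- ellipse_radius(th0, ax[["y"]], ax[["x"]])
      depth_px <- ing$depth_um / spec$pixel_size_um
      if (active) {
        dth <- abs(theta - th0)
        dth <- pmin(dth, 2 * pi - dth)
        s <- r0 * dth
        defo <- defo + depth_px * exp(-(s / ing$width_px)^4)
      }
      if (t == 1L) {
        r_peak <- r0 - depth_px
        truth_rows[[k]] <- data.frame(
          id = k, angle_deg = ing$angle_deg, depth_um = ing$depth_um,
          depth_px = depth_px, width_px = ing$width_px,
          frame_start = fr[1], frame_end = fr[2],
          near_chromosomes = ing$near_chromosomes,
          peak_row = cy - r_peak * sin(th0),
          peak_col = cx + r_peak * cos(th0))
      }
    }
    r_def <- r_base - defo
    # membrane = band of the given thickness dilated outward from the
    # deformed interior region; guarantees a closed ring at any wall slope
    inner <- rho <= r_def - spec$membrane_thickness_px / 2
    ring <- maximum_filter_disk(matrix(as.numeric(inner), ny, nx),
                                spec$membrane_thickness_px) > 0 & !inner
    mem <- matrix(0, ny, nx)
    mem[ring] <- 3000
    data5[, , z_mid, 2, t] <- mem
    cr <- chromosome_radius_at(track, t)
    blob <- disk_image(ny, nx, c(track$center[["row"]], track$center[["col"]]),
                       cr, 3000)
    for (z in max(1, z_mid - 1):min(nz, z_mid + 1))
      data5[, , z, 1, t] <- blob
  }
  data5 <- apply_drift(data5, spec$drift_track)
  data5[] <- add_noise(data5, spec$noise_sd)

  m <- movie(data5, pixel_size_um = spec$pixel_size_um,
             z_step_um = spec$z_step_um,
             frame_interval_s = spec$frame_interval_s,
             channel_roles = c(chromosomes = 1L, membrane = 2L))
  truth <- list(
    kind = "ingression",
    ingressions = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(),
    anaphase_onset_frame = track$min_frame,
    decondense_frame = track$decondense_frame,
    central_plane = z_mid,
    chromosome_center = unname(track$center),
    drift = spec$drift_track,
    seed = spec$seed)
  list(movie = m, truth = truth)
}

# forward model: measured mean raw intensity of an isolated focus rendered
# at amplitude V, run through the tubulin isolation + detection steps
measure_focus_mean <- function(V, radius_px, spec, cutoff = 150) {
  side <- 4 * 20 + 1  # outsize the outlier-removal block
  pad <- (side + 1) / 2
  vol <- array(0, c(side, side, 1))
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  disk <- (rows - pad)^2 + (cols - pad)^2 <= radius_px^2
  pl <- matrix(0, side, side); pl[disk] <- round(V)
  vol[, , 1] <- pl
  iso <- filter_tubulin(vol)
  foci <- detect_scmf(iso, vol, array(TRUE, dim(vol)), cutoff = cutoff,
                      pixel_size_um = spec$pixel_size_um,
                      z_step_um = spec$z_step_um)
  if (!nrow(foci)) return(0)
  foci$mean_intensity[which.max(foci$n_voxels)]
}

focus_amp_cache <- new.env(parent = emptyenv())

#' Drawn amplitude achieving a target measured mean intensity
#'
#' Inverts the detection pipeline's monotone response for an isolated
#' uniform-disk focus by bisection, so planted foci can be parameterised by
#' the mean raw intensity the pipeline should measure.
#'
#' @param target_mean target measured mean raw intensity.
#' @param radius_px focus radius in pixels.
#' @param spec a `synthetic_spec` (calibration context).
#' @param cutoff detection cutoff.
#' @return integer amplitude.
#' @export
focus_amplitude_for_mean <- function(target_mean, radius_px, spec,
                                     cutoff = 150) {
  key <- paste(round(target_mean), radius_px, round(spec$pixel_size_um, 6),
               spec$z_step_um, cutoff, sep = "_")
  if (!is.null(focus_amp_cache[[key]])) return(focus_amp_cache[[key]])
  lo <- cutoff; hi <- 60000
  if (measure_focus_mean(hi, radius_px, spec, cutoff) < target_mean)
    stop("target mean intensity unreachable within the 16-bit range")
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (measure_focus_mean(mid, radius_px, spec, cutoff) < target_mean)
      lo <- mid else hi <- mid
  }
  amp <- as.integer(round(hi))
  focus_amp_cache[[key]] <- amp
  amp
}

#' Generate a sub-cortical microtubule foci movie
#'
#' Channel 1: chromosome blob (V-shaped compaction).  Channel 2: tubulin --
#' planted foci plus a bright spindle region adjoining the chromosome blob.
#' Channel 3: binary oocyte segmentation mask.  The drift track shifts
#' whole frames; the ground truth lists each planted focus with its
#' intended class and exclusion flags, and the per-frame retained class
#' counts.
#'
#' @param spec a [synthetic_spec()] with `foci`.
#' @return list with `movie` (roles chromosomes = 1, tubulin = 2,
#'   mask = 3) and `truth`.
#' @export
make_scmf_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  ny <- shape[["y"]]; nx <- shape[["x"]]; nz <- shape[["z"]]
  nt <- spec$n_frames
  ax <- oocyte_axes_px(spec)
  cy <- ny / 2; cx <- nx / 2; cz <- (nz + 1) / 2
  z_mid <- as.integer(ceiling(nz / 2))
  track <- spec$chromosome_track

  # oocyte ellipsoid mask (mask channel; also the containment reference)
  oomask <- array(FALSE, c(ny, nx, nz))
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (z in seq_len(nz)) {
    oomask[, , z] <- ((z - cz) / ax[["z"]])^2 + ((rows - cy) / ax[["y"]])^2 +
      ((cols - cx) / ax[["x"]])^2 <= 1
  }

  # expanded chromosome (sperm-adjacent) exclusion footprint at its
  # largest: the generator uses the same expansion filters as the analysis
  # so auto-placed foci stay clear of the exclusion zone
  blob_big <- disk_image(ny, nx, c(track$center[["row"]], track$center[["col"]]),
                         track$r_max_px, 3000)
  h2bf <- filter_h2b(array(blob_big, c(ny, nx, 1L)))[, , 1]
  h2b_thr <- tryCatch(threshold_yen(h2bf), error = function(e) Inf)
  h2b2d <- h2bf > h2b_thr
  h2b_px <- which(h2b2d, arr.ind = TRUE)
  h2b_max_col <- if (nrow(h2b_px)) max(h2b_px[, 2]) else
    track$center[["col"]] + track$r_max_px

  # spindle: bright ellipsoid overlapping the chromosome region but whose
  # far pole pokes beyond the expanded-H2B footprint, as the anaphase
  # spindle does
  sp_ax <- c(row = 6, col = 14, z = 2)
  sp_center <- c(row = track$center[["row"]], col = h2b_max_col - 2)
  spindle <- array(FALSE, c(ny, nx, nz))
  for (z in max(1, z_mid - 2):min(nz, z_mid + 2)) {
    spindle[, , z] <- ((z - z_mid) / sp_ax[["z"]])^2 +
      ((rows - sp_center[["row"]]) / sp_ax[["row"]])^2 +
      ((cols - sp_center[["col"]]) / sp_ax[["col"]])^2 <= 1
  }
  sp_idx <- arrayInd(which(spindle), dim(spindle))
  sp_tip_col <- max(sp_idx[, 2])

  # valid shell angles for auto placement: clear of the exclusion zones
  shell_pos <- function(ang) {
    c(round(cy - 0.765 * ax[["y"]] * sin(ang)),
      round(cx + 0.765 * ax[["x"]] * cos(ang)))
  }
  n_wanted <- sum(vapply(spec$foci, function(fc)
    is.null(fc$center) && is.null(fc$distance_to_spindle_um), logical(1)))
  margin <- 12 + max(c(6, vapply(spec$foci, function(fc) fc$radius_px,
                                 numeric(1))))
  cand <- seq(0, 2 * pi, length.out = 181)[-181]
  ok <- vapply(cand, function(ang) {
    p <- shell_pos(ang)
    if (nrow(h2b_px) &&
        min((h2b_px[, 1] - p[1])^2 + (h2b_px[, 2] - p[2])^2) < margin^2)
      return(FALSE)
    if (min((sp_idx[, 1] - p[1])^2 + (sp_idx[, 2] - p[2])^2) < margin^2)
      return(FALSE)
    TRUE
  }, logical(1))
  valid <- cand[ok]
  if (n_wanted > 0 && length(valid) < n_wanted)
    stop("not enough clear boundary positions for the requested foci")
  # greedy spread with a minimum chord spacing: a bright focus inside the
  # 41 x 41 outlier-removal block of a dim one inflates the local SD and
  # absorbs the dim focus into the background model
  min_space <- 2 * 20 + 2 * max(c(6, vapply(spec$foci, function(fc)
    fc$radius_px, numeric(1))))
  pick <- numeric(0)
  if (n_wanted > 0) {
    for (ang in valid[order(seq_along(valid) %% 2, seq_along(valid))]) {
      p <- shell_pos(ang)
      if (length(pick)) {
        prev <- t(vapply(pick, shell_pos, numeric(2)))
        if (min((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2) < min_space^2)
          next
      }
      pick <- c(pick, ang)
      if (length(pick) == n_wanted) break
    }
    if (length(pick) < n_wanted)
      stop("not enough clear, well-spaced boundary positions for the ",
           "requested foci; use a larger field or fewer foci")
  }

  n_auto <- 0L
  foci <- lapply(spec$foci, function(fc) {
    if (is.null(fc$center)) {
      if (!is.null(fc$distance_to_spindle_um)) {
        gap_px <- fc$distance_to_spindle_um / spec$pixel_size_um
        if (fc$distance_to_spindle_um <= 0.1) {
          col0 <- sp_tip_col + fc$radius_px - 1  # touching / overlapping
        } else {
          col0 <- sp_tip_col + fc$radius_px + max(1, round(gap_px))
        }
        fc$center <- c(z_mid, round(sp_center[["row"]]), round(col0))
      } else {
        n_auto <<- n_auto + 1L
        p <- shell_pos(pick[n_auto])
        fc$center <- c(z_mid, p[1], p[2])
      }
    }
    fc$amplitude <- focus_amplitude_for_mean(fc$intensity, fc$radius_px, spec)
    fc
  })

  data5 <- array(0, dim = c(ny, nx, nz, 3, nt))
  for (t in seq_len(nt)) {
    tbb <- array(0, c(ny, nx, nz))
    tbb[spindle] <- 9000
    for (fc in foci) {
      z0 <- fc$center[1]
      disk <- (rows - fc$center[2])^2 + (cols - fc$center[3])^2 <= fc$radius_px^2
      pl <- tbb[, , z0]
      pl[disk] <- pmax(pl[disk], fc$amplitude)
      tbb[, , z0] <- pl
    }
    data5[, , , 2, t] <- tbb
    cr <- chromosome_radius_at(track, t)
    blob <- disk_image(ny, nx, c(track$center[["row"]], track$center[["col"]]),
                       cr, 3000)
    for (z in max(1, z_mid - 1):min(nz, z_mid + 1))
      data5[, , z, 1, t] <- blob
    data5[, , , 3, t] <- oomask * 1000
  }
  data5 <- apply_drift(data5, spec$drift_track)
  data5[] <- add_noise(data5, spec$noise_sd)

  # ground-truth exclusion flags from the rendered geometry
  spacing <- c(spec$z_step_um, spec$pixel_size_um, spec$pixel_size_um)
  truth_foci <- do.call(rbind, lapply(seq_along(foci), function(k) {
    fc <- foci[[k]]
    disk <- (rows - fc$center[2])^2 + (cols - fc$center[3])^2 <= fc$radius_px^2
    vox <- which(disk, arr.ind = TRUE)
    coords <- cbind(fc$center[1], vox[, 1], vox[, 2])
    dist_sp <- cpp_min_pair_dist(coords,
                                 cbind(sp_idx[, 3], sp_idx[, 1], sp_idx[, 2]),
                                 spacing)
    data.frame(id = k, cz = fc$center[1], cy = fc$center[2],
               cx = fc$center[3], radius_px = fc$radius_px,
               target_mean = fc$intensity, amplitude = fc$amplitude,
               intended_class = fc$intended_class,
               dist_spindle_um = dist_sp,
               excluded_spindle = dist_sp <= 0.1,
               excluded_h2b = any(h2b2d[disk]))
  }))
  if (is.null(truth_foci)) truth_foci <- data.frame()
  retained <- if (nrow(truth_foci))
    truth_foci[!truth_foci$excluded_spindle & !truth_foci$excluded_h2b,
               , drop = FALSE] else truth_foci
  counts <- c(weak = sum(retained$intended_class == "weak"),
              medium = sum(retained$intended_class == "medium"),
              strong = sum(retained$intended_class == "strong"))
  m <- movie(data5, pixel_size_um = spec$pixel_size_um,
             z_step_um = spec$z_step_um,
             frame_interval_s = spec$frame_interval_s,
             channel_roles = c(chromosomes = 1L, tubulin = 2L, mask = 3L))
  truth <- list(kind = "scmf", foci = truth_foci,
                class_counts = counts, total = sum(counts),
                anaphase_onset_frame = track$min_frame,
                decondense_frame = track$decondense_frame,
                drift = spec$drift_track, seed = spec$seed)
  list(movie = m, truth = truth)
}

#' Generate a patch-intensity series
#'
#' Channel 1: chromosome blob; channel 2: rectangular patches of known
#' constant value on a zero background (single plane).  The ground truth
#' holds the exact per-frame integrated sums.
#'
#' @param spec a [synthetic_spec()] with `patches`.
#' @return list with `movie` (roles chromosomes = 1, patch = 2) and
#'   `truth` (per-frame integrated sums and the patch table).
#' @export
make_patch_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  ny <- shape[["y"]]; nx <- shape[["x"]]; nz <- shape[["z"]]
  nt <- spec$n_frames
  track <- spec$chromosome_track
  z_mid <- as.integer(ceiling(nz / 2))
  data5 <- array(0, dim = c(ny, nx, nz, 2, nt))
  per_frame_sum <- 0
  pl <- matrix(0, ny, nx)
  for (p in spec$patches) {
    pl[p$row:(p$row + p$height - 1), p$col:(p$col + p$width - 1)] <-
      pl[p$row:(p$row + p$height - 1), p$col:(p$col + p$width - 1)] + p$value
    per_frame_sum <- per_frame_sum + p$value * p$height * p$width
  }
  for (t in seq_len(nt)) {
    data5[, , z_mid, 2, t] <- pl
    cr <- chromosome_radius_at(track, t)
    data5[, , z_mid, 1, t] <-
      disk_image(ny, nx, c(track$center[["row"]], track$center[["col"]]),
                 cr, 3000)
  }
  data5 <- apply_drift(data5, spec$drift_track)
  data5[] <- add_noise(data5, spec$noise_sd)
  m <- movie(data5, pixel_size_um = spec$pixel_size_um,
             z_step_um = spec$z_step_um,
             frame_interval_s = spec$frame_interval_s,
             channel_roles = c(chromosomes = 1L, patch = 2L))
  patch_df <- if (length(spec$patches)) do.call(rbind, lapply(spec$patches,
    function(p) data.frame(row = p$row, col = p$col, height = p$height,
                           width = p$width, value = p$value))) else data.frame()
  truth <- list(kind = "patch",
                patches = patch_df,
                integrated_per_frame = rep(per_frame_sum, nt),
                anaphase_onset_frame = track$min_frame,
                seed = spec$seed)
  list(movie = m, truth = truth)
}
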