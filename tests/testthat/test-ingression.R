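# cortex segmentation, contour extraction, event detection and the
# anaphase-B timing / summary machinery

test_that("segment_cortex recovers the interior of a plain ring", {
  img <- ring_image(101, c(51, 51), 35)
  interior <- segment_cortex(img)
  # one object, roughly the disk inside the ring minus the 1-px dilation rim
  expect_true(interior[51, 51])
  expect_false(any(interior[1, ]) || any(interior[, 1]))
  area <- sum(interior)
  expect_gt(area, 0.8 * pi * 32^2)
  expect_lt(area, pi * 34^2)
})

test_that("segment_cortex captures a narrow deep slit", {
  img <- ring_image(101, c(51, 51), 35)
  # 1-px-wide bright slit reaching 10 px into the interior at the top
  img[(51 - 35):(51 - 25), 51] <- 3000
  interior <- segment_cortex(img)
  slit <- cbind((51 - 35):(51 - 25), 51)
  expect_false(any(interior[slit]))
  # and the contour dips into the slit: a recorded ingression results
  ct <- extract_contour(interior)
  href <- hull_reference(ct)
  ev <- find_ingressions(href, pixel_size_um = 0.1468)
  expect_gte(nrow(ev), 1)
  expect_gt(max(ev$length_px), 5)
})

test_that("segment_cortex rejects blank and ambiguous images", {
  expect_error(segment_cortex(matrix(0, 50, 50)))
  # two nested rings -> two interior objects
  img <- ring_image(121, c(61, 61), 50) + ring_image(121, c(61, 61), 25)
  expect_error(segment_cortex(img), "multiple interior")
})

test_that("extract_contour traces squares, disks and rejects degenerates", {
  sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE
  ct <- extract_contour(sq)
  expect_equal(nrow(ct), 36)
  expect_true(all(ct[, 1] %in% 2:11 & ct[, 2] %in% 2:11))
  # closed: consecutive points (and last-first) are 8-adjacent
  nxt <- rbind(ct[-1, ], ct[1, ])
  expect_true(all(pmax(abs(nxt[, 1] - ct[, 1]), abs(nxt[, 2] - ct[, 2])) == 1))

  dm <- disk_mask(41, c(21, 21), 15)
  ctd <- extract_contour(dm)
  rad <- sqrt((ctd[, 1] - 21)^2 + (ctd[, 2] - 21)^2)
  expect_true(all(abs(rad - 15) <= 1.5))

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_error(extract_contour(single), "minimum area")
  two <- matrix(FALSE, 20, 20); two[2:6, 2:6] <- TRUE; two[12:16, 12:16] <- TRUE
  expect_error(extract_contour(two), "disconnected")
})

test_that("chromosome_objects thresholds the projection, allows empty masks", {
  vol <- array(0, c(40, 40, 3))
  vol[10:14, 10:14, 2] <- 4000
  vol[30:33, 25:28, 3] <- 4000
  mask <- chromosome_objects(vol)
  expect_true(all(mask[11:13, 11:13]))
  expect_true(all(mask[31:32, 26:27]))
  expect_false(mask[20, 20])
  expect_false(any(chromosome_objects(array(0, c(20, 20, 2)))))
})

test_that("spindle association uses the 22-px edge distance rule", {
  ev <- data.frame(frame = c(1L, 1L), contour_index = c(1L, 2L),
                   row = c(30, 30), col = c(40 + 10, 40 + 30),
                   length_px = c(8, 8), length_um = c(1.2, 1.2),
                   seg_a = 1L, seg_c = 2L, spindle_associated = FALSE)
  chrom <- matrix(FALSE, 80, 80)
  chrom[28:32, 36:40] <- TRUE  # edge at col 40
  out <- flag_spindle_associated(ev, chrom, radius_px = 22)
  expect_true(out$spindle_associated[1])    # 10 px from the edge
  expect_false(out$spindle_associated[2])   # 30 px away
  none <- flag_spindle_associated(ev, matrix(FALSE, 80, 80))
  expect_false(any(none$spindle_associated))
})

test_that("minimum-length filter keeps >= 1 um and is idempotent", {
  ev <- data.frame(length_um = c(0.8, 1.0, 2.5))
  kept <- filter_min_length(ev)
  expect_equal(kept$length_um, c(1.0, 2.5))
  expect_identical(filter_min_length(kept), kept)
  expect_equal(nrow(filter_min_length(data.frame(length_um = c(0.1, 0.9)))), 0)
})

test_that("anaphase onset is the frame of minimal chromosome area", {
  m <- schedule_movie(c(10, 8, 6, 4, 6, 8, 10))
  expect_equal(detect_anaphase_onset(m), 4L)
  # ties break to the earliest frame
  expect_equal(detect_anaphase_onset(schedule_movie(rep(5, 6))), 1L)
  # monotone decreasing area: last frame
  expect_equal(detect_anaphase_onset(schedule_movie(c(10, 8, 6, 5, 4))), 5L)
  expect_error(detect_anaphase_onset(schedule_movie(rep(0, 3))),
               "no chromosome signal")
})

test_that("anaphase end is the first sustained decondensation frame", {
  m <- schedule_movie(c(10, 5, 5.2, 5.2, 5.2, 9, 9, 9))
  expect_equal(detect_anaphase_onset(m), 2L)
  expect_equal(detect_anaphase_end(m), 6L)
  # no decondensation: falls back to the last frame
  m2 <- schedule_movie(c(10, 5, 5, 5))
  expect_equal(detect_anaphase_end(m2), 4L)
})

test_that("normalized time bins are quarters, half-open, last closed", {
  # fractions 0, .25, .3, .5, .75, 1: half-open bins put .25 in bin 2
  ev <- data.frame(frame = c(1, 6, 7, 11, 16, 21))
  out <- normalize_anaphase_time(ev, t0 = 1, t_end = 21)
  expect_equal(out$bin, c(1L, 2L, 2L, 3L, 4L, 4L))
  expect_warning(normalize_anaphase_time(data.frame(frame = c(0, 5, 25)),
                                         t0 = 1, t_end = 21),
                 "outside the anaphase window")
  out2 <- suppressWarnings(
    normalize_anaphase_time(data.frame(frame = c(0, 5, 25)), 1, 21))
  expect_equal(out2$frame, 5)
})

test_that("summaries average per oocyte, omitting empty-bin means", {
  ev <- data.frame(oocyte = c("a", "a", "a", "b"),
                   bin = c(1L, 1L, 1L, 1L),
                   length_um = c(1, 2, 3, 2),
                   spindle_associated = FALSE)
  s <- summarize_ingressions(ev)
  a1 <- s$per_oocyte[s$per_oocyte$oocyte == "a" & s$per_oocyte$bin == 1, ]
  expect_equal(a1$mean_length_um, 2)
  expect_equal(a1$sum_length_um, 6)
  expect_equal(a1$n_ingressions, 3L)
  b1 <- s$per_bin[s$per_bin$bin == 1, ]
  expect_equal(b1$mean_sum_um, mean(c(6, 2)))
  expect_equal(b1$mean_count, mean(c(3, 1)))
  # empty bins: zero sums/counts; mean length NA (not imputed as 0)
  b2 <- s$per_bin[s$per_bin$bin == 2, ]
  expect_equal(b2$mean_sum_um, 0)
  expect_equal(b2$mean_count, 0)
  expect_true(is.na(b2$mean_length_um))
  # flagged events are excluded
  ev$spindle_associated[1] <- TRUE
  s2 <- summarize_ingressions(ev)
  expect_equal(s2$per_oocyte$n_ingressions[s2$per_oocyte$oocyte == "a" &
                                           s2$per_oocyte$bin == 1], 2L)
})

test_that("group comparison is a two-sided rank-sum test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1.0)
  p <- compare_groups(c(1, 2, 3, 4), c(101, 102, 103, 104))
  expect_lt(p, 0.05)
  expect_equal(compare_groups(c(5, 1, 9), c(2, 7, 4)),
               compare_groups(c(2, 7, 4), c(5, 1, 9)))
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})
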