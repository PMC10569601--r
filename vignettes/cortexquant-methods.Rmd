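---
title: "cortexquant: methods, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexquant: methods, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortexquant` quantifies two phenomena in multi-channel time-lapse
z-stacks of *C. elegans* oocytes during meiosis I polar body extrusion:
cortical membrane ingression (local inward furrowing of the plasma
membrane) and sub-cortical microtubule foci (sCMFs, punctate tubulin
accumulations near the cell surface). This vignette is the package's own
account of how the measurements are defined, which parameters matter, how
the synthetic ground-truth generator is built, and what the test suite
does and does not establish.

## 1. The movie model

A movie is a `T x Z x C x Y x X` hyperstack with physical calibration
(`pixel_size_um`, `z_step_um`, `frame_interval_s`) and a named mapping
from channel roles (`chromosomes`, `membrane`, `tubulin`, `patch`,
`mask`) to channel indices. The targeted acquisition uses 1 µm z spacing,
16 focal planes and a 10 s frame interval. The default lateral
calibration is **0.1468 µm/px**, the single scale jointly consistent with
the three pixel-micrometre pairs the measurement rules quote (3 px =
0.441 µm, 22 px = 3.23 µm, 80 px = 11.75 µm); `consistent_pixel_scale()`
computes it as a least-squares fit. In memory the array is stored
`(y, x, z, c, t)` (column-major friendly); on disk, `write_movie()`
emits an uncompressed multi-page TIFF in T-Z-C page order with the layout
and calibration embedded as JSON in the ImageDescription tag. The reader
is deliberately minimal (little-endian, single-strip, 8/16-bit
grayscale); it exists because no TIFF reader is available in the target
R environment, not as a general TIFF library.

## 2. Membrane ingression measurement

**Segmentation.** In one central focal plane (default: the z index with
the highest membrane-channel contrast; the acquisition protocol used "a
single central focal plane" without stating a rule) the membrane image is
despeckled with a 2x2 median kernel and binarized with Yen's
maximum-correlation threshold. The binary cortex is dilated by 1 px and
inverted; the object touching the image border (the exterior) is
discarded and the remaining connected object is the oocyte interior.
The dilate-invert step keeps narrow, deep furrows open as thin corridors
in the interior, which a plain fill would close.

**Contour and hull.** The interior boundary is traced (Moore neighbour
tracing, counter-clockwise, 0.5-px-free pixel coordinates) into a closed
contour, and its convex hull (monotone chain; collinear points are not
vertices) provides the measurement reference. Contour points within
`eps = 0.5` px of the hull polygon count as intersections — discrete
pixel contours rarely touch the real-valued hull exactly. Between each
adjacent intersection pair (A, C) the contour is transformed to a 1-D
profile of perpendicular distances `d = ||AB x AC|| / ||AC||`.

**Events.** Profile peaks are strict local maxima with topographic
prominence of at least 1 px (the source procedure says only "find
peaks"; the prominence floor suppresses pixel-noise double counting).
A peak is recorded when its depth exceeds **3 px** (0.441 µm), strictly —
a peak exactly at 3 px is not recorded ("longer than"). Events whose
peak point lies within **22 px** (3.23 µm) of the nearest pixel of the
Yen-thresholded chromosome MIP are flagged spindle-associated and
excluded from summaries. Summaries keep events of length **>= 1 µm**
(inclusive; the figure-legend convention — the Methods prose reads the
other way and the discrepancy is documented here).

**Timing.** Anaphase-B onset `t0` is the frame minimizing the area of
the thresholded chromosome MIP mask (maximal compaction; ties break
earliest). The end `t_end` is the first frame after `t0` whose mask area
exceeds 1.5x the minimum for two consecutive frames (decondensation;
both the factor and the persistence are configurable — the source
defines the end qualitatively). `[t0, t_end]` is divided into four equal
bins, half-open `[a, b)` with the last bin closed. Per oocyte-bin the
mean length, summed length and count are computed; per condition-bin
these are averaged across oocytes, with empty-bin means omitted from the
average rather than imputed as zero (an empty bin still contributes sum
0 and count 0).

**Statistics.** Group comparisons delegate to the standard two-sided
Mann-Whitney U test (`stats::wilcox.test`, normal approximation with
continuity correction under ties).

## 3. Sub-cortical microtubule foci

**Channel conditioning.** The chromosome channel is expanded per plane —
median (disk radius 5), Gaussian (sigma 10 px), maximum (disk radius 5) —
so that chromosome- and sperm-adjacent tubulin can be excluded. The
tubulin channel is background-subtracted: a local outlier-replacement
filter (block radius 20 px; a pixel deviating from its local median by
more than 0.90 local SD is replaced by that median — the reference
tool's mechanism is loosely documented, so the mechanism is stated here
with the printed parameters) models the background, which is subtracted
from the original and the residue cleaned with a median of radius 5.

**Drift.** Frames are registered to frame 1 by 3-D cross-correlation of
the tubulin channel with integer shifts capped at **10 / 10 / 90** px in
x / y / z (the z cap is quoted verbatim although it exceeds any stack
depth used here; it is additionally limited to Z-1, and caps rarely
bind). Estimates beyond a cap are clipped with a warning; featureless
frames get zero shift with a warning. Reported offsets are the applied
compensating shifts (planted drift `(0, 3, 2)` yields offsets
`(0, -3, -2)`).

**Masks.** The oocyte mask comes from a segmentation channel smoothed at
0.294 µm, thresholded, with 26-connected components of at least
**6.34e4 voxels** retained. The spindle mask is the union of isolated-
tubulin components (at the detection cutoff) that overlap the thresholded
expanded-chromosome mask — the tubulin structure contiguous with the
chromosome mass.

**Detection and classification.** The isolated channel is smoothed at
0.294 µm, a large-scale background at the 10 µm "largest fitting sphere"
scale is subtracted — implemented as a flat box opening (separable
erosion/dilation) at that scale, which is exact on the zero backgrounds
the generator produces — and 26-connected components of voxels at or
above **150**, inside the oocyte mask and outside the expanded chromosome
mask, are foci candidates. Components whose anisotropic Euclidean
distance to the spindle mask is **<= 0.1 µm** are dropped (on a 0.1468 µm
grid this is equivalent to voxel overlap: the nearest non-overlapping
voxel centre is already 0.1468 µm away). Mean intensity is computed on
the **raw** tubulin channel over the component's voxels and classified:
weak `< 2303`, medium `2303..2999` inclusive, strong `> 2999`. The
boundary value 2303 is assigned to medium per the "between 2303 and
2999" clause (the printed prose is internally inconsistent at that exact
value). The thresholds were calibrated on control movies in the source
workflow and are configurable here.

**Tracking and counts.** Foci are linked across frames by greedy
nearest-neighbour assignment with a 5 µm distance cap and gap closing up
to 3 frames — a deliberate simplification of the commercial
autoregressive-motion tracker; per-frame counts are unaffected by
tracking. Class counts are tabulated per frame and averaged within the
four normalized anaphase-B bins.

## 4. Patch / microtubule intensity and RSD

Per timepoint the measured channel is z-projected (max), median-filtered
(disk radius 3), background-subtracted with a rolling ball of radius
20 px (grayscale opening with a ball-height structuring element), and
thresholded within the oocyte ROI by the Triangle method; the integrated
intensity of threshold-passing particles is summed, excluding particles
that overlap the chromosome mask ("chromosome-associated signal"
subtraction is implemented as particle exclusion; subtracting a measured
chromosome-region sum reduces the same quantity). The default window is
five frames starting 200 s before anaphase onset (-200..-160 s; the
source enumerates four timepoints but states five — five are used); the
drug-treatment variant uses 16 frames. Within a condition group,
`z = (x - min) / (max - min) * 100` maps sums onto 0..100 (min to 0, max
to 100, exactly); percent depletion is reported as the magnitude
`100 - z` (the source's "100 was subtracted" yields the negated value;
the magnitude matches the bar-graph convention).

The relative standard deviation metric divides the sample SD (n-1
denominator, stated in output metadata) by the mean over ROI pixels of a
surface-five-plane MIP taken 10 s after anaphase onset, excluding a
circle of radius 80 px (11.75 µm) around the spindle.

## 5. The synthetic world

The generators render what the pipelines assume, with exact echoes of
every planted object:

* **Ingression movies** (default 128x128x16, 12 frames): a bright
  (3000-count) closed membrane band of thickness 3 px around an
  elliptical oocyte (semi-axes 6.8 x 8.2 µm — a scaled-down oocyte that
  keeps runtimes small; `scmf_spec()` below uses full size), drawn by
  dilating the deformed interior region so the ring is closed at any
  wall slope. Planted ingressions are inward radial notches with a
  **super-Gaussian (quartic)** profile
  `depth * exp(-(s / width)^4)` along the boundary arc. A plain Gaussian
  notch was tried first and rejected: its opening narrows below the
  membrane thickness well above the notch bottom, so the dilate-invert
  contour cannot reach the planted depth and recovery errors exceed 2 px
  by construction. The quartic profile has steep walls and a rounded
  bottom wider than the membrane, which is also how measured furrows
  look: an opening of finite width, not a cusp. Recovery over planted
  depths 1.0-2.2 µm at all orientations is within 1.7 px.
* **Chromosome compaction** follows a V-with-plateau schedule: the blob
  radius falls 13 -> 7 px to a unique minimum frame, stays on a
  condensed plateau (7.35 px — strictly more area than the minimum, so
  the minimum frame is unique in the rendered data), then rises after a
  decondensation frame. Radii are realistic for the condensed chromosome
  mass (~2 µm across) and, importantly, large enough to survive the
  radius-5 median filter of the chromosome-expansion chain; a smaller
  blob is erased by that filter and the exclusion masks silently vanish.
* **sCMF movies** (`scmf_spec()`: 192x192x16, oocyte semi-axes
  6.5 x 11 x 13 µm, i.e. a 26 µm equatorial diameter) hold a binary mask
  channel, the chromosome blob, a bright spindle ellipsoid overlapping
  the chromosome region whose far pole pokes beyond the expanded-H2B
  footprint (as the anaphase spindle does), and uniform-disk foci of
  radius 6 px on the sub-cortical shell. Planted foci are parameterised
  by the **target mean raw intensity** the pipeline should measure; the
  drawn amplitude is obtained by bisecting the pipeline's own forward
  response on an isolated template. Auto-placement keeps foci clear of
  the exclusion zones and at least ~52 px apart, because a bright focus
  inside the 41x41 outlier-removal block of a dim one inflates the local
  SD and absorbs the dim focus into the background model — a real
  property of the published filter chain, not an artefact.
* **Patch series**: rectangles of known constant value; ground truth is
  the exact drawn sum. Defaults are 20 x 96 px at value 2000: the median
  filter always erodes ~12 fixed rim pixels of a rectangle and the
  rolling ball bulges by `R - sqrt(R^2 - (w/2)^2)` under a patch of
  width w, so only patches that are long, thin (w below the ball
  diameter) and bright are measured within 1%. A 10x10 patch is measured
  ~8% low by the faithful pipeline; its ground truth is still exactly
  `area * value`.
* **Noise** is additive Gaussian, clipped at zero, rounded to integers
  (16-bit camera semantics); Poisson noise is deliberately omitted since
  every threshold in the pipelines is absolute. **Drift** is an integer
  per-frame (dz, dy, dx) roll with zero fill, validated against the
  registration caps.

### What a green test establishes — and what it does not

Because planted focus amplitudes are calibrated through the package's own
forward model, the exact class-recovery test validates detection
geometry, mask logic, exclusion rules, connected-component bookkeeping
and counting — not the absolute intensity calibration of a microscope.
Similarly, the synthetic membrane is noise-free and exactly elliptical;
green recovery tests do not establish robustness to out-of-focus light,
photobleaching, or segmentation of touching oocytes (hand-cropping
replaced those steps in the source workflow, and a mask TIFF input plays
that role here). The intensity class boundaries (2303/2999) and the
detection cutoff (150) are instrument-specific constants carried as
defaults, not re-derivable from synthetic data.

## 6. Numerical choices

* Hull-contour coincidence tolerance 0.5 px; peak prominence 1 px;
  recording threshold strictly greater than 3 px; minimum kept length
  >= 1 µm inclusive.
* Yen and Triangle thresholds operate on integer-binned histograms
  (one bin per grey level); both were cross-checked against an
  independent reference implementation on frozen fixtures.
* Median filters use disk footprints (in-bounds part at borders); the
  2x2 kernel is anchored with the pixel at its top-left, upper-middle
  order statistic for even counts.
* Gaussian blurs are separable with reflect boundary, kernel truncated
  at 3 sigma; physical sigmas are converted per axis (0.294 µm is
  2.0 px laterally and 0.294 voxels axially at default calibration).
* Connected components are 8-connected in 2-D and 26-connected in 3-D.
* Spindle distance is the minimum pairwise anisotropic Euclidean
  distance between component voxels and spindle voxels.
* Degenerate inputs error loudly: blank or multi-interior segmentations,
  single-level histograms, collinear contours, empty ROIs, zero-mean RSD
  regions, max = min normalization groups.

## 7. Known limitations

* The TIFF reader handles only the subset of TIFF this package writes
  (plus similar uncompressed grayscale files); proprietary formats are
  out of scope.
* The tracker is a greedy nearest-neighbour linker; track identities in
  dense, fast-moving scenes will differ from an autoregressive-motion
  tracker. Counts, the quantity analysed downstream, do not depend on
  it.
* Volumetric (3-D) furrow measurement, contractile-ring kinetics and
  polar-body success calling are out of scope.
* The ingression pipeline measures one central plane; oocytes whose
  furrows tilt strongly out of plane are under-measured, as in the
  source workflow.
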