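---
title: "Methods: two-channel fly morphometry with flywalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-channel fly morphometry with flywalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flywalk` measures morphometric traits of single walking flies from
two-channel frame sequences and ranks individuals for selection. This
vignette documents the measurement model, the tunable parameters, the
synthetic-data generator that backs the test suite, and the numerical
choices made where the design was genuinely open.

## Imaging model and assumptions

Each fly is recorded as an ordered sequence of registered frame pairs
against a fixed background:

* **blue channel** — diffuse backlighting. The body is strongly absorbing
  (dark), wing membranes are translucent (slightly darker than the
  background), and the wing outline and longitudinal veins are markedly
  darker thin curves.
* **red channel** — side transillumination. The thorax, head and abdomen
  glow; the abdominal luminance falls off along the
  anterior–posterior axis with a sex-specific pattern; the three ocelli
  are bright dots on the head and the compound eyes are dark; where a wing
  overlies the body, the body acts as the light source and the veins appear
  as attenuation.

Assumptions: a single fly per sequence, dorsal view, in-plane pose changes
only (translation and a few degrees of rotation between frames), and a
fly-free background frame. Pixel calibration (`mm_per_px`) is applied only
when reporting millimetre columns; every internal computation is in pixels.

## Frame validation and sequence acceptance

Six per-frame criteria must all hold: focus, border clearance, absence of
wing reflections, dorsal wing exposure, tunnel alignment, and bilateral
symmetry. A sequence is accepted iff at least `qc.min_valid_frames`
(default 3) frames are valid. The criteria are classical; the metrics
behind them are package choices:

* **focus** — variance of the 4-neighbour Laplacian inside the fly bounding
  box after 1 px Gaussian pre-smoothing (so sensor noise does not dominate).
  The default threshold (2e-4 on the [0, 1] luminance scale) was calibrated
  once on the renderer: it sits between sharp renders and renders defocused
  with a sigma = 4 px Gaussian.
* **border clearance** — no foreground pixel within `qc.border_margin`
  (2 px) of any image border.
* **reflections** — fraction of saturated pixels (≥ 250/255) in the wing
  region (foreground minus dilated body core) below 0.5 %.
* **dorsal exposure** — wing silhouette area outside the body core at least
  `qc.min_wing_ratio` (0.3) of the body-core area; a side view hides the
  blades and fails this ratio.
* **alignment** — the body axis within `qc.max_axis_angle_deg` (10°) of the
  tunnel axis.
* **symmetry** — IoU of the silhouette with its mirror image about the body
  axis at least `qc.min_symmetry_iou` (0.85).

Two stability details matter. The axis used for alignment and for the
mirror line is estimated from the *body core* (the strongly absorbing
silhouette, opened to drop the legs), not from the full foreground: with
the wings spread, the full silhouette's second-moment tensor is nearly
isotropic and its principal direction is numerically unstable.

## Body segmentation

Valid blue frames are background-subtracted and complemented (dark fly on a
bright field), aligned by central image moments (centroid to the stack
centre, major axis vertical), and collapsed by a per-pixel temporal
95th-percentile projection, which restores the background under the
constantly moving legs. Conventions chosen here:

* the 180° ambiguity of the axis is resolved by requiring the widest
  leg-free body section — the abdomen — to lie below the centroid. The
  decision is taken *once per sequence* (summing per-frame scores): a fly
  keeps its walking direction within a run, and a *consensus* flip is far
  more robust than per-frame votes, whose failure on a single frame would
  corrupt the whole projection.
* the percentile uses the linear-interpolation order statistic (type 7 of
  `stats::quantile()`); with few frames the exact convention visibly
  changes the result, so it is fixed and tested against a brute-force
  per-pixel sort.
* the projection runs on the complemented images; the high percentile then
  *brightens away* dark transients, which is what "deleting" the legs means
  in this convention.

The projection is thresholded with a **two-stage Otsu**: the first split
separates background and membranes from dark structures, the second —
applied to the dark pixels only — separates the strongly absorbing body
from wing veins and bristles. Remaining thin structures are removed by
opening the fly mask with a disc of radius `body.closing_radius` (3 px;
note that closing the dark-fly *image*, the classical description, is the
same operation as opening the fly *mask*), and the largest connected
component is kept.

Head/thorax/abdomen are split by marker-controlled watershed: the three
strongest maxima of the per-row distance-transform profile (smoothed,
minimum separation `body.min_peak_separation` = 25 px ≈ half the smallest
lobe-centre spacing) seed a descending flood of the distance transform, so
the region boundaries form across the distance ridges at the neck between
lobes. The head end is the smaller terminal segment, with the brighter
red-channel maxima (the ocelli) as a tie-break. Each segment is summarized
by its second-moment ellipse — exact for a filled ellipse and much stabler
on watershed-truncated lobes than a least-squares fit to the (cut) contour.
Shoulder width is the thorax template's reference shoulder width times the
fitted scale factor; with the default 1:1 template it equals the fitted
thorax width, and any constant offset against a manual landmark convention
is absorbed by the validation regression.

## Sex call

The abdominal luminance profile (red channel sampled along the abdomen
axis, resampled to 100 points of normalized arc length, divided by its
mean) is correlated at zero lag against packaged average male and female
curves; arc-length normalization makes a lag search unnecessary. The
packaged templates were built by averaging measured profiles of 50 rendered
flies per sex and are user-replaceable (two-column CSVs) for real imagery
or other genotypes.

Sex combs are searched in the region extending anterior to the head: dark
spots in the red channel (below `sex.comb_threshold` = 0.16) with area in
`sex.comb_area_range` (3–80 px²) and second-moment eccentricity below
`sex.eccentricity_max` (0.95) — the eccentricity filter rejects elongated
artifacts such as a leg crossing the antennae.

Fusion rule: a detected comb with confidence ≥ `sex.tau_comb` (0.3) calls
male — combs exist only in males, so positive comb evidence is decisive.
Otherwise a luminance confidence `|r_male − r_female|` ≥ `sex.tau_lum`
(0.15) calls the winning template; otherwise the *absence* of a comb plus a
female-favouring margin of at least `tau_lum / 2` still calls female (comb
absence is itself weak female evidence); anything else is `unknown` for
manual resolution. Comb confidence combines the fraction of frames with a
detection and the mean detected area (reference area 8 px²).

## Interocular distance

On the brightest red frame (maximum mean luminance inside the body mask,
ties to the first frame) the head ROI is the head segment's bounding box
plus 5 px. The ocellar triangle is located by normalized cross-correlation
against a three-dot template (17 px, dot sigma 1.4 px, posterior separation
11 px); a peak below `head.ocelli_min_ncc` (0.5) is "ocelli not found".
The peak is interpolated quadratically and each posterior dot is refined by
a local intensity centroid, giving sub-pixel landmark positions — needed
because the landmark precision dominates the IOD error budget. The
luminance is then sampled along the line through the posterior pair
(bilinear interpolation at 0.5 px steps), smoothed with a
`head.profile_sigma` = 1 px Gaussian, and differentiated by central
differences. The eye edges are the *outermost* derivative-magnitude peaks
above `head.edge_rel_threshold` (0.4 of the strongest peak) on each side —
"outermost above threshold" rather than "global maximum" so that cuticle
texture between the ocelli and the eye cannot shadow the true edge. IOD is
the distance between the two (sub-pixel refined) edges.

## Wing measurement

Thin wing structures are detected on the brightest frame in both channels
and combined: in blue outside the body, gated to the wing blades (the
membrane's intermediate luminance band, area-filtered to drop the thin
luminance-ramp sleeves along legs and body edges); in red over the body.
Both detections threshold the CLAHE-enhanced channel on the *ratio* of
local luminance to a Gaussian-smoothed local background (sigma
`wing.local_sigma` = 5 px, threshold `wing.ratio_threshold` = 0.78), which
is insensitive to the smooth sex-dependent abdominal gradient under the
wing. Two refinements keep the detection unbiased at boundaries: the red
local background is estimated separately on the body and off-body domains
by normalized convolution (no spurious contrast ring at the body edge), and
a second pass re-estimates it with first-pass detections excluded, so the
core of the thick vein-convergence blob at the hinge cannot suppress its
own contrast.

The mask is cleaned (components ≥ `wing.min_object_px`), split by body
side, and thinned to a 1 px skeleton (Zhang–Suen; no installed package
provides skeletonization). Template fitting then proceeds in two stages:

1. **similarity initialization + trimmed ICP.** The canonical template
   (outline through hinge and tip, veins L2–L5 as quadratic Béziers from
   the hinge) is placed by principal-axis/extent matching, trying both axis
   directions and both chiralities, and refined by ~12 iterations of
   trimmed (92 %) iterative-closest-point with a closed-form similarity
   Procrustes update.
2. **assignment / B-spline refit loop.** Skeleton points are assigned to
   their nearest template curve (carrying the curve parameter), and each
   curve is refitted as a cubic B-spline — periodic with 12 control points
   for the outline, clamped with 6 per vein — by least squares, with the
   ridge *anchored to the transformed template control points* so spline
   spans with little data follow the template instead of collapsing.
   Points farther than 5 px from every fitted curve are dropped as
   contamination. The loop stops when control points move < `wing.tol_px`
   (0.1 px) or after `wing.max_iter` (20) iterations; non-convergence is
   flagged, not fatal. A vein with under 12 assigned points or under 30 %
   parameter coverage is flagged unfitted; WL and WW are computed whenever
   the veins they need (L3; L2 + L5) are available.

Landmarks: each vein's distal end projects to the nearest point of the
fitted outline; the hinge is the convergence point of the fitted veins'
proximal ends, falling back to the similarity-mapped template anchor when
they disagree by more than 4 px (the convergence point tracks the true
hinge more precisely on 1 px skeletons than the mapped anchor alone).
WL = |hinge − outline∩L3|, WW = |outline∩L2 − outline∩L5|, WA = shoelace
area of the outline sampled at 512 points. One wing per fly is reported —
the side with the better fit quality (mean skeleton-to-curve distance),
mirroring the manual convention of measuring an intact wing.

## Validation statistics

`bisquare_regression()` is iteratively reweighted least squares with Tukey
bisquare weights, tuning constant c = 4.685, and scale
`median(|r|) / 0.6745` recomputed each iteration — the scale is taken about
zero (the model already has an intercept): taking it about the residual
median can collapse to all-zero weights when a gross outlier drags the
initial least-squares fit. Percent residuals are
`100 (y − fit(x)) / x` with x the manual value (a raw `(y − x)/x` mode is
available). Boxplot summaries use type-7 quartiles and flag outliers beyond
1.5 box-widths outside the quartiles. Sexes are pooled in the regression.

## The synthetic generator, and what passing tests do not show

`sample_fly()` draws a fly from a population model: sex-specific overall
scale (canonical female 1, male 0.88, CV 4 %), three overlapping body
ellipses with 3–4 % per-axis jitter, wing length normal with mean 100 px
(female) / 85 px (male) and SD 5 px, jittered wing aspect ratio
(0.235 ± 0.008), vein anchor angles (± 0.03 rad) and low-order outline
harmonics, an interocular distance of 0.60 ± 0.025 of the head width, a
male dark posterior abdominal band versus a female ramp-with-banding
gradient, and a sex comb (radius 1.5–2 px, so ~7–13 px²) rendered on the
foreleg tip in 60 % of frames for males. `render_sequence()` renders 8-bit
quantized frames (default 600 × 1800 px portrait tunnel, 6 frames,
Gaussian sensor noise SD 2/255) with per-frame pose jitter (± 15 px,
± 3°) and moving legs, plus configurable nuisance frames: defocus,
border contact, saturated wing reflections, and a folded wing. Identical
seeds give byte-identical output, and every ground-truth trait is defined
by the same geometry that is rendered.

The generator emulates the *structure* of tunnel imagery, not its
photometric realism: no 3D posture (the dominant real-world error source
for body traits), no occlusion between legs and wings, no illumination
drift, no motion blur, and luminance patterns far cleaner than real
cuticle. Recovery statistics on generator output therefore demonstrate the
correctness and numerical stability of the operators, not field accuracy
on real flies.

## Problem sizes and numerical conventions

The packaged tests and the acceptance script use 50-fly populations at the
default frame size and 6 frames per fly, 100-frame sequences for the
nuisance grid, and n = 147 for the residual-SD sampling check, with fixed
seeds throughout. Degenerate inputs follow a fail-soft contract inside the
batch driver: a failed stage (ocelli not found, wing not fitted) yields a
partial record with `NA` fields and a note; an unaccepted sequence keeps
its row with the rejection reason. Ties are deterministic everywhere
(first-wins frame selection, `fly_id` order in selection ranking).

## Known limitations

* Body-trait accuracy is bounded by the percentile projection's erosion of
  the silhouette under residual alignment error; shoulder width in
  particular carries a systematic negative offset relative to the
  generating ellipse width, which the validation regression absorbs.
* The sex-comb detector assumes the comb region reaches anterior of the
  head; a fly photographed with forelegs tucked would fall back to the
  luminance route.
* The wing fitter assumes four longitudinal veins in a fan; heavily damaged
  wings are better excluded via the well-exclusion mechanism than measured.
* Real-data use requires re-deriving the luminance templates and the
  ocelli template from manually annotated flies; both are user-replaceable
  artifacts.
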