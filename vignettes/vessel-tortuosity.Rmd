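---
title: "Measuring retinal vascular tortuosity from flat-mount segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vascular tortuosity from flat-mount segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltort)
```

## Background

In the murine oxygen-induced retinopathy (OIR) model, pups are exposed to
hyperoxia from postnatal day (P) 7 to P12; the resulting vaso-obliteration
(VO) creates an ischemic drive that triggers pathological
neovascularization (NV) peaking around P17 and partially resolving by P25.
Alongside NV and VO, the major retinal vessels become visibly tortuous, as
they do in human ischemic retinopathies where tortuosity ("plus disease" in
retinopathy of prematurity) guides treatment decisions. `vesseltort`
quantifies this third phenotype from the same flat-mount images used for NV
and VO analysis.

The input contract is deliberately minimal: an 8-bit single-channel raster
in which any nonzero pixel is vessel (manual segmentations from raster
editors are binary by construction, hence the default threshold of 1), plus
the optic-disc center coordinates. Coordinates are `(row, col)`, 0-based,
row 0 at the top; files recorded in `(x, y)` order are converted with
`xy_order = TRUE` (CLI `--xy-order`). Physical pixel size is optional
metadata only — every metric in scope is dimensionless or reported in pixel
units.

## Pipeline

1. **Skeletonization** (`skeletonize_mask`). Zhang–Suen two-subiteration
   thinning reduces the mask to a unit-width, 8-connected skeleton. Two
   amendments matter in practice. First, deletions within a subiteration
   are committed topology-safely: mutually non-adjacent candidates are
   removed in parallel, adjacent ones sequentially with a simple-point
   (Hilditch crossing number) recheck. Plain parallel commits can erase a
   2-px-wide diagonal stage of a vessel cap wholesale, amputating 10–20 px
   of tip. Second, a sequential simple-point cleanup removes the 2-px
   staircase leftovers the parallel scheme produces, so the result is
   minimal and the whole operation is idempotent.
2. **Vessel graph** (`build_vessel_graph`). Every skeleton pixel is a node;
   edges are the 8-adjacencies; node class follows degree (endpoint 1,
   slab 2, branch 3+, isolated 0).
3. **Disc exclusion** (`exclude_disc_region`). Nodes within
   `disc_radius_px` (default 50) of the disc center are removed. The disc
   is the confluence of all major vessels; junction geometry there is
   degenerate and segment decomposition ill-defined. Radius 0 disables.
4. **Segment extraction** (`extract_segments`). Terminal spurs shorter than
   `spur_length_px` (default 10) are pruned to a fixed point — thinning
   sprouts such twigs at boundary irregularities. Maximal slab chains
   between terminals (endpoints, branch pixels) become segments; chains
   shorter than `min_length_px` (default 20) are dropped; each chain is
   oriented so its first point is nearer the disc. Free tips
   (endpoint-terminated ends) are extended to the mask boundary minus the
   estimated stroke radius, compensating the ~half-stroke-width tip
   retraction inherent to thinning; the extension ray is the local tangent
   unless a small cone search finds a clearly longer in-mask run (the
   amputated-tip signature). Ends cut by disc exclusion are not extended.
   The stroke width is estimated from mask area and skeleton length under a
   stadium (rounded-cap) model.
5. **Per-segment metrics** (`segment_tortuosity`) and image summaries
   (`image_tortuosity`), described next.

Isolated cycles (closed loops with no junction) are not traced; segments
whose chord is shorter than the resampling spacing are flagged and excluded
from image means.

## The tortuosity estimator

Each segment chain is resampled at 1 px arc spacing, position-smoothed by a
centered moving average over `smoothing_window` px of arc (default 9;
windows shrink symmetrically at the ends so endpoints are preserved
exactly), and resampled at `spacing_px` (default 5). Resampling to uniform
arc length *before* smoothing makes the filter direction-independent —
a fixed pixel-count window would be √2 wider along diagonal runs.

**CTI** is the arc-to-chord ratio of this polyline. It is scale invariant,
equals 1 for straight vessels, and matches the reported range of
disc-rooted tortuosity indices in both healthy (≈1.0) and diseased (≈1.1+)
murine retinas. The verbal alternative — accumulated turning normalized by
vessel length — is available as `cti_formula = "angle_sum"`
(`1 + IC/L`, rad/px); it is pixel-scale dependent and kept for sensitivity
analysis only.

**Turning angles.** The tangent angle `phi(s)` of the polyline is unwrapped
and smoothed with a moving average over `tangent_window_px` (default 35 px);
turning angles are `theta_i = |diff(phi)|`. Three guards separate real
curvature from rasterization noise:

- *Dead-band*: a digital straight line carries up to 0.5 px of lateral
  quantization, which survives smoothing as spurious angles of up to
  ≈0.02 rad; angles below `angle_floor_rad` (default 0.03) are zeroed, with
  a soft linear shoulder up to 4/3 of the floor so that angles jittering
  across the threshold do not flip IC discontinuously. The price is a
  detection floor: curvature below `angle_floor_rad / spacing_px`
  (0.006 px^-1, radius ≈ 170 px) reads as zero.
- *End weighting*: within `end_trim` spacings (default 5, i.e. 25 px) of a
  segment end, the truncated smoothing windows and the straight tip
  extension make angles unreliable; they are down-weighted to zero with a
  one-spacing linear ramp (a hard cut would make IC jump when resampling
  adds or removes a vertex).
- *Tangent smoothing*: the 35 px box filter suppresses alternating
  quantization angles while preserving the total turning of monotone
  bends. It also defines the estimator's passband: sinusoidal waviness of
  wavelength λ is attenuated by ≈`sinc(pi * 35 / λ)`, i.e. <5% for
  λ ≳ 240 px, ≈8% at λ = 150 px. Constant-curvature arcs are unaffected
  (a linear `phi` ramp passes a box filter unchanged). CTI does not use
  angles and has no such passband.

**IC** is `sum(w_i * theta_i)` with the end weights `w_i`; **OC** is IC
divided by the end-trimmed measured length in spacings (a continuous
denominator; an angle count would be quantized by the resampling grid).
Image-level values are unweighted means over non-flagged segments
(`aggregate = "length_weighted"` is available).

These defaults were calibrated on rasterized phantoms: straight tubes at
all orientations must produce exactly zero IC/OC and CTI within 0.005 of 1;
a rasterized semicircle (r = 100 px) and one-period sinusoid
(a = 10, λ = 100) must recover their quadrature arc/chord ratios within 1%.
The test suite asserts all of these, plus recovery of ground-truth
arc/chord within 2% across amplitudes 0–40 px and stability of image
CTI/IC/OC under 30° rotation plus translation within 0.5%. Residual
rigid-motion sensitivity of IC/OC is dominated by ±0.5 px tip-placement
noise and dead-band crossings and was measured at ≈0.1–0.6% across seeds;
CTI is an order of magnitude more stable.

## Supporting modules

- **Agreement**: `dice_coefficient` (`2|A∩B| / (|A|+|B|)`) and
  `pairwise_dice` over all grader pairs (k graders → k(k−1)/2 values).
  Two empty masks return 1 with a warning — vacuous agreement almost
  always indicates an input problem.
- **Ratios**: `area_ratio` divides pathology area by the reference region —
  the whole image by default (the flat-mount crop is the operative area), a
  retina-region mask optionally. `apply_override` records expert
  corrections (e.g. VO falsely detected in normoxic retinas over lighter
  pigmentation) with the original value and a mandatory reason.
- **Group statistics**: exactly two groups use the classical
  equal-variance unpaired Student *t* test (Welch via `welch = TRUE`);
  three or more use one-way ANOVA. Stars follow the strict scheme
  `* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001` (so p = 0.05 is `ns`).
  Identical groups (0/0 statistics) report statistic 0, p = 1. No
  multiple-testing correction is applied, and that is recorded here rather
  than hidden.

## The synthetic flat-mount generator

`generate_retina` lays out `n_vessels` (default 8) radial centerlines from
the disc, each perturbed perpendicular to its radial direction by
`a * env(t) * sin(2*pi*t/lambda + phi)`. Defaults and their reasons:

- `wavelength_px = 150`: the minimum curvature radius of the perturbed
  centerline is `lambda^2 / (4*pi^2*a)`; at the largest amplitude of
  interest (a = 40) this is ≈14 px, safely above the stroke radius, so the
  rasterized tube never self-overlaps. At λ = 100 and a = 40 it would not
  be.
- `taper_px = 100`: the amplitude ramps from 0 at `r_start_px` (default 30)
  to full over 100 px, mirroring the straighter peri-papillary course of
  real vessels and preventing adjacent-vessel collisions near the
  confluence at high amplitude.
- `amplitude_px = 20` with `amplitude_jitter = 0.15`: a strongly tortuous,
  disease-like phenotype with per-vessel biological variability; a = 0
  gives exactly straight vessels, and amplitude is the single tortuosity
  dial.
- `stroke_width_px = 5`, image 1024²; rasterization stamps a disc of the
  stroke radius along the centerline sampled every 0.25 px so no gaps
  appear.

Ground truth is computed *before* rasterization: composite Simpson
quadrature (2001 nodes) of the analytic speed `sqrt(1 + off'(t)^2)` gives
each vessel's arc length, and the chord comes from the continuous
endpoints; `true_ratio = arc/chord` is the quantity the pipeline should
recover as CTI. Optional branches (`branch_prob`) make images more
realistic, but per-vessel correspondence between truth and measured
segments is only exact without them, so validation phantoms default to
unbranched vessels. Rigid motion (`rotation_deg`, `offset_px`) is applied
to the continuous centerlines, so invariance tests compare
re-rasterizations of identical curves; such tests must pin `r_end_px` so
the moved field still fits inside the frame.

What the phantoms do *not* emulate: capillary beds, neovascular tufts, VO
zones, vessel calibre variation, staining artifacts, or segmentation error.
Passing the synthetic validation therefore demonstrates that the geometry
pipeline is accurate on clean vessel-like shapes, not that segmentation
noise on real data is harmless — on real images the quality of the input
segmentation remains the dominant error source.

## Problem sizes and determinism

The test suite and the acceptance script run the cohort checks on 512²
phantoms (8 vessels each, n = 20 per group) and the recovery and
rigid-motion checks on 1024² phantoms; these sizes keep every acceptance
check well-resolved (vessel spans of 200–450 px at spacing 5 px) while the
whole suite completes in a few minutes on one CPU. All randomness flows
from explicit seeds; `generate_retina` is bit-reproducible for a fixed
seed, and identical configurations hash identically (`config_hash`) in
every output table.

## Known limitations

- Curvature below `angle_floor_rad / spacing_px` is deliberately invisible
  to IC/OC; gently curved vessels (radius > ≈170 px) read as straight.
  CTI still detects them.
- Waviness below λ ≈ 100 px is attenuated in IC/OC by the tangent filter's
  passband (CTI is unaffected); at the default spacing, wavelengths under
  ≈30 px are unresolvable outright.
- Closed vascular loops are not traced; vessels whose skeleton chord is
  shorter than the spacing are flagged out of image means.
- The segment decomposition treats each junction-to-junction span
  independently; no artery/vein classification, no vessel-width or
  dilation measurement, and no attempt to stitch segments across
  junctions into anatomical vessels.
- NV/VO masks are consumed, not produced: the package does not segment
  pathology, it quantifies and audits externally produced masks.
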