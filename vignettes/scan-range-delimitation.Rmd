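---
title: "Automated scan-range delimitation and its dosimetric accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scan-range delimitation and its dosimetric accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoutrange)
```

## The problem

Before a helical chest CT acquisition, the technologist marks the
craniocaudal scan range on a low-dose 2D scout (localizer) image. Marking
generously is the path of least resistance — missing a costophrenic recess
can void the study, while a few extra centimetres of coverage are invisible
in the reading room. The result is systematic *overscanning*: coverage
beyond the lungs that irradiates the thyroid, liver, stomach and other
organs for no diagnostic benefit. `scoutrange` implements an automated
alternative and the accounting needed to quantify what overscanning costs:

1. synthesize scout-like projections from a 3D volume (or ingest real
   scouts),
2. segment the lungs on the 2D image,
3. convert the 2D mask to a scan range with a one-voxel safety margin,
4. compare ranges (exact / human / predicted) in millimetres of signed
   overscan and in effective dose.

All coordinates share one convention: slice 1 is most superior, z (mm, at
slice centers) grows caudally, range limits are inclusive. Signed errors
follow the radiological convention: positive = overscan, negative = missed
lung.

## The synthetic phantom: what it emulates and what it does not

Every stage is testable offline because `generate_phantom()` produces the
study conditions synthetically: an elliptical soft-tissue body (+40 HU)
containing two lungs (−800 HU) with linearly tapered apices and a slanted
costophrenic recess (posterior recess deeper than anterior, so the most
inferior lung slices contain only a thin posterior sliver — the hardest
part of real delimitation), a vertebral bone column (+700 HU), optional
consolidation (−100 HU) with basal/peripheral predominance, and additive
Gaussian HU noise.

Defaults were chosen once, as plausible adult-chest magnitudes, and define
the benchmark conditions:

* body diameters 23.3 × 31.1 cm (AP × lateral) — typical cohort means for
  an adult referral population; tests vary them over 20–26 × 28–34 cm;
* grid 96 × 96 × 64 at (3.75, 3.75, 2.5) mm — a desk-scale grid that keeps
  a 100-phantom cohort under a minute while leaving the geometry
  (taper ≈ 30 mm, slant ≈ 25 mm) several voxels wide;
* noise SD 20 HU, consolidation fraction 0.1 — enough to stress
  segmentation without simulating scanner physics;
* tube-current modulation `ma = base * (A / mean(A))^0.5` clipped to
  [0.2, 3] × base, where `A` is the slice attenuation sum — the
  qualitative craniocaudal TCM pattern of clinical scanners.

What the phantom does *not* emulate: heart and vasculature, respiratory
motion, beam hardening and scatter, vendor scout post-processing. Passing
tests therefore demonstrate the pipeline's internal consistency and its
behaviour under controlled difficulty (faint apices, slivers, noise,
consolidation), not clinical-grade segmentation accuracy.

Simulated operator ("human") ranges extend the true range by draws from
per-direction Normal distributions, truncated at zero by default (clinical
audits find overscan in well over 95% of cases; a flag allows untruncated
draws, used for distributional parameter recovery). The defaults —
superior 26.0 ± 9.2 mm, inferior 38.1 ± 21.0 mm — are the operator
statistics of a large single-center clinical audit. Only mean ± SD are
published for such audits; the Normal form is this package's assumption.

## Projection and the row-to-z contract

`project_volume()` forms a line integral of `max(HU + 1000, 0)` along the
AP or lateral axis, scaled by the ray step. Using the attenuation proxy
rather than raw HU sums makes air contribute exactly zero and keeps pixel
values non-negative, matching radiographic appearance; total projected
attenuation is conserved to floating-point precision, which the tests
assert. Published work on localizer synthesis says only that slices are
"summed"; the attenuation-weighted form is this package's choice and is
recorded in the projection object.

Masks are projected by logical OR, so the set of occupied image rows
equals the set of lung-bearing slices *exactly* — this is the property
that makes 2D range selection equivalent to 3D range selection at native
resolution, and it is tested exactly on 100 random phantoms.

Every 2D object carries an affine `z(r) = z0 + (r − 1) dz`. Min-max
normalization to [0, 1] (the normalization record is kept so it can be
inverted in reports) and resizing to 256 × 256 (bilinear for intensity,
nearest-neighbour for masks, anisotropic for non-square inputs — no
padding) update the affine so each resampled row addresses the same
patient z interval; round trips are exact.

Scout geometry is emulated by `apply_magnification()`: column coordinates
scale by `M = SDD/(SDD − y)` about the image center, rows are untouched
because scout acquisition translates the table along z. Real scout
magnification varies with depth along each ray; a single imaged-plane
offset `y` is the 2D approximation available once the volume has been
projected, and it reproduces the limits that matter (M(0) = 1,
parallel-beam limit, invertibility for |y| < SID).

## Segmentation: network and classical oracle

The learned segmenter is a 2D residual dilated convolutional network: 20
convolutional 3 × 3 layers, every two forming a residual block, with
per-block dilation factors (1, 1, 2, 2, 4, 4, 8, 8, 4, 2) replacing
pooling as the mechanism for multi-scale context, and a 1 × 1 sigmoid
scoring head. Published descriptions of this architecture family fix the
layer count, the residual span and the dilation idea but not widths,
loss or optimizer; the package's choices are: per-block widths
(default 8 at input 64 for the desk-scale benchmark; any widths are
configurable), Dice + cross-entropy loss, Adam at lr 1e−3, probability
threshold 0.5, He initialization. Since no deep-learning framework is part
of this package's stack, the forward/backward passes are implemented here
(im2col/col2im gather-scatter in compiled code, matrix products through
BLAS) and verified against numeric differentiation to ~1e−9 relative
error.

The desk-scale training protocol — 200 synthetic AP projections at
64 × 64, 70/10/20 split, 10 epochs, batch 8 — reaches held-out Dice
≈ 0.95 in a few minutes on one CPU. This protocol is a property-level
rerun of the full-scale idea (tens of thousands of 256 × 256 images); it
demonstrates that the architecture learns the task, not that the weights
match any clinically trained model. Fine-tuning (warm-starting `train()`
from an existing model) transfers the projection model to magnified
"scout-mode" images, the synthetic analogue of adapting to real
localizers.

`classical_segment()` is the deterministic oracle/fallback, so range
selection can be tested without training: body = largest connected
component above the air floor, holes filled; a per-column background is
the column maximum over body rows (valid because every column contains
lung-free slices); lungs are found by hysteresis on the relative
attenuation deficit (strong 0.08 seeds, weak 0.025 extension). The weak
level exists because thin structures — tapered apices, the costophrenic
sliver — attenuate only a few percent below background; a single
threshold either misses them or floods the body. Holes are filled and the
two largest components kept (in the lateral view both lungs project onto
one component; keeping two is then harmless).

Dice uses the convention that two empty masks agree perfectly (1.0).

## Range selection

`postprocess_mask()` removes components below 50 pixels (at 256 × 256)
while always keeping the largest — published descriptions say only
"a certain number of pixels", so 50 is a package default; it is idempotent.
`mask_to_range()` takes the first and last occupied rows, widens by a
one-voxel margin per direction (clipped to the image), and maps rows to z
through the affine. AP and lateral ranges combine by limit-wise averaging
by default: published per-view and combined error tables place the
combined limits between the single-view limits, which motivates averaging
but does not prove it, so union and intersection are provided as explicit
alternatives rather than guessed away.

## Dosimetry

Per scenario (exact / human / predicted) the package computes:

* effective diameter `sqrt(D_AP × D_Lat)` from a body mask at the
  mid-lung slice (threshold −300 HU, largest component);
* SSDE = f(D_eff) × CTDIvol with the published 32-cm-phantom exponential
  conversion fit `f = 3.704369 exp(−0.03671937 D)`, valid on 6–55 cm and
  checked against printed table values in the tests;
* regional tube current: per-slice mA averaged over the lung range, the
  selected slices cranial to it, and caudal to it; regional CTDIvol scales
  by regional-to-whole-scan mean mA, and DLP is the sum of regional
  CTDI × length products (additive by construction, asserted to 1e−9);
* organ doses via a *declared simplified surrogate*: in-field organ
  segments receive the regional SSDE; out-of-field dose decays as
  `exp(−d/λ)` from the nearest field edge with λ = 30 mm. The organ dose
  is the closed-form length-weighted mean over the organ's craniocaudal
  extent in a reference frame where overscan lengths are rescaled by the
  reference-to-patient lung-length ratio (reference lung 240 mm). λ = 30 mm
  was fixed once: it yields non-zero but rapidly decaying out-of-field
  organ dose, the qualitative behaviour of scatter, and the identities the
  tests check (bounded by SSDE, monotone in field length, exact
  closed-form tail) hold for any positive λ;
* effective dose as the ICRP-103 tissue-weighted sum; weights are bundled
  (remainder tissues share the remainder weight equally) and must sum to
  1 at load time.

The organ z-extent table bundled with the package is a synthetic
stand-in: plausible adult anatomy relative to the lung top, *not* values
from any computational-phantom library or commercial dosimetry tool. The
surrogate reproduces structure and identities — ED(exact) ≤ ED(nested
predicted) ≤ ED(human), DLP/length proportionality at constant CTDI, the
decomposition of human ED into exact + superior + inferior contributions
(exact in constant-current mode because the three field modifications
affect disjoint z regions) — but its absolute organ doses are
configuration, not clinical claims. Monte-Carlo transport and
scanner-specific spectra are out of scope.

## Numerical choices and degenerate inputs

* Constant-intensity projections normalize to all zeros with a warning;
  segmentation on them raises "no body found".
* Empty 2D masks: projection of an empty 3D mask warns; `mask_to_range()`
  on an empty mask is an error ("no lung found"); post-processing an empty
  mask warns and returns it.
* The SSDE conversion refuses diameters outside the published 6–55 cm
  domain rather than extrapolating.
* TCM region means over zero slices propagate as `NA` and drop out of the
  regional DLP sum.
* All randomness (phantoms, draws, splits, initialization) flows through
  explicit integer seeds; the pipeline derives per-stage child seeds from
  the master seed by a fixed documented formula, and reruns are
  bit-identical.
* Channel-width changes across residual blocks use zero-padding /
  truncation skips (no learned projections), keeping the parameter count
  honest for the layer count.

## Problem sizes used by the shipped tests

The test-suite and acceptance script sizes are package choices balancing
statistical force against a single-CPU workflow: 100 phantoms for the
exact 2D/3D range equivalence, 1000 random masks against the brute-force
oracle, 10 000 draws for parameter recovery, 20 noiseless phantoms at
256 × 256 for the classical error bounds, and the 200-image / 10-epoch
training protocol described above.

## Known limitations

* The phantom's difficulty is controlled, not clinical; Dice values here
  do not transfer to patients.
* The magnification model is a single-plane approximation of depth-
  dependent scout distortion.
* The organ table and scatter surrogate are synthetic configuration; only
  relative, structural dose statements should be read from them.
* DICOM ingestion covers uncompressed explicit-VR little-endian axial
  series (the tags the pipeline needs); compressed transfer syntaxes and
  sequence elements are not parsed.
* Training is CPU-bound R + BLAS; the default protocol is sized for
  minutes, not for large-scale experiments.
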