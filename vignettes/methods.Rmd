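---
title: "Measurement methods and design notes"
author: "usquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model behind `usquant`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-phantom validation does and does not
demonstrate. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Scope and assumptions

`usquant` measures 2-D B-mode scans of two regions in two planes:
longitudinal and transverse scans of the abdomen and of the anterior
thigh. The method assumes:

* the scan is grayscale (colour input is collapsed with luma weights
  0.299/0.587/0.114) with brighter pixels meaning stronger reflection;
* the informative echo field is a contiguous rectangle surrounded by a
  near-black frame, and it straddles the image centre;
* the target anatomy is framed inside the echo field — an interface
  cropped by the field edge is out of scope;
* anatomical interfaces (skin base, fascia, aponeuroses, peritoneum)
  appear as roughly horizontal bright bands ordered superficially to
  deep;
* the scan type is declared via the file-name code (or supplied
  explicitly); automatic scan-type recognition is deliberately not
  attempted.

## Pipeline order

ROI detection runs on the *raw* intensities and only then is the ROI
filtered, because the centre-out boundary scans key on sharp intensity
transitions that smoothing would displace. An integration test asserts
this ordering by constructing a 1-px bright border line that survives ROI
detection but not filtering.

### ROI detection

From the middle column, the scan walks left and right (restricted to a
vertical band, by default the middle half of the image height, to avoid
on-screen annotations) to the outermost columns whose band maximum
exceeds a threshold; then, restricted to those columns, up and down from
the middle row. Defaults: threshold 10/255 (the black frame is what must
be skipped), band [0.25, 0.75], minimum ROI area 256 px. A column counts
as informative when its band *maximum* exceeds the threshold — a
deliberate choice that is robust to sparse speckle and is mirrored
exactly by the brute-force oracle in the tests. All coordinates in the
package are row-major, 0-based, half-open.

### Bilateral filter

Intensities are normalized to [0, 1]; each output pixel is the
spatial-Gaussian x intensity-Gaussian weighted mean of its window
(sigma_spatial = 5 px, sigma_intensity = 0.1). The window is 11 x 11 at
the defaults (radius = round(sigma_spatial)); neighbours outside the
image are excluded with weight renormalization, so output values are
convex combinations of inputs and never leave the input range. The
intensity sigma of 0.1 only makes sense on a normalized axis, which is
why the pixel-unit sigma is read as the spatial one — with both sigmas
configurable should a different reading be wanted.

### Template matching and structure detection

The filtered ROI is affinely rescaled to 0–255 bytes (a constant image
maps to zeros — it carries no information). Matching uses zero-mean
normalized cross-correlation (ZNCC, the Pearson correlation of window
and patch), which is invariant to affine intensity changes; the raw
correlation variant (`method = "ccorr"`) is kept behind a switch for
fidelity experiments but is brightness-biased and not the default.

`matchTemplate()` itself is the classic primitive: score every offset,
return the arg-max (ties resolve to the first offset in column-major
order). The *detector* wraps it differently, and this is the package's
central design decision: in a layered scan, different interfaces look
locally alike (a bright band over fat looks much like a bright band over
muscle once normalized), so a global arg-max may lock onto the wrong
band — one speckle realization is enough to flip a near-tie, after which
every subsequent structure shifts by one interface. The detector
therefore makes the search direction load-bearing:

* the **top-down pass** walks the depth axis downward and, per
  structure, accepts the *first contiguous run* of depths whose best
  column score reaches `acceptScore` (default 0.60), taking the run's
  score peak;
* the **bottom-up pass** does the same upward, starting from the deepest
  structure;
* after each acceptance, the admissible band for the next structure
  starts beyond the accepted band — beyond the accepted template's own
  supra-threshold run *and* at least half a window height past its peak.
  The margin matters: a different structure's template can still score
  above threshold on the near tail of an already-claimed band even where
  the claimed template's own run has ended;
* per structure, fallback variants (bilinear rescales at 0.9/1.1, then
  contrast remaps at 0.8/1.2 — the latter only effective under
  `"ccorr"`, since ZNCC is contrast-invariant) are tried in order until
  one yields an acceptable match;
* the two passes are fused per structure by keeping the higher accepted
  score (ties go to the bottom-up pass); structures neither pass finds
  are flagged `detection_failure` and their variables are simply absent
  from the record — never zero, so downstream agreement statistics are
  not contaminated.

Order validation then enforces strictly increasing interface depth along
the anatomical order and at most 50 % height overlap between consecutive
boxes, demoting the lower-score member of any violating pair.

Contour refinement binarizes the ROI at the Otsu level inside each
accepted box, applies morphological closing then opening with a disk of
radius 2 px (speckle-scale, too small to erode an interface band), keeps
the largest connected component, and re-estimates the interface depth as
the median row of the component's upper edge — the median being robust
to residual speckle along the edge. An empty mask falls back to the box
outline with a flag.

### Geometry

* **Thicknesses** (the Y-axis family, and the three abdominal fat
  variables) are calibrated differences of interface depths. The
  abdominal model uses five interfaces so that all three fat variables
  are defined: superficial subcutaneous fat = fascia − skin, total
  subcutaneous fat = muscle wall − skin, peritoneal fat = deep
  peritoneal boundary − peritoneum.
* **Widths** (the X-axis family) equal the ROI width. Whether a
  structure-specific width was meant instead is ambiguous in the
  underlying description; the ROI width is the documented choice here.
* **Areas**: muscle cross-sections that are roughly elliptical (the
  transverse rectus femoris) are fitted with the direct least-squares
  conic fit under the ellipse constraint 4AC − B² = 1 (stable
  block-decomposition form), applied to the boundary of the
  Otsu-segmented muscle belly between the two aponeuroses; area = πab.
  All other zones use the rectangular approximation height x width. The
  approximation used is recorded per record, and the ellipse fit falls
  back to the rectangle (flagged) if segmentation or the fit fails.
* **Calibration** comes from DICOM PixelSpacing (mm, converted to cm)
  when present, else a config value; otherwise measurements are reported
  in px/px² with a `units` flag rather than failing.
* The leg-longitudinal scans additionally report a "Subcutaneous Fat"
  thickness (skin to superficial rectus aponeurosis) — a variable that
  appears in the clinical reporting tables without a formal definition;
  it is emitted only when both bounding interfaces are detected.

### Texture features

The seven image-characteristic variables are computed on the full
preprocessed ROI: six gray-level co-occurrence features (ASM, contrast,
correlation, dissimilarity, entropy, homogeneity) plus the histogram
mean (numerically the mean byte value). GLCM construction parameters are
nowhere specified in the source description, so the defaults follow
common musculoskeletal-ultrasound texture practice: 32 equal-width
levels, offset distance 1, four angles (0, π/4, π/2, 3π/4), symmetric,
features averaged over angles — all configurable. Entropy is
co-occurrence entropy in bits (log₂). Degenerate correlation
(zero marginal variance) is defined as 0. Homogeneity defaults to the
inverse-difference-moment form 1/(1+(i−j)²), with the 1/(1+|i−j|)
dialect available as an option.

### Agreement statistics

Bland–Altman: differences d = auto − manual, bias = mean(d), limits of
agreement = bias ± 1.96·sd(d) with the sample (n−1) SD, and a 95 % CI of
the bias of ± 1.96·sd(d)/√n. The 1.96 multiplier is fixed (not t-based),
matching the standard formulation. Precision = 100 − MAPE, clipped below
at zero; the "adjusted" precision of the original report is not printed
anywhere as a formula, so 100 − MAPE is implemented as stated, with a
seeded bootstrap (2000 resamples) available for its 95 % CI.

## The phantom generator

Clinical scans are unavailable (privacy restrictions), so validation
runs on synthetic layered phantoms with exact ground truth. A phantom is
a piecewise-constant depth profile (zone means 35–75) with bright bands
(185–210, 5 px thick) at the declared interface depths, an optional
elliptical muscle-belly inclusion for leg-transverse scans, multiplied
by log-normal speckle with unit mean (exp(N(−σ²/2, σ²)), σ = 0.25 by
default), clipped to 0–255, inside a 20 px black frame; 300 x 260 px at
0.01 cm/px. Default layouts mirror the scanned anatomy: five abdominal
interfaces (skin at 50, fascia 110, muscle wall 170, peritoneum 210,
deep boundary 260 — 0.6/1.2/0.5 cm fat variables) and four leg
interfaces (45/85/165/235 — 0.8 cm rectus, 0.7 cm vastus); the
leg-transverse inclusion is derived to fit the rectus compartment.
Cohorts jitter interface depths by ±10 px and zone means by ±10 %, each
phantom with its own derived speckle seed; (spec, seed) fully determines
the image byte for byte.

Two validity rules encode the study conditions: bands must be strictly
ordered and non-overlapping, and every band must keep 8 px clearance
from the frame — a centred template window cannot reach a band at the
field edge, and a sonographer frames the target anatomy anyway. Draws
violating the rules are rejected and redrawn.

The multiplicative log-normal speckle reproduces the first-order
statistics that stress this pipeline (intensity-proportional grain,
bright-band dominance) at trivial cost; it is *not* a physical
scattering simulation. Consequently, phantom results demonstrate the
correctness and numerical robustness of the measurement chain — they do
not certify clinical accuracy, where tissue-texture variation, curved
interfaces, shadowing and probe-pressure deformation (none of which the
generator emulates) dominate the error budget. The simulated "expert
reader" (truth + Normal noise) plays the same role for the agreement
module.

## Problem sizes and numerical choices

The test suite validates each operation against independent brute-force
oracles (scalar-loop correlation, pair-enumeration GLCMs, full-scan ROI,
double-loop bilateral sums, Monte-Carlo ellipse areas) at sizes chosen
to keep the default run comfortably desk-scale: 100 random 16 x 16
windows for the texture oracle, 100 random 64 x 64 image / 9 x 9 patch
pairs for matching, 200 random ROI fixtures, 50 noisy 100-point
ellipses, and an end-to-end cohort of 50 phantoms (13/12/13/12 across
the four scan categories) measured with template libraries cut from
phantoms whose seeds are disjoint from every cohort seed.
`scripts/acceptance.R` re-runs the cohort experiment from scratch and
writes boundary/thickness/area recovery rates, precision percentages and
the Bland–Altman bias as JSON, with every random draw derived from its
`--seed` argument.

Numerical conventions worth knowing: byte rescaling rounds half-up and
maps constant images to zero; match-score ties take the first offset in
column-major order; the ellipse fit centres the points before building
the scatter matrices (conditioning) and reports orientation in [0, π)
with a ≥ b; interface rows may be half-integral after refinement
(median of an even count); all pipeline stages are deterministic — the
only RNG in the package lives in the generator, the reader simulation
and the bootstrap, each seeded explicitly and restoring the caller's RNG
state.

## Known limitations

* Interfaces must be near-horizontal bands; strongly curved or oblique
  fascia would need orientation-aware templates.
* The detector measures the scan type it is told; mislabelled codes
  produce wrong variable sets, not errors.
* Area precision is intrinsically lower than length precision: both the
  elliptical and rectangular approximations discard boundary detail, and
  mask discretization biases fitted areas by a few percent at phantom
  scale.
* DICOM support covers single-frame, uncompressed, 8-bit little-endian
  files (the export format of portable B-mode consoles); multi-frame
  cine loops and compressed transfer syntaxes are rejected explicitly.
* Only isotropic pixel spacing is supported; anisotropic DICOM spacing
  uses the row value.
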