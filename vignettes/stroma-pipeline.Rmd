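---
title: "From H&E tiles to survival groups: the StromaSurv pipeline"
author: "StromaSurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From H&E tiles to survival groups: the StromaSurv pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StromaSurv)
```

# The problem and the model

Stroma-rich carcinomas — pancreatic ductal adenocarcinoma being the
extreme case — embed their tumor glands in a desmoplastic stroma
infiltrated by varying numbers of lymphocytes. The area fractions of a
pathologist-outlined region of interest (ROI) occupied by stroma, tumor
and lymphocytes (SIP, TIP, LIP) are prognostic, but in a non-monotone
way: an *intermediate* stromal fraction is protective relative to both
stroma-poor and stroma-rich extremes, while high lymphocyte infiltration
is protective throughout. `StromaSurv` implements the measurement chain
(tiling → stain normalization → semantic segmentation → area
quantification) and the inference chain (optimal cutpoints → risk
groups → Kaplan–Meier/Cox) behind that statement, together with
synthetic generators that make every stage testable without clinical
data.

This vignette is the package's methods account: the procedures, their
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

# Tile geometry and the overlapping-tile strategy

Tiles are square patches of `inputPx = 396` pixels at `micronsPerPx =
0.25`, i.e. a physical side of 99 µm. Because the segmentation network
uses only unpadded convolutions, each 396-px input window predicts only
its central `outputPx = 212` window. `planTiles()` therefore places
*output* windows on a non-overlapping grid with stride 212 anchored at
the slide origin and keeps every window that touches the ROI; the
corresponding input windows (each output window dilated by
(396 − 212)/2 = 92 px per side) overlap. Coordinates are 0-based with
half-open windows, which makes the partition arithmetic exact: the kept
output windows are pairwise disjoint and cover every ROI pixel once, a
property the test suite checks pixel-by-pixel on random blob ROIs.

Where an input window leaves the slide, `extractInputWindow()` fills the
margin by mirror reflection about the slide edge (position −k maps to
k − 1). Reflection is the convention of the original valid-convolution
U-Net design; nothing in the quantification depends on it because
reflected pixels only ever feed the network's context margin, never the
output window.

Tiles whose output window only partially intersects the ROI are kept and
the out-of-ROI pixels are masked *after* stitching (`stitchTiles()` sets
them to the ignore sentinel 255). Discarding partial tiles instead would
bias the area accounting at the ROI boundary.

The ROI polygon is rasterized by even-odd scanline fill at pixel
centers — deterministic and checkable against a per-pixel ray-casting
oracle, which the tests do.

# Macenko stain normalization

`estimateStainProfile()` follows the classical recipe: convert RGB to
optical density (OD = −log10 I, with I floored at 1/255), discard
pixels with any OD channel below `betaOD = 0.15`, project the remaining
OD vectors onto the plane of their two leading singular directions, and
take the unit vectors at the `alphaPct = 1` and 99 angle percentiles as
the stain axes. β and α are the defaults of the method's original
description; the analysis they support is not sensitive to them because
normalization only standardizes appearance before segmentation.
Hematoxylin is identified as the column with the larger blue-channel
optical density. Per-pixel stain concentrations solve a non-negative
least-squares problem; with exactly two stains this has a closed-form
active-set solution (unconstrained 2×2 solve, refit one stain alone if
the other goes negative), so no iterative solver is involved. Robust
stain concentrations are 99th percentiles.

`normalizeTile()` rescales concentrations by the ratio of reference to
source maxima and re-composites with the reference stain matrix,
quantized to the 8-bit grid. Two numerical points worth knowing:

* When source and reference profiles are numerically identical the
  function short-circuits to the identity. The decompose/recomposite
  cycle would otherwise clamp the ~2 α % of pixels whose OD lies outside
  the non-negative cone of the estimated stain matrix.
* A tile with too few stained pixels (default `minPixels = 100`), e.g. a
  blank margin tile, raises an estimation error; `segmentSlide()`
  catches it and passes the window through unnormalized rather than
  inventing a profile.

The reference profile is estimated once from designated reference tiles
and stored as JSON (`writeStainProfile()`).

# The valid-convolution U-Net

`unetSpec()` describes the architecture: `depth = 4` pooling levels,
`convsPerBlock = 2` unpadded 3×3 convolutions per block, ReLU, 2×2
max-pooling, a two-convolution bottleneck, 2×2-stride-2
transpose-convolution upsampling, center-crop-and-concatenate skip
connections, and a 1×1 softmax head over 3 classes. `unetGeometry()`
traces the spatial size through every stage and raises an error naming
the offending stage for invalid geometries (non-positive size, odd size
before pooling, asymmetric skip crop). For the default spec a 396-px
input yields exactly a 212-px output:

```{r geometry}
unetGeometry(396, unetSpec())
```

Channel widths double per level from `baseChannels` (default 32, the
scale a GPU implementation would use; the tests train width-4 models).
The exact widths of the published figure are not stated in text, so they
are configurable rather than hard-coded.

Design choices where the source description is silent or ambiguous:

* **Loss**: pixel-wise categorical cross-entropy over non-ignored
  pixels. The ignore sentinel (255) masks out-of-ROI pixels from both
  loss and metrics.
* **Optimizer**: Adam with `lrInit = 1e-3`.
* **Dropout**: "10 % of pixels dropped after each convolution" is
  implemented literally as element-wise (inverted) dropout on feature
  maps, rate 0.10. Channel-wise ("spatial") dropout was considered and
  rejected: on narrow test-scale networks dropping one of four channels
  removes a quarter of a layer's capacity at once, and such nets
  reliably collapse onto the majority class.
* **"Training steps"** in the schedule rules are read as monitoring
  intervals of one epoch: the learning rate is multiplied by
  `lrFactor = 0.1` (a 90 % reduction) after `plateauPatience = 3`
  epochs without improvement of the monitored loss, and training stops
  after `earlyStopPatience = 5`; `maxEpochs = 50`, `batchSize = 160`.
  `plateauSchedule()` exposes these semantics as a pure function so they
  are testable in isolation.
* **Class imbalance** is left unweighted: the training data (synthetic
  or curated tiles) is expected to be reasonably balanced, and an
  optional weighting was judged not worth the extra surface.

The entire network, including backpropagation, is written in
R/RcppArmadillo (im2col + GEMM convolutions with patches-in-rows memory
layout). Analytic gradients are verified against central finite
differences for every layer type in the test suite (relative error
< 1e-3 at ε = 1e-6, typically ~1e-9).

`predictTile()` takes the per-pixel argmax with ties broken toward the
lower class index; `evaluateSegmentation()` pools pixel counts over
tiles and reports per-class IoU (classes absent from both prediction and
truth are excluded from the mean), mean IoU and categorical accuracy;
`diceScores()` the analogous Dice coefficients.

# Synthetic scenes: what they emulate and what they do not

`generateTileScene()` paints, in order: a pink fibrous stroma background
(superposed oriented sine waves, contrast set by `stromaFiberDensity`),
`tumorGlands` ring-shaped gland structures (perturbed-circle polygons
with a dark rim and pale lumen; the whole gland counts as tumor),
and `lymphClusters` clusters of small dark basophilic discs (drawn last,
overriding tumor). The mask is painted by exactly the same geometry, so
ground truth is exact by construction — the point of a procedural rather
than generative-model appearance. Pixel noise and per-channel
multiplicative log-normal stain jitter (`stainJitter = 0.03`) provide
appearance variation; output is quantized to the 8-bit grid so PNG
round-trips are exact.

Defaults are chosen to make the default scene's composition clinically
plausible for a stroma-rich carcinoma: ~80 % stroma, ~17 % tumor and
~2.3 % lymphocytes on a 396-px canvas (`lymphClusters = 6`); the
published LIP cut-offs fall in 0.01–0.03, so scenes carry lymphocyte
fractions on that scale.

What the generator deliberately does **not** emulate: nuclear
morphology, scanner artifacts, pen marks, tissue folds, out-of-focus
regions, or realistic inter-laboratory stain variation. Consequently,
passing segmentation tests demonstrate that the architecture, the
training loop and the tile plumbing are correct and can learn
color/texture-separable tissue classes — they say nothing about
performance on real slides, which is a property of training data, not of
this code.

`generateSlide()` abuts scenes (derived per-scene seeds; a 1×1 slide is
bit-identical to the single scene) and supplies a rectangular ROI
strictly inside the slide as a stand-in for the pathologist's outline.

# Synthetic cohorts

`generateCohort()` draws SIP ~ Beta(4, 2) (mean 2/3; the marker mass
straddles the true band) and LIP ~ Beta(1.4, 45) (mean ≈ 0.03, ~43 %
below the true cut — the scale of published LIP cut-offs), assigns each
patient to the {SIP-intermediate, SIP-LH} × {LIP-low, LIP-high} cell via
the true cuts (`sipCutsTrue = c(0.54, 0.75)`, `lipCutTrue = 0.02`), and
draws exponential event times with the cell's rate. Default rates come
from the ln 2 / median-OS scale of published pancreatic-cancer groups:
0.025 /month for the doubly favorable cell (median 28 months) up to
0.085 /month for the doubly unfavorable one (median 8 months). Censoring
is an independent exponential (0.01 /month) plus an administrative
cutoff at 84 months — the source analyses say nothing about their
censoring process, so the simplest independent mechanism is used.
Covariates (age, sex) are generated independently of survival, which
makes them exact null variables for the Cox screens.

# Quantification

`quantifySlide()` counts ROI pixels per class and applies
`A_Stroma = A_ROI − (A_Tumor + A_Lymphocytes)`; all arithmetic happens
on integer pixel counts before any division. One floating-point
subtlety: the three fractions are stored as `sip = A_Stroma/A_ROI`,
`lip = A_Lymph/A_ROI` and `tip = 1 − (sip + lip)`. Storing TIP as the
exact complement guarantees `sip + lip + tip == 1` in IEEE arithmetic
for every mask (naive triple division violates exact equality for ~7 %
of count triples); `tip` equals `A_Tumor/A_ROI` to within one ulp.
Patients with several slides are aggregated by ROI-area weighting
(equivalently: pooled pixels), LIP counts all lymphocyte pixels in the
ROI (not only stromal ones), and fractions are kept at full double
precision.

# Optimal cutpoints

**Binary (LIP).** `maxstatBinary()` computes log-rank (Nelson–Aalen)
scores `a_i = event_i − Λ(t_i)` and scans all candidate cuts at
midpoints between consecutive distinct marker values whose smaller
resulting group holds at least `minGroupFrac = 0.10` of the cohort,
maximizing the absolute standardized score sum (permutation variance).
Midpoint candidates make the search equivariant under strictly monotone
marker transforms; the 10 % floor is a conventional choice, stated
because neither the X-tile tool nor the source analysis publishes its
minimum population. The selected cut's p-value is adjusted for the
multiple looks with the Lausen–Schumacher improved-Bonferroni
approximation (never reported below the single-look bound); a
permutation p-value (seeded, ≥ 500 permutations recommended) is
available as `pMethod = "permutation"`. Ties in the maximum break toward
the smaller cut.

**Two-cut (SIP).** `xtileTwoCut()` searches *exhaustively* over all
admissible cut pairs (each of the three groups ≥ 10 %) for the pair
maximizing the unadjusted 3-group log-rank chi-square, in C++ (O(pairs ×
n); ~4 s at n = 600 on one core). The reported chi-square is the maximum
over many looks and therefore selection-biased; it is meant
descriptively, as in X-tile plots, and no p-value is attached. At
moderate sample sizes or diluted effects the selected pair can be a
chance partition that beats the generating one — the package's own
recovery tests therefore use sharp hazard contrasts, and users should
treat the cuts as exploratory. Ties break toward the lexicographically
smallest pair. Both searches are verified against exhaustive brute-force
oracles on dozens of random cohorts in the test suite.

`mergeSipLH()` pools SIP-low and SIP-high into SIP-LH, and
`combinedGroups()` assigns Group 1 = SIP-intermediate ∧ LIP-high,
Group 3 = SIP-LH ∧ LIP-low, Group 2 = the rest.

# Survival analysis

`filterCohort()` applies the perioperative-mortality rule — deaths
within 30 days of surgery are excluded, censored records are not — as
`os_days <= 30` when day resolution is available and `os_months < 1`
otherwise. `kmFit()` wraps the product-limit estimator with log(−log)
(Brookmeyer–Crowley-style) confidence intervals; the median is the
earliest time the curve reaches 0.5, reported as not reached when it
never does. `compareGroups()` adds the overall log-rank test and the
first-group-versus-each/versus-others Cox contrasts used in combined
group reporting. Cox models use the Efron tie approximation (the
`survival` package default; the source analysis does not state its
choice), and `coxCarryForward()` implements the stated selection rule
exactly: every variable with univariate p < 0.05 enters the joint model,
with no stepwise refinement; variables keeping p < 0.05 there are
flagged as independent predictors. All tests are two-sided at α = 0.05.

# Numerical choices and problem sizes

* Every stochastic stage takes an explicit integer seed and restores the
  caller's RNG state; identical parameters give bit-identical output.
* The test suite trains a width-4, depth-4 network on 200 synthetic
  396-px tiles for 4 epochs (batch 1, Adam at 3e-3) and requires
  per-class Dice ≥ 0.80 on 20 held-out tiles; at this scale the run
  takes roughly ten minutes on one CPU core. These sizes are the
  package's chosen demonstration scale: large enough that the three
  classes (including the ~2 % lymphocyte class) must genuinely be
  learned, small enough to run routinely.
* Cutpoint recovery is exercised at n = 500 (binary, 50 seeds, cut
  within ±0.01 in ≥ 90 %) and n = 600 (two-cut, within ±0.03), KM/Cox
  recovery at n = 2000.
* Degenerate inputs are defined errors, not silent results: empty ROIs,
  masks with foreign values, all-ignored training batches, cohorts
  without events, constant Cox covariates, collinear multivariate
  selections.

# Known limitations

* The synthetic appearance model is far simpler than real H&E; Dice
  scores on it are an upper bound for nothing — see the scene section.
* The two-cut chi-square is selection-biased by design (descriptive
  use); only the binary cutpoint carries an adjusted p-value.
* Whole-slide inference is sequential over tiles; for genuinely large
  slides a practitioner would parallelize over tiles, which the
  per-tile API permits but the package does not orchestrate.
* Areas are reported in pixels (and fractions); µm² calibration is left
  to `micronsPerPx²` by the caller, since prognosis uses fractions only.
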