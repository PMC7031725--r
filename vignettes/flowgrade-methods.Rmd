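---
title: "Perfusion-based facial-paralysis grading: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion-based facial-paralysis grading: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `flowgrade`, the
assumptions behind each stage, the tunable parameters and their
defaults, what the synthetic cohort simulator does and does not emulate,
and the numerical and design decisions that were genuinely open.

## The measurement and the clinical question

Laser speckle contrast imaging (LSCI) illuminates tissue with coherent
laser light; moving red blood cells blur the speckle interference
pattern within the camera's integration time, so the local contrast
$K = \sigma_I / \mu_I$ of the intensity image decreases where flow is
high. The conventional inversion takes flow proportional to $1/K^2$. An
LSCI scanner reports full-field perfusion in *relative* units — absolute
calibration is not available — as a strictly positive raster, together
with a pixel-registered colour image.

In unilateral facial palsy the affected hemiface perfuses less than the
healthy one, and the asymmetry grows with House–Brackmann (HB) grade
(I = normal … VI = total paralysis). The package quantifies this
asymmetry over seven anatomically premarked regions per hemiface —
eyebrow, eye circumference, nose wing, cheek, mouth upper, mouth corner,
mouth below — and grades it with standard classifiers.

## Segmentation by morphable-model fitting

The face is segmented geometrically, not by appearance: a PCA shape
model (mean shape $\bar v$, orthonormal modes $v_i$ scaled by standard
deviations $\sigma_i$) is fitted to 68 detected landmarks, and the
region masks are obtained by projecting premarked vertex sets.

*Camera step.* The affine camera is estimated by the gold-standard
least-squares algorithm from the 2D–3D landmark correspondences. Both
point sets are conditioned first (zero centroid; isotropic scaling to
RMS distance $\sqrt 2$ in 2D and $\sqrt 3$ in 3D); a coplanar 3D
configuration is rejected as degenerate. An affine (parallel-projection)
camera is adequate because the scanner sits ~20 cm above a near-frontal
face: perspective effects across a face at that stand-off are below the
landmark noise.

*Shape step.* With the camera fixed, the standardized coefficients
$\alpha$ minimise
$E=\sum_i \lVert y_i - x_i\rVert^2 / (2\sigma_{2D}^2) + \lVert\alpha\rVert^2$,
a ridge problem solved exactly via
$(A^\top A + 2\sigma_{2D}^2 I)\,\alpha = A^\top b$. The penalty is a
unit-normal prior on $\alpha$, which is meaningful only because the
basis is stored unscaled with $\sigma_i$ separate and the design matrix
uses the $\sigma$-scaled modes.

Parameters:

* `sigma_2d` (pixels, default 3) — the assumed landmark-detector error.
  It acts as ridge strength $2\sigma_{2D}^2$: larger values shrink the
  fit towards the mean face. 3 px reflects typical detector accuracy at
  512×512; for noiseless synthetic landmarks a much smaller value
  recovers the generating coefficients to numerical precision.
* `iterations` (default 1) — with 1 the procedure is strictly
  sequential (camera from mean-shape correspondences, one shape solve);
  larger values alternate camera re-estimation against the fitted mesh
  with re-solves. The cost is monitored and an uphill alternation is
  refused, so the trace is non-increasing. Whether the original system
  refined the camera is unknown; both behaviours are exposed and the
  sequential one is the default.

*Mask projection.* For each region/side, triangles whose three vertices
lie in the region's vertex set are rasterised as filled triangles
(pixel-centre test with a deterministic top-left-style rule for edge
ties, so adjacent triangles neither overlap nor crack; 0-based pixel
grid, half-open image domain). Rasterisation was chosen over vertex
scatter plus morphology because it is deterministic and
resolution-independent; the original system's choice is not documented.
Depth resolution of overlapping regions (z-buffer at triangle-centroid
granularity) exists but is off by default — at near-frontal acquisition
the 14 regions cannot occlude each other.

Label images use codes 0 (background), 1–7 (left-side regions in the
region-index order above) and 8–14 (right side). Dice overlap is
computed per region and pooled,
$\mathrm{DSC}=2\sum_i |X_i\cap Y_i| / \sum_i (|X_i|+|Y_i|)$ — the pooled
form weights regions by size and is *not* the mean of per-region values.
Two empty masks agree perfectly (DSC 1); empty versus nonempty is 0.

## Features

Regional mean flow is the arithmetic mean of blood-flow pixels under
each mask, averaged per patient over the QC-passed frames (one vector
per participant; a per-frame mode exists but the patient is the
natural sample unit of an 80-participant cohort and avoids pseudo-
replication). The classifier input is
$[A_B,\dots,A_{MB},H_B,\dots,H_{MB}]$ — affected side first — divided by
$\mathrm{Volume}_{\min}$, the minimum over all 14 means (read literally
as the minimum over *all* regions, not per side). The vector therefore
has minimum exactly 1 and is invariant to any global rescaling of the
frame, as required by relative-unit perfusion imaging. Missing regions
(empty masks) are a hard error — imputation would corrupt the classifier
input silently. For healthy participants the right side is treated as
"affected" by convention, so grade-I vectors are symmetric in
expectation.

## Classifiers

* **K-NN**: Euclidean, $k=11$; the likelihood is the vote fraction over
  the six grades. Unstandardised features (distances on the
  min-normalised scale are already comparable).
* **SVM**: degree-2 polynomial kernel ($\gamma = 1/14$, coef0 1,
  cost 1), fold-local feature standardisation. Likelihoods are pairwise
  (one-vs-one) vote fractions. An earlier one-vs-rest design with
  softmaxed decision values was abandoned: under six-way class imbalance
  the per-machine decision values live on incomparable scales, and the
  softmax argmax performed far below an LDA reference on identical
  features, whereas the standard pairwise formulation matched it.
* **Neural network**: 14–32–16–6 multilayer perceptron, ReLU, softmax
  output, cross-entropy, full-batch Adam (rate 0.01), 500 epochs,
  AdamW-style weight decay 0.01 on weights (not biases), fold-local
  standardisation, seeded initialisation. Two hidden layers are fixed by
  the study design; the sizes, epochs and the conventional decay are the
  smallest standard configuration that trains in seconds on ~80 samples
  and does not memorise them — without decay the network reaches 100%
  training accuracy while generalising at chance-adjacent levels.

Exact likelihood ties resolve to the lower (less severe) grade and are
reported; deterministic and clinically conservative.

Evaluation is patient-grouped k-fold cross-validation: patients are
shuffled with the seed and partitioned at the patient level, each fold
held out once, accuracy = correctly graded held-out patients / patients.
The per-patient "estimated vs true grade" report uses out-of-fold
predictions only.

## The synthetic cohort simulator

The simulator defines the study conditions: 80 participants
(8 healthy, 17/16/13/16/10 at grades II–VI), 100 frames each, 512×512
frames. It emulates:

* **Face geometry** — a parametric frontal face surface (ellipsoid patch
  with nose, brow and mouth displacement fields) on a disc grid, with a
  region atlas and iBUG-style 68-landmark correspondences placed from
  the surface parameters. The PCA basis consists of seeded random smooth
  deformation fields, orthonormalised. Two constructions matter:
  (a) each mode's affine regression onto the mean landmark configuration
  is removed before orthonormalisation, as in aligned-shape PCA — a
  deformation an affine camera can mimic at the landmarks carries no
  shape information and would otherwise couple the camera and shape
  solves into a slowly converging valley; (b) mode standard deviations
  are $2.5\sqrt{3N}\,(0.85)^{j-1}$ model units, i.e. ~2.5 units
  (mm-scale) rms per-coordinate displacement at one standard deviation —
  the inter-subject variability typical of face shape models. The model
  needs roughly 2000+ vertices so that the thinnest premarked regions
  contain fully interior triangles; coarser requests error out.
* **Perfusion** — per-vertex flux rendered by barycentric interpolation
  over the projected mesh, Gaussian-smoothed, on a positive background
  (0.1). Regional bases (1.15–1.5× surrounding skin) × lognormal
  subject scale (σ 0.2, cancels under min-normalisation) × lognormal
  per-region patient jitter (σ 0.05, the dominant within-grade noise) ×
  lognormal per-frame fluctuation (σ 0.05). The affected side's regional
  flux is attenuated by $m = 1-\delta(\mathrm{grade}-1)$ with δ = 0.09,
  so the expected asymmetry ratio is $P_r = 1/m$, increasing from 1
  (grade I) to ≈1.8 (grade VI). The linear-in-grade form is the simplest
  monotone family consistent with the reported trend; the true clinical
  dose–response is unknown and δ is explicitly a free parameter, not a
  clinical estimate.
* **Artifacts and QC** — head motion multiplies a whole frame by an
  amplitude in [1.5, 3] (~3% of frames) and blurs it mildly. QC screens
  the frame-mean series with a one-sided robust z-score
  (median/MAD, threshold 3): elevation is the physical failure mode.
  MAD = 0 triggers a degenerate-scale warning and no flags.
* **Speckle physics** — reduced to variance shaping: target contrast
  $K = 1/\sqrt{1+c\,f}$, lognormal intensities with exactly that
  sd/mean, windowed contrast (default 7×7), flow estimate
  $(1/\hat K^2 - 1)/c$. The contrast map averages 16 independent
  realisations: a single window-7 estimate has ~10% per-pixel sampling
  error regardless of implementation, and a short burst (0.27 s at the
  scanner's 60 fps) is exactly how LSCI devices reach per-pixel
  precision. Temporal decorrelation dynamics and exposure-time integrals
  are not modelled.

Everything is a pure function of the configuration: per-patient seeds
derive from the master seed by a stable arithmetic hash of the patient
index, so extending the cohort never changes existing patients.

What passing tests on this simulator show — and what they do not: the
pipeline recovers known ground truth through every stage (pose, shape,
masks, features, grade) under controlled noise, and the classifier
ordering (network > SVM > K-NN) matches the clinical report. They do not
validate the clinical effect size, real detector behaviour, skin-texture
or illumination effects, or out-of-plane pose — the simulator's faces
are near-frontal and flat-shaded by design, because the colour image
serves only landmarking.

## Numerical choices and degenerate inputs

* Camera estimation rejects coplanar 3D configurations (third singular
  value < 1e-9 of the first); the shape solve is always positive
  definite thanks to the ridge term, and its condition number is
  attached to the result.
* Rasterisation edge ties follow a fixed top-left-style rule; exact
  shared-edge pixels belong to exactly one triangle.
* Empty∩empty Dice = 1; empty-vs-nonempty = 0.
* Frames must be strictly positive (device contract); zero or NaN
  pixels are rejected with counts.
* Flow frames are stored as uncompressed little-endian IEEE-float
  32-bit single-channel TIFF written by the package itself (standard
  baseline tags, SampleFormat 3), since scaled-integer TIFF cannot hold
  unscaled perfusion values; foreign TIFFs are parsed and rejected with
  a format error if multichannel or non-float.
* Exact classifier likelihood ties break to the lower grade.

## Problem sizes used in the shipped checks

Regional-mean features are resolution-independent by construction
(means over projected masks), so cohort-level checks render frames at
128×128; recovery, segmentation-fidelity and speckle checks run at
384–512 where pixel granularity matters. Monte-Carlo feature properties
(asymmetry trend, grade-I symmetry) draw $10^4$ patients from the
generative flux layer — the same code path that drives rendering —
rather than rendering $10^6$ images. The zero-noise classifier sanity
check uses a balanced 15-per-grade cohort: with only 8 healthy subjects
an 11-neighbour vote can be outvoted by an adjacent grade even at zero
noise, so unanimity is only guaranteed when every training fold retains
at least 11 same-grade points.

## Known limitations

* The synthetic model is face-like, not a face: segmentation accuracy
  against its own atlas bounds geometric pipeline error only.
* The grade→asymmetry relation is assumed linear with independent
  lognormal noise; real perfusion asymmetry may saturate, interact with
  region, or correlate across regions.
* The affine camera ignores perspective; acceptable at 20 cm stand-off,
  not in general.
* Landmark detection is delegated entirely to an external tool; detector
  bias (systematic landmark shifts) is not simulated, only isotropic
  noise.
* Likelihoods are vote fractions or softmaxed scores, not calibrated
  probabilities.
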