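---
title: "Rigid 2D-3D X-ray/CT registration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid 2D-3D X-ray/CT registration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drrpose)
```

## The problem

Intraoperative 2D radiographs and preoperative CT volumes live in different
dimensions, so they cannot be compared directly. The standard bridge is the
digitally reconstructed radiograph (DRR): a simulated projection of the CT
volume under an explicit camera model. Registration then means finding the
rigid pose of the patient — three rotations $\alpha,\beta,\theta$ about the
$x,y,z$ axes (degrees) and three translations $d_x,d_y,d_z$ (mm) — whose DRR
best matches the observed radiograph.

`drrpose` implements this pipeline twice over: a *learning-based* route, in
which a dual-channel hierarchical attention encoder regresses the six pose
parameters directly from an image pair, and an *optimization-based* route
(Powell's direction-set method and CMA-ES driving a gradient-correlation
similarity), plus the shared infrastructure: DRR simulation, pose-labelled
dataset generation, a noise model, and a registration-error evaluation
suite.

## Coordinate model and the rigid transform

Points are column vectors; transforms act by left multiplication. The pose
maps to a homogeneous matrix whose rotation block equals
$R_z(\theta)R_y(\beta)R_x(\alpha)$ — `poseToMatrix()` writes the matrix
elements out explicitly, and the test-suite checks it against an independent
three-matrix product oracle. Angles are stored in degrees (the units of all
capture-range tables) and converted only at the matrix boundary.

Three frames are chained:

* **CT frame**: the scanner's voxel grid, with origin offset $(a,b,c)$ and
  physical extent $L\times W\times H$ (voxel counts times spacing, mm).
* **Patient frame**: `patientFromCT()` translates by
  $-(a+L/2,\,b+W/2,\,c+H/2)$, placing the grid's geometric center at the
  origin. The estimated pose acts in this frame.
* **Source frame**: the X-ray source sits at $(0,0,+\mathrm{SOD})$;
  `sourceFromPatient()` carries the optional C-arm extrinsic rotation
  (identity in the single-view setup). By default
  $\mathrm{SOD}=\mathrm{SDD}/2$, so the patient origin lies halfway between
  source and detector.

The detector plane lies at $z=\mathrm{SOD}-\mathrm{SDD}$ with axes parallel
to the patient $x$ (columns) and $y$ (rows) axes and the principal point at
the detector center. The sign conventions (which way the detector axes
point, where the principal point sits) are package choices — the physical
setup fixes only the axis orientations — and are asserted by the
translation-consistency test: shifting the volume by $+d_x$ shifts the
projection by $+d_x\cdot\mathrm{SDD}/\mathrm{SOD}$ detector millimetres for
structures at the patient origin.

Gimbal lock ($|\beta|=90^\circ$) makes the Euler decomposition non-unique;
`matrixToPose()` then sets $\theta:=0$, folds the remaining rotation into
$\alpha$, and warns. The capture ranges used anywhere in the package keep
$|\beta|\le 15^\circ$, far from the degeneracy. Long composition chains
re-project the rotation block onto SO(3) (via SVD) whenever its
orthonormality defect exceeds $10^{-10}$, so drift stays below $10^{-9}$
even over $10^4$ compositions.

## DRR simulation

The imaging model assumes a logarithmic detector response and no beam
divergence, under which the recorded pixel value is the line integral of
the linear attenuation coefficient $\mu$ along the ray from the source to
that pixel. `huToAttenuation()` converts Hounsfield units linearly,
$\mu = \mu_\text{water}(1 + \mathrm{HU}/1000)$, clamped below at zero;
$\mu_\text{water}$ defaults to 0.02 mm$^{-1}$ and only sets the overall
scale, which display normalization removes anyway.

`projectSiddon()` computes the integral *exactly* for the voxelized field
by Siddon's parametric plane-crossing traversal: each ray accumulates
$\mu \cdot$ (intersection length) over the voxels it crosses, in one
incremental pass. Rays missing the volume contribute zero. The projector is
linear in $\mu$ by construction, and the suite verifies an analytic chord
length through a homogeneous cube at relative error below $10^{-6}$.

`projectDenseOracle()` is the independent reference: trapezoidal
integration of the *trilinearly interpolated* field at a fixed step (at
most half the smallest voxel spacing). The two routes discretize
differently — piecewise-constant versus interpolated — so they agree only
up to interpolation bias at sharp boundaries; on smooth fields the
agreement criterion is a maximum pixel deviation below 1% of the oracle's
image maximum (64³ volume, 64² detector in the shipped check). Halving the
oracle's step on a smooth field changes its output by less than 0.1%,
which bounds its own discretization error.

Default imaging parameters follow a mobile C-arm: 1536×1536 detector at
0.194 mm pitch and SDD 1020 mm. All tests and examples render on coarser
detector grids with the same field of view (the `renderSize` machinery)
purely for speed; the geometry model is unchanged.

## The synthetic phantom

Every test runs on a synthetic phantom rather than clinical CT. The
phantom emulates what matters for rigid 2D-3D registration: a bone-density
ellipsoidal shell (≈1000 HU) around soft tissue (≈40 HU) in air
(−1000 HU), a vertebra-like axial column, oblique high-density rods and
spheres at mid-to-large radius, and high-density asymmetry markers placed
off every symmetry plane. The shell is deliberately off-center in the
volume so that no nontrivial 90°-multiple rotation maps the phantom onto
itself (the suite checks all 23 cube rotations); elongated internal
structures give projections a strong orientation signature, which real
skeletal anatomy has and a plain ellipsoid does not.

What the phantom does *not* emulate: soft-tissue texture, scanner noise
and artifacts, patient-to-patient anatomical variability, and truncated
fields of view. Tests passing on the phantom therefore demonstrate the
correctness of the geometry, projector, training machinery and metrics,
and the *feasibility* of pose recovery — not clinical-grade accuracy on
real radiographs.

The default phantom is 128³ voxels at 1 mm spacing — large enough for pose
identifiability, small enough for CPU test runs; several tests use 48–64³
versions with correspondingly scaled spacing.

## Capture ranges and pose sampling

Per-anatomy capture ranges are shipped as presets (head, chest, pelvis),
e.g. chest: $d_x \in [-25,25]$, $d_y \in [-15,15]$, $d_z \in [-30,30]$ mm,
rotations $[-15,15]^\circ$ about $x$ and $y$ and $[-5,5]^\circ$ about $z$.
The $z$ translation range is widest (depth along the source axis varies
most); the in-plane rotation (about $z$, the projection axis) is narrowest
because it is well controlled clinically. The head translation and pelvis
$x$-rotation presets are off-center — they pre-position the scan so the
region of interest is centered, or rotated into the anterior-posterior
view, and the regressor simply learns absolute values over those shifted
intervals. Where the anatomical rotation labels (roll/pitch/yaw) meet the
axis convention, the package treats the per-axis assignment as normative
and the names as labels; the narrow in-plane range is anchored to the
projection axis, which is what the clinical argument fixes.

Training poses draw each parameter independently from a normal
distribution truncated to its range. The distribution's center and spread
within the range are not physically determined; the package uses mean =
range midpoint and sd = quarter-range, which concentrates mass centrally
while still exercising the edges, and exposes both as knobs plus a uniform
sampling mode. Sampling uses the inverse-CDF method, so it is exactly
reproducible under a seed.

## The pose regressor

The encoder follows the hierarchical shifted-window attention design: 4×4
patch tokenization (224² → 56² tokens), linear embedding to 96 channels,
four stages of paired attention blocks (depths 2, 2, 6, 2; heads 3, 6, 12,
24) with 2×2 patch merging between stages (56→28→14→7 spatial,
96→192→384→768 channels). Within each pair, the first block attends within
aligned 7×7 windows and the second within windows cyclically shifted by
⌊7/2⌋, with attention masked across wrap-around boundaries — this is what
lets information cross window borders while keeping the attention cost
linear in image area (`attentionCost()` evaluates both complexity
formulas). Blocks use pre-normalization, learned relative-position bias,
GELU MLPs with expansion 4, and residual connections, all following the
cited window-attention design. Stage grids not divisible by the window are
zero-padded and the padding masked out; a stage whose grid is no larger
than the window uses a single whole-grid window without shifting.

After each stage, a squeeze-and-excitation block reweights channels:
global average pool → bottleneck FC (reduction 16) with ReLU → FC with
sigmoid → per-channel multiply, so every gate lies in [0,1] and gating
never amplifies. The reweighted map both feeds the next stage and is
tapped for fusion — the architecture drawing places the SE blocks at the
stage outputs without specifying whether the main path sees them; feeding
them forward was chosen so that a single consistent feature stream exists.

The four reweighted stage outputs enter a feature pyramid: 1×1 projections
unify channels to 768, the top-down path upsamples (bilinear ×2, additive
fusion — the standard pyramid choices, since the source design says only
"up-sampled and combined") and each fused level is globally pooled to a
768-vector; concatenation yields 3072 values per image channel. Moving and
reference channels share encoder weights by default (a siamese design,
halving parameters and making reference-feature caching exact); an
unshared option exists. The regression head is
concat(3072+3072) → FC 1024 → ReLU → dropout 0.2 → FC 256 → ReLU → FC 6 —
the smallest fully connected head consistent with the published
description, which does not recover the exact head topology.

Training minimizes mean squared error on *normalized* parameters: each of
the six is standardized by its capture-range midpoint and half-width so
that degrees and millimetres contribute comparably to the shared loss.
Optimization is Adam; the clinical-scale reference learning rate is
$10^{-5}$ with batch 128 and dropout 0.2, while the desk-scale runs in the
tests use larger rates (up to $10^{-3}$) and small batches, which converge
in few epochs at these model sizes. All stochastic elements — weight
initialization, shuffling, dropout — draw from one seeded stream, so
training is bit-reproducible and checkpoints restore identical
predictions.

Because no deep-learning framework is available to R in this environment
and the encoder is the package's core contribution, the forward *and*
backward passes are implemented directly (R matrix algebra over BLAS with
C++ kernels for the windowed attention, layer normalization and GELU). The
backward pass is verified against central finite differences
leaf-by-leaf — the strongest correctness evidence a hand-written autodiff
can offer.

### Desk-scale learning study

The full-scale experiment behind the published headline numbers —
hundreds of thousands of DRRs per anatomy, GPU training — is out of desk
reach. The package instead ships a scaled-down recovery study as its
learning check: the miniature configuration (64² inputs, embedding width
24, depths 2/2/2/2, small head) trained on 2500 phantom DRRs sampled from
the chest capture range and evaluated on 300 held-out DRRs against the
untrained model's MAE, with batch 64 and a step-decayed Adam schedule
($10^{-3}$ for four epochs, then $3\times10^{-4}$ for three). These are
the package's study conditions, fixed once to fit a single-CPU run.

What the study shows, and what it does not: the three translations train
to a small fraction of the untrained error (the projection's position and
scale respond strongly to them), and the depth translation $d_z$ remains
the hardest translation — it only rescales the projection — so the suite
asserts its range-normalized error stays at or above that of $d_x$. The
three rotations, in contrast, need far more data than a desk-scale run
can supply: in a rotation-only setting the same encoder halves the
out-of-plane rotation errors, and the suite's translation-compensation
check shows rotations remain distinguishable from translations in these
images (no pure translation reproduces a 5° rotation's gradient
correlation), but in the joint six-parameter problem at a few thousand
samples the optimizer does not find the rotation signal before the
budget ends. The full-scale design resolves this with two to three
orders of magnitude more images; the scaled-down study therefore bounds
what desk-scale training demonstrates.

## Optimization baselines

`registerOptim()` minimizes $1-\mathrm{GradNCC}$ between the target
radiograph and the DRR rendered at the candidate pose. GradNCC computes
central-difference gradients of both images along $x$ and $y$ and averages
the normalized cross-correlations of the two gradient components; the
published protocol does not pin down the exact variant, and the
mean-of-NCCs form was chosen for symmetry and affine-intensity invariance
(both asserted in tests). A constant image has undefined correlation; it
is defined as 0 with a warning.

Powell's direction-set method uses Brent line minimization along each
direction with per-parameter initial scales of 2° / 2 mm, and the classic
direction-replacement rule; CMA-ES is the standard
$(\mu/\mu_w,\lambda)$ strategy with rank-one and rank-$\mu$ covariance
updates, $\sigma_0 = 3$ in mixed degree/mm units (range-matched for the
capture ranges at hand). Both stop when the similarity improves by less
than $10^{-3}$ (CMA-ES: over two consecutive generations, since its best
value changes generation-wise) or at 100 iterations — interpreted as
objective-improvement sweeps for Powell and generations for CMA-ES, each
algorithm's natural unit. DRRs inside the loop render at a configurable
reduced resolution (224² by default, 48–64² in tests).

## Noise model

Test-time corruption composes photon noise and detector noise:
$\mathrm{out} = \mathrm{clip}(\mathrm{Poisson}(v\lambda)/\lambda +
\mathcal{N}(0,\sigma^2),\,0,\,1)$ on display-normalized intensities. The
severity levels are named low ($\lambda=200, \sigma=0.01$), medium
($\lambda=50, \sigma=0.03$) and high ($\lambda=10, \sigma=0.08$); the
source imagery shows the corruption levels only visually, so these
defaults were set once to span visibly mild to severe corruption at 224²
scale, and are recorded in output metadata wherever noise is applied. Away
from the clip boundaries the model is mean-preserving with per-pixel
variance $v/\lambda + \sigma^2$, which the suite verifies empirically.

## Evaluation metrics

* **Per-parameter MAE** in native units, reported as mean ± sd, with the
  three translation (rotation) MAEs further averaged into a mean
  translation (rotation) error.
* **mTRE**: the mean Euclidean distance between landmark positions mapped
  by the estimated versus true transforms. Landmarks default to the eight
  corners of the CT physical bounding box plus the centroid — the
  published definition leaves the landmark set open, and spanning the
  volume makes rotational error count. With a single landmark at the
  origin, mTRE reduces to the translation-difference norm; it is invariant
  under a common rigid transform applied to both poses.
* **GFR**: the percentage of cases with mTRE strictly above 10 mm, the
  conventional failure threshold (strictly above: exactly 10 mm is not a
  failure).

## Numerical choices and degenerate inputs

* Constant images: display normalization and preprocessing map them to
  all-zeros; GradNCC defines them as similarity 0 with a warning.
* Attenuation is clamped at zero after the HU conversion (HU below
  −1000 mm would otherwise go negative).
* The Siddon traversal nudges entry points by 10⁻¹² into the grid to
  resolve rays starting exactly on voxel planes; ties among plane
  crossings advance all tied axes at once.
* Layer normalization uses ε = 10⁻⁵; softmax subtracts row maxima.
* Degenerate capture ranges (low = high) sample the constant and
  standardize by half-width 1 to avoid division by zero.
* 16-bit TIFF storage quantizes images to 1/65535; the dataset
  regeneration test re-renders through the same quantization path and
  demands bit-identity.

## Known limitations

* The projector models neither beam divergence/polychromatic spectra nor
  scatter — consistent with the log-response assumption, but a gap to real
  fluoroscopy.
* The learning results shown by the tests are phantom-scale existence
  proofs; transferring to clinical images requires full-scale training and
  domain adaptation, which are out of scope.
* DICOM series input is not supported (no DICOM reader is available to
  the package); NIfTI-1 is the volume interchange format, with a
  MetaImage writer for viewers.
* Only axis-aligned (possibly flipped) volume orientations are accepted;
  oblique direction cosines raise an error rather than being resampled.
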