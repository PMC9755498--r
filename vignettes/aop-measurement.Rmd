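---
title: "Automatic measurement of the fetal angle of progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic measurement of the fetal angle of progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopseg)
```

## The measurement problem

During the second stage of labor, the station of the fetal head is assessed
on transperineal ultrasound (TPU) through the **angle of progression (AoP)**:
the angle between the long axis of the pubic symphysis (PS) and the line
from the inferior end of the symphysis drawn tangentially to the fetal head
(FH) contour. Manual measurement is operator-dependent and slow, so this
package automates the whole chain:

1. **Segmentation.** A dual-branch U-shaped network labels each pixel of a
   TPU frame as background, PS or FH.
2. **Target fitting.** Each segmented structure is summarized by an ellipse
   fitted to its boundary by direct least squares under the conic
   constraint $4AC - B^2 = 1$.
3. **Angle computation.** The PS ellipse contributes its major-axis
   endpoints $U_p$ (superior) and $L_p$ (inferior); the FH ellipse
   contributes the tangent point $T_p$ seen from $L_p$; the AoP is the
   angle $\angle(U_p, L_p, T_p)$.

Because clinical TPU datasets cannot be redistributed, the package also
ships a phantom generator that renders ultrasound-like images with exact
masks and analytically known angles, so that every stage — network,
geometry, metrics — is testable end to end without any data download.

## The segmentation network

The network follows a U-Net layout with a **shared encoder** and a
**dual-branch decoder**:

* The encoder has five blocks of two (3×3 convolution, group norm, ReLU)
  layers, the first four followed by 2×2 max pooling; widths double per
  level from `base_channels` (default 32) to 16× that, so a 512×384 input
  reaches the bottleneck at 32×24.
* The **lower branch** decodes at the bottleneck resolution only: four
  blocks halve the channel count back down, and a 1×1 convolution with
  softmax emits a coarse 32×24 probability map. This branch sees only
  high-level shape semantics — roughly "where is the head, where is the
  symphysis" — with no fine detail.
* The **upper branch** decodes back to full resolution. Each level fuses
  three signals: the matching encoder skip (taken before pooling), the
  previous upper block after 2× upsampling and a 3×3 *deformable*
  convolution, and the lower branch's same-level features upsampled to the
  current resolution. An additive **attention gate** — 1×1 projections of
  the upper path (gating) and lower path (signal), ReLU, a 1×1 projection
  to one channel, sigmoid — re-weights the lower-branch signal pixelwise
  before fusion, letting the upper decoder consume the coarse shape prior
  only where it helps.
* Deformable convolutions learn per-position sampling offsets; the
  offset-predicting convolution is zero-initialized so training starts as
  an ordinary convolution and the receptive field deforms gradually. This
  targets the non-rigid, variably oriented anatomy.

Training minimizes the **collaborative loss**
$w_U \, D_U + w_L \, D_L$, the weighted sum of soft Dice losses of the two
branches (background channel excluded). The lower branch is supervised by
the ground truth downsampled 16× by per-cell majority vote (ties go to the
higher class index, protecting the thin PS). Defaults are $w_U = 1$,
$w_L = 0.2$; `sweep_w_lower()` reproduces the supporting grid search.
Ablation flags in `network_config()` reproduce the variants without the
attention gates, without the whole lower branch, and without deformable
convolution; `ablation_harness()` trains them under one seed and split.

All layers — convolutions, deformable sampling, group normalization,
pooling, bilinear upsampling — and their reverse-mode gradients are
implemented in compiled code inside the package, with a small tape-based
autodiff driving the backward pass. The unit tests verify every kernel
against central-difference gradients, and end-to-end parameter gradients
against numeric differentiation through the whole graph.

## Geometry

`fit_ellipse()` minimizes the algebraic residual subject to
$\mathbf a^\top C \mathbf a = 4AC - B^2 = 1$, the constraint that forces
the conic to be an ellipse. We use the numerically stable split formulation
of the generalized eigenproblem (Halir & Flusser's arrangement of
Fitzgibbon's method) on centred, isotropically scaled coordinates, then map
the conic back and re-normalize. Boundary pixel centres of the largest
8-connected component feed the fit; fitting boundaries rather than filled
regions keeps the residual a contour distance proxy, and taking the largest
component suppresses spurious islands a network may emit.

Tangency is solved in closed form: the polar line of the external point
$L_p$ intersected with the conic yields both tangent points; a dense
boundary-scan oracle in the tests confirms them to better than 0.1 px. Of
the two candidates the package keeps the one maximizing
$\angle(U_p, L_p, T)$ ("max-angle"), with `tangent_rule = "right-x"`
offering the literal image-right alternative. Max-angle is the default
because it is invariant under rotations of the frame — the measured angle
of a mask rotated by 90° agrees with the original to a fraction of a
degree — whereas an image-axis rule is not.

Two conventions are worth stating explicitly. Coordinates are 0-based
pixel centres, x rightward and y downward; all geometry, including the
reported ellipse orientation θ ∈ [0, π), lives in that frame. Circles get
θ = 0 by a deterministic tie-break. The inferior endpoint $L_p$ is the
major-axis endpoint nearer the FH ellipse centre (ties break toward larger
x, then larger y): the inferior symphysis end is the one the descending
head approaches, and unlike an image-axis rule this labelling survives
rotation augmentation.

A consequence of these two choices deserves note. With $L_p$ labelled by
head proximity, the angle to the head centre seen from $L_p$ is at least
$90° - \arcsin(a_{PS}/d)$, and the max-angle tangent adds
$\arcsin(r_{FH}/d)$; since the head ellipse is always larger than the
symphysis semi-axis, the analytic phantom AoP is bounded below by roughly
95°. Angles below 90° (a head still high in the pelvis) would require
either anatomically fixed endpoint labels or the image-right tangent rule;
the phantom generator therefore covers approximately 95°–170°, and the
coverage test asserts spread over that attainable range.

## The phantom generator

`phantom_spec(seed)` samples an anatomically plausible layout: a small
bright filled PS ellipse (semi-axes 25–45 × 8–16 px at 512×384) up-left,
its long axis pointing toward the head, and a large FH ellipse (90–150 ×
70–120 px) placed at a polar angle from the inferior PS endpoint; 30% of
draws place a smaller, more distant head nearly abeam of the axis to
populate the low end of the attainable angle range. Rejection sampling
(capped at 1,000 retries) enforces: both structures inside the frame and
the imaging fan, disjoint interiors, the inferior endpoint strictly
outside the FH, and an analytic AoP inside [60°, 170°].

`generate_sample()` rasterizes the exact ellipse interiors into the mask
(0/1/2 labels on pixel centres) and renders the image as half-normal
speckle over a tissue baseline inside a fan sector, a bright FH rim with
hypoechoic interior (the skull echo presents as a bright arc), a bright
filled PS blob, Gaussian blur, and renormalization to [−1, 1]. The
reference key points and angle come from the *exact* parameters through
the same closed-form geometry the measurement pipeline uses — which makes
the generator an independent oracle: measuring the angle from the
rasterized ground-truth mask must agree with the analytic value to within
2° (rasterization noise), and it does for 100/100 seeds in the acceptance
suite.

What the phantoms deliberately do **not** model: attenuation and acoustic
shadowing, anisotropic speckle statistics, neighbouring anatomy, probe
pressure deformation, or video correlation. Passing the phantom suite
therefore demonstrates that the architecture trains, that the geometric
chain is correct, and that the end-to-end error budget is consistent — not
clinical-grade segmentation accuracy on real ultrasound.

## Evaluation metrics

Per image the package reports multi-class pixel accuracy; Dice for PS, for
FH, and pooled over both foreground classes (`dice_all`; the mean-of-both
alternative is available via an argument — pooled is the default because
the defining formula is written in raw counts); and the average surface
distance (ASD), the symmetrized mean of nearest-boundary distances
normalized by the two surface sizes, computed over all components of the
pooled foreground with Euclidean distances between pixel centres and no
surface interpolation. Endpoint quality uses the Euclidean errors of
$U_p$ and $L_p$ and the angle between predicted and reference PS axes.
Angle accuracy uses |ΔAoP| summarized by mean, median and *population*
standard deviation (configurable to sample), plus a count of cases above
20°, the conventional gross-failure threshold. ASD and ΔAoP are averaged
per image and then across images; pixel units refer to the processing
grid, which is recorded alongside every report.

## Training protocol and problem sizes

The reference protocol is Adam at learning rate 1e-4 (the community
default optimizer for this family; only the rate and Kaiming
initialization are prescribed), 200 epochs, batch size 1, ±30° rotation
plus horizontal-flip augmentation applied identically to image, mask and
key points, and patient-grouped 5-fold cross-validation — all images of a
patient stay on one side of every split, which `patient_grouped_kfold()`
guarantees and the tests assert.

The package's self-contained experiments run a scaled-down version sized
for a single CPU: 200 phantoms from 20 synthetic patients, a
`base_channels = 8` network, 15 epochs at 128×96 (phantoms are generated
at 512×384 and uniformly resized, preserving 4:3 and hence all angles),
learning rate 1e-3 — the usual compensation when a 200-epoch schedule is
compressed to 15 — on a patient-grouped 80/20 split. The acceptance
criteria at these sizes are pooled foreground Dice ≥ 0.85, mean ΔAoP ≤ 8°
against the analytic references, and ≥ 90% of held-out images yielding a
valid measurement.

## Numerical choices and degenerate inputs

* Ellipse fits require ≥ 5 non-collinear points; degeneracy (collinear
  scatter, no ellipse eigenvector) raises a typed error that
  `measure_aop_from_mask()` converts to a per-image failure status
  (`ps_fit_failed`, `fh_fit_failed`, `lp_inside_fh`, `empty_class`) —
  batch processing never aborts.
* Every returned conic satisfies $|4AC - B^2 - 1| < 10^{-8}$; points are
  centred and scaled before fitting for conditioning.
* Group-norm groups default to `min(8, channels)`; ε = 1e-5.
* Bilinear resampling uses half-pixel-centre alignment with edge
  clamping; mask warps are nearest-neighbour (ties round up) with
  background fill; image warps fill with −1.
* The deformable offset convolution is zero-initialized (weights and
  bias), the established stabilizer.
* Determinism: all randomness flows from explicit seeds through R's RNG;
  single-threaded compiled kernels make training bit-reproducible, which
  the tests check.

## Limitations

The network and geometry behave as documented above on phantom data, but
the empirical results shipped with the package are phantom results; clinical
deployment would require training and validation on real annotated TPU
data. The parameter count of the full-width network depends on gate and
offset-layer internals that published descriptions leave open, so counts
are reported, not matched to any external figure. Sub-90° angles are not
reachable under the default labelling/tangent conventions (see above);
the `right-x` tangent rule is provided for data where the acquisition
orientation is guaranteed.
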