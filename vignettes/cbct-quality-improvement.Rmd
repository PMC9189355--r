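---
title: "Improving CBCT image quality: deformable registration vs. CycleGAN synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Improving CBCT image quality: deformable registration vs. CycleGAN synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam CT acquired on the treatment machine (CBCT; on modern systems
iterative, scatter-corrected "iCBCT") guides patient setup in pelvic
radiotherapy, but its image quality is below that of the planning CT (pCT):
HU calibration is systematically off, low-frequency shading and streaks
remain, and cavity artifacts appear near gas. Two routes can substitute a
CT-quality image for the day's anatomy:

1. **Deformed planning CT (dpCT)** — deformably register the pCT onto the
   CBCT and propagate the planning contours. The image is real CT, but the
   anatomy is only as right as the registration.
2. **Synthetic CT (sCT)** — translate the CBCT itself into a CT-like image
   with an image-to-image model. The anatomy is the day's anatomy, but the
   intensities are model output.

The interesting regime is large day-to-day anatomical change — above all
bladder filling, which in cervical-cancer patients can more than double
between scans. This package implements both routes end to end, plus a
seedable digital pelvis phantom with known ground truth, so the central
comparison (registration accuracy collapses under large bladder mismatch;
synthesis accuracy does not) is reproducible on a laptop without any
patient data.

## The registration route

`train_registration()` fits a three-stage coarse-to-fine 3D convolutional
network. Each stage is an encoder–decoder (two stride-2 down-sampling
convolutions, six residual blocks, two nearest-neighbour up-sampling steps,
and a 1×1×1 zero-initialized field head so the initial prediction is the
identity). Stage *k* sees the moving image pre-warped by the composition of
the earlier stages' fields and predicts a residual displacement at 1/4, 1/2
and full in-plane resolution. Displacement fields are stored in voxel units
on the fixed grid with the convention `warped(x) = moving(x + u(x))`.

Training is unsupervised with

* an image-similarity term: the **MIND** (modality-independent neighborhood
  descriptor) dissimilarity between the warped moving image and the fixed
  image — per voxel and offset, the Gaussian-weighted patch distance is
  normalized by the local mean distance and exponentiated, which makes the
  descriptor insensitive to the intensity mapping and hence usable across
  the CT/CBCT gap; and
* a diffusion smoothness penalty on the residual field (mean squared
  forward difference).

Inputs are clipped to [−250, 200] HU and mapped linearly onto (−1, 1)
(`normalize_registration()`); propagated contours use nearest-neighbour
warping (`propagate_contours()`).

Numerical choices that mattered, and why:

* **Loss weights.** `w_mind = 1, w_smooth = 0.3`. With a weight of 1 the
  smoothness term stalls bladder-boundary recovery on the desk phantoms
  slightly below the deformation actually present; 0.3 recovers it while
  mean endpoint error stays well below 2 voxels.
* **MIND variance floor.** The similarity loss uses a *relative* variance
  floor equal to the global mean patch dissimilarity
  (`mind_params(eps_rel = 1)`). With the classic tiny floor, descriptors in
  flat noisy regions encode pure noise and the optimizer "matches" them by
  resampling noise through the warp: the loss at its optimum is then ~3×
  lower than at the true field, and the recovered field degrades. The
  relative floor flattens descriptors where there is no structure and
  leaves edges sharp; because it scales with the image, the affine-intensity
  invariance of MIND is preserved exactly. `mind_descriptor()` itself keeps
  the classic floor.
* **Instance fitting.** At desk scale the network is fit to the pair being
  registered; the objective is identical to population training, which the
  clinical-scale (`paper`) preset is wired for but which needs GPU-class
  hardware.

## The synthesis route

`train_cyclegan()` trains the standard two-generator/two-discriminator
cycle-consistent translation between unpaired CBCT and CT slice sets, with
the generator objective

L<sub>G</sub> = L<sub>adv</sub> + λ·L<sub>cycle</sub> + μ·L<sub>sc</sub>,  λ = μ = 10,

least-squares adversarial losses, L1 cycle reconstruction, and a 2D MIND
similarity constraint between every synthetic slice and its source slice
(`mind_params(ndim = 2)` with the classic variance floor — the constraint
should be maximally intensity-invariant so it preserves structure without
opposing intensity correction). Slices are normalized by `tanh(HU/400)`;
the generators end in a hyperbolic tangent; `synthesize_ct()` inverts the
mapping (`400·atanh`, clamped so the output range is [−1200, 1200] HU) and
passes input air voxels through unchanged, matching the preprocessing
convention that everything outside the body is air. The step-size schedule
holds 0.002 constant for the first half of training and decays linearly to
zero over the second half; batches of 6 slices; a 50-slice historical pool
stabilizes the discriminators.

Desk-scale design choices that mattered:

* **Global residual skip (resnet15).** The 15-block trunk predicts a
  correction *r* in pre-activation space and the output is
  `tanh(HU/400 + r)`; the full-resolution head convolution additionally
  sees the raw input slice as an extra channel. A fresh generator is then
  exactly the identity. Without this, the cycle and MIND terms (both
  intensity-invariant or near-invariant) leave the absolute HU level
  anchored only by the adversarial term, which needs far more steps than a
  CPU run affords. The `unet5` generator keeps the standard form.
* **Discriminator width.** Discriminators default to 32 base channels
  against the desk generators' 4. The L1 cycle gradient has constant
  magnitude λ/n per pixel; a narrow discriminator produces adversarial
  gradients below that barrier and the game stalls at the identity. Wide
  discriminators cost a few percent of step time and cross it.
* **"Discrimination rate".** The discriminator step size is a separate
  parameter (default 1e-3). The configuration value 0.02 reported for the
  original system is recorded as `discrimination_rate` but its meaning
  (learning rate? update frequency?) cannot be pinned down, so nothing is
  wired to it.

## The phantom

`generate_phantom()` builds a pelvis from geometric primitives — elliptical
body with a subcutaneous fat layer, ellipsoidal bladder, cylindrical
spinal cord, spherical femoral heads, paired posterior bone-marrow arcs —
with per-tissue HU means (air −1000, soft tissue 40, fat −80, bladder 10,
cord 25, marrow 250, femoral head 700), seeded jitter and a smooth texture
field. Two grids: `desk` 24×96×128 at 5×2×2 mm and `paper` 48×288×400 at
5×1×1 mm.

`make_pair()` creates a pCT/CBCT case: the CBCT anatomy is the pCT warped
by a known smooth deformation composed with an analytic bladder inflation
whose scale is chosen so the measured volume-difference statistic
Diff = |V<sub>CBCT</sub> − V<sub>pCT</sub>| / min(V) × 100% lands within
10% of the requested target; the exact ground-truth field and warped labels
are retained. The random deformation is concentrated in the soft-tissue
interior by a Gaussian envelope and includes a coherent ~14 mm
organ-filling shift; bones and skin stay nearly static — mirroring the
clinical observation that bony-structure overlap is insensitive to
mismatch while soft tissue moves.

`degrade_to_cbct()` adds iCBCT-style artifact content *additively inside
the body*: a 40 HU calibration offset, correlated noise mottle (15 HU SD,
8 mm correlation — statistical reconstruction leaves correlated, not white,
noise), smooth shading (30 HU peak, 120 mm), six 25 HU streaks, a dark
cavity artifact (80 HU), and optionally a couch slab. Harsher,
conventional-CBCT settings remain available through `degradation_spec()`.

What the phantom does *not* emulate: projection/reconstruction physics,
tissue heterogeneity beyond a smooth texture, target volumes, multi-organ
topology change, and delineation ambiguity (its labels are exact).
Passing desk-scale checks therefore demonstrates the machinery and the
direction of the clinical effects, not clinical accuracy values — reported
DSCs are optimistic relative to values judged against manual contours.

## The study driver

`run_study()` reproduces the study design: cases are generated across
bladder-mismatch strata (<20%, 20–50%, 50–100%, >100%; stratum membership
by *measured* Diff), each case is preprocessed, registered (instance fit)
and translated by a synthesis model trained once per study on a separate
training split (no slice leakage), and the full metric suite (NMI, NCC,
DSC per organ, MAE, RMSE, PSNR, SSIM) is aggregated per stratum.
Re-delineation on the sCT is replaced by a deterministic proxy,
`sct_organ_mask()`: in-plane smoothing, an HU band centered on the organ's
own median (robust to residual calibration error), restricted to a dilated
neighborhood of the reference contour, closed and hole-filled. It scores
boundary placement — anatomy — which is what the comparison needs. The
spinal-cord band (25 vs 40 HU against soft tissue) is the weakest proxy
and its absolute values should not be over-read.

## Problem sizes and tolerances

The desk preset is sized for a single CPU: 24×96×128 phantoms,
registration on 8×96×128 after 3× z-pooling (stages at 1/4, 1/2, full
in-plane resolution, 8 base channels, ≤300 instance-fit iterations),
synthesis on 96×128 slices (generator width 4, discriminator width 32,
≤10 epochs over every third slice). The acceptance suite uses 3 seeds for
the registration checks, 2 for synthesis, and a 4-strata × 3-case study on
3 seeds for the central comparison. Convolution GEMMs run in single
precision; every loss, metric and gradient kernel used in tests
(MIND, warp, SSIM, smoothness) is double precision, and the analytic MIND
gradient matches central differences to 1e-4 relative on 5³ inputs.
Degenerate inputs are defined explicitly: DSC of two empty masks is 1,
PSNR of identical images is +Inf, constant images raise errors in NMI/NCC,
and a constant image has MIND descriptor 1 everywhere under the variance
floor.

## Known limitations

* Unsupervised GAN training at ~100–200 steps is far from the asymptotic
  regime; the sCT intensity improvement is dominated by the learnable
  artifact components (calibration offset, shading, cavity), while fine
  noise is only partially removed.
* The rigid alignment is a 4-DOF coordinate-descent search (3 translations,
  in-plane rotation), adequate for phantoms generated near alignment, not a
  general-purpose initializer.
* Paper-scale presets (48×288×400, width 16/64) are wired through the same
  code paths but are not CPU-practical; they are untested beyond
  construction.

## A minimal run

```{r}
library(cbctqi)

pair <- make_pair(phantom_spec(seed = 11), degradation_spec(seed = 12),
                  deformation_spec(seed = 13), bladder_diff_target = 10)
reg <- train_registration(
  list(list(moving = normalize_registration(pair$pct),
            fixed = normalize_registration(pair$cbct))),
  msnet_config(iters = c(180L, 90L, 30L), seed = 11))
dmask <- propagate_contours(pair$pct_labels, reg$fields_full[[1]])
dsc(extract_mask(dmask, "bladder"),
    extract_mask(pair$cbct_labels, "bladder"))
```

and the full comparison:

```{r}
report <- run_study(study_design(seed = 1))
print(report)
render_report(report, "study_out")
```
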