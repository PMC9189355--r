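# cbctqi — improving CBCT image quality by registration and synthesis

Cone-beam CT (CBCT) guides patient positioning in pelvic radiotherapy, but
its image quality — HU calibration offsets, shading, streaks, cavity
artifacts — falls short of the planning CT (pCT). Two families of methods
substitute a CT-quality image for the anatomy of the day:

* **deformed planning CT (dpCT):** deformably register the pCT onto the
  CBCT and propagate the planning contours through the displacement field;
* **synthetic CT (sCT):** translate the CBCT into a CT-like image with a
  trained image-to-image model.

Their trade-off hinges on anatomical change between scans. Bladder filling
in particular can more than double between the planning scan and treatment;
registration accuracy collapses there, while synthesis — which keeps the
CBCT's own anatomy — does not. `cbctqi` implements both routes end to end
in R, together with a seedable digital pelvis phantom with exact ground
truth, so that comparison is reproducible on one CPU without patient data.

## What is inside

* **Registration (dpCT):** a 3-stage coarse-to-fine 3D convolutional
  cascade. Each stage is an encoder–decoder (2 stride-2 down-sampling
  layers, 6 residual blocks, 2 up-sampling layers, zero-initialized field
  head) predicting a residual displacement field u(x), composed across
  stages; `warped(x) = moving(x + u(x))`. Training is unsupervised with
  `L = w_mind * L_MIND(warped, fixed) + w_smooth * L_smooth(u)`, where
  `L_MIND` is the mean L1 distance between modality-independent
  neighborhood descriptors (per voxel and offset,
  `D(x,o) = exp(-(Dp(x,o) - min_o Dp)/V(x))` from Gaussian-weighted patch
  distances `Dp` and a local variance normalizer `V`) and `L_smooth` is a
  diffusion penalty on the field gradients. Inputs are clipped to
  [-250, 200] HU and mapped onto (-1, 1).
* **Synthesis (sCT):** a 2D CycleGAN over axial slices normalized by
  `tanh(HU/400)`: generators `G_cbct-ct`, `G_ct-cbct` (ResNet-15 or U-net-5,
  tanh output), patch discriminators `D_ct`, `D_cbct`, and the generator
  objective `L_G = L_adv + lambda*L_cycle + mu*L_sc` with
  `lambda = mu = 10`, least-squares adversarial losses, L1 cycle
  reconstruction, and a 2D MIND similarity constraint between each
  synthetic slice and its source. The step size (0.002) is constant for the
  first half of training and decays linearly to zero over the second half.
* **Preprocessing:** skin mask (threshold + morphology), couch removal,
  air fill (-1000 HU outside the body), resampling, 4-DOF rigid alignment
  by NCC search, centered in-plane crop, and the two normalizations.
* **Metrics:** NMI, NCC, DSC, MAE, RMSE, PSNR, SSIM, and the organ
  volume-difference statistic
  `Diff = |V_CBCT - V_pCT| / min(V_CBCT, V_pCT) * 100%` used to stratify
  cases (<20%, 20–50%, 50–100%, >100%).
* **Phantom:** geometric pelvis (body + fat layer, bladder, spinal cord,
  femoral heads, bone-marrow arcs) in HU with seeded noise/texture,
  iCBCT-style degradation (calibration offset, correlated noise mottle,
  shading, streaks, cavity artifact, optional couch), controllable bladder
  mismatch, and exact smooth ground-truth deformation fields.
* **Study driver:** `run_study()` generates cases across mismatch strata,
  runs both methods on every case and aggregates all metrics per stratum.

## A worked example

Register a phantom pCT to its degraded, deformed CBCT (small bladder
mismatch) and score the propagated bladder contour:

```r
library(cbctqi)

pair <- make_pair(phantom_spec(seed = 11), degradation_spec(seed = 12),
                  deformation_spec(seed = 13), bladder_diff_target = 10)
reg <- train_registration(
  list(list(moving = normalize_registration(pair$pct),
            fixed  = normalize_registration(pair$cbct))),
  msnet_config(iters = c(180L, 90L, 30L), seed = 11))
dmask <- propagate_contours(pair$pct_labels, reg$fields_full[[1]])

dsc(extract_mask(pair$pct_labels, "bladder"),   # before registration
    extract_mask(pair$cbct_labels, "bladder"))
#> [1] 0.691
dsc(extract_mask(dmask, "bladder"),             # after registration
    extract_mask(pair$cbct_labels, "bladder"))
#> [1] 0.856
endpoint_error(reg$fields_full[[1]], pair$gt_field,
               pair$cbct_labels$labels > 0)
#> [1] 1.37
```

The deformable registration lifts the bladder overlap from 0.69 to 0.86
and recovers the hidden deformation to a mean error of 1.4 voxels inside
the body. Repeating with `bladder_diff_target = 200` (volume mismatch
beyond doubling) drops the post-registration bladder DSC to ~0.69 — the
failure mode that motivates the synthesis route, whose contour accuracy is
insensitive to the mismatch. `run_study(study_design(seed = 1))` runs that
comparison across all four strata and `render_report()` writes the tables
and a boxplot.

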