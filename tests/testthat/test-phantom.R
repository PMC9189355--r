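test_that("phantom generation is bitwise deterministic in the seed", {
  a <- generate_phantom(phantom_spec(seed = 9))
  b <- generate_phantom(phantom_spec(seed = 9))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- generate_phantom(phantom_spec(seed = 10))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("bladder volume scales with the cube of the linear scale", {
  v1 <- sum(generate_phantom(phantom_spec(seed = 1))$labels$labels == 2L)
  v2 <- sum(generate_phantom(phantom_spec(seed = 1,
                                          bladder_scale = 1.26))$labels$labels == 2L)
  expect_equal(v2 / v1, 2.0, tolerance = 0.05)   # 1.26^3 ~ 2
})

test_that("organ placement outside the body is rejected", {
  spec <- phantom_spec(seed = 1)
  spec$organs$spinal_cord$center <- c(0, -120, 0)
  expect_error(generate_phantom(spec), "outside the body")
  expect_error(phantom_spec(bladder_scale = 0), "positive")
})

test_that("labels are mutually exclusive and HU means are as configured", {
  ph <- fixture_phantom(5)
  lab <- ph$labels$labels
  expect_true(all(lab %in% 0:6))
  # interior of each organ carries its configured mean HU (jitter aside)
  blad <- lab == 2L
  expect_equal(mean(ph$volume$voxels[blad]), 10, tolerance = 10)
  expect_equal(mean(ph$volume$voxels[lab == 4L]), 700, tolerance = 30)
  expect_true(all(ph$volume$voxels[lab == 0L] == -1000))
})

test_that("all-zero degradation is the identity; nonzero degrades", {
  ph <- fixture_phantom(5)
  z <- degradation_spec(noise_sd = 0, bias_amp = 0, streak_n = 0L,
                        cavity = FALSE, offset = 0, seed = 1)
  out <- degrade_to_cbct(ph$volume, ph$labels$labels > 0, z)
  expect_identical(out$voxels, ph$volume$voxels)
  d <- degrade_to_cbct(ph$volume, ph$labels$labels > 0, degradation_spec(seed = 2))
  expect_gt(error_metrics(ph$volume, d)$mae, 0)
  d2 <- degrade_to_cbct(ph$volume, ph$labels$labels > 0, degradation_spec(seed = 2))
  expect_identical(d$voxels, d2$voxels)       # seeded determinism
  expect_error(degrade_to_cbct(ph$volume, array(TRUE, c(2, 2, 2)),
                               degradation_spec()), "shape")
})

test_that("noise-only degradation reproduces the requested SD inside the body", {
  ph <- fixture_phantom(5)
  body <- ph$labels$labels > 0
  for (corr in c(0, 8)) {
    sp <- degradation_spec(noise_sd = 30, noise_corr_mm = corr, bias_amp = 0,
                           streak_n = 0L, streak_amp = 0, cavity = FALSE,
                           cavity_depth = 0, offset = 0, seed = 3)
    out <- degrade_to_cbct(ph$volume, body, sp)
    expect_equal(sd(out$voxels[body] - ph$volume$voxels[body]), 30,
                 tolerance = 2)
  }
})

test_that("sampled deformations respect the spec invariants", {
  dims <- c(24L, 96L, 128L); sp <- c(5, 2, 2)
  f0 <- sample_deformation(deformation_spec(max_disp_mm = 0, seed = 1), dims, sp)
  expect_true(all(f0 == 0))
  f1 <- sample_deformation(deformation_spec(seed = 2), dims, sp)
  f2 <- sample_deformation(deformation_spec(seed = 2), dims, sp)
  expect_identical(f1, f2)
  mag_mm <- sqrt((f1[, , , 1] * 5)^2 + (f1[, , , 2] * 2)^2 + (f1[, , , 3] * 2)^2)
  expect_lte(max(mag_mm), 16 + 1e-9)
  # zero at the volume border
  expect_true(all(f1[1, , , ] == 0))
  expect_true(all(f1[, 1, , ] == 0))
  expect_true(all(f1[, , 1, ] == 0))
  expect_error(sample_deformation(deformation_spec(control_mm = 3), dims, sp),
               "control spacing")
})

test_that("small smooth deformations keep a positive Jacobian in the body", {
  dims <- c(24L, 96L, 128L); sp <- c(5, 2, 2)
  f <- sample_deformation(deformation_spec(control_mm = 48, max_disp_mm = 13,
                                           shift_mm = 0, seed = 4), dims, sp)
  J <- field_jacobian(f)
  body <- fixture_phantom(5)$labels$labels > 0
  expect_gte(mean(J[body] > 0), 0.99)
})

test_that("make_pair hits the mismatch target and retains exact ground truth", {
  pair <- fixture_pair(31, 100)
  expect_gte(pair$measured_diff, 90)
  expect_lte(pair$measured_diff, 110)
  # ground-truth field propagates pCT labels exactly onto the CBCT labels
  dm <- propagate_contours(pair$pct_labels, pair$gt_field)
  expect_equal(dsc(extract_mask(dm, "bladder"),
                   extract_mask(pair$cbct_labels, "bladder")), 1)
  expect_error(make_pair(bladder_diff_target = 500), "reachable")
  expect_error(make_pair(bladder_diff_target = -5), ">= 0")
})

test_that("zero target with zero deformation and degradation is the identity", {
  z <- degradation_spec(noise_sd = 0, bias_amp = 0, streak_n = 0L,
                        cavity = FALSE, offset = 0, seed = 1)
  f <- deformation_spec(max_disp_mm = 0, shift_mm = 0, seed = 1)
  pair <- make_pair(phantom_spec(seed = 3), z, f, bladder_diff_target = 0)
  expect_identical(pair$cbct$voxels, pair$pct$voxels)
  expect_identical(pair$cbct_labels$labels, pair$pct_labels$labels)
})

test_that("pairs with the same seeds are identical; body stays put", {
  p1 <- fixture_pair(31, 100)
  p2 <- make_pair(phantom_spec(seed = 31), degradation_spec(seed = 32),
                  deformation_spec(seed = 33), bladder_diff_target = 100)
  expect_identical(p1$cbct$voxels, p2$cbct$voxels)
  expect_gte(dsc(p1$pct_labels$labels > 0, p1$cbct_labels$labels > 0), 0.95)
})

test_that("measured bladder Diff is monotone in the bladder scale", {
  diffs <- sapply(c(10, 60, 150), function(t) fixture_pair(31, t)$measured_diff)
  expect_true(all(diff(diffs) > 0))
})

test_that("write_pair emits the five NIfTI artifacts", {
  pair <- fixture_pair(31, 100)
  d <- file.path(tempdir(), "pairout")
  write_pair(pair, d)
  expect_setequal(list.files(d), c("pct.nii.gz", "pct_labels.nii.gz",
                                   "cbct.nii.gz", "cbct_labels.nii.gz",
                                   "gt_field.nii.gz"))
  rt <- read_volume(file.path(d, "cbct.nii.gz"))
  expect_equal(rt$voxels, pair$cbct$voxels, tolerance = 1e-4)  # float32 file
})
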