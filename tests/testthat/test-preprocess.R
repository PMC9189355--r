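test_that("skin mask recovers the phantom body and excludes the couch", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  vol <- degrade_to_cbct(ph$volume, ph$labels$labels > 0,
                         degradation_spec(couch = TRUE, seed = 22))
  skin <- extract_skin_mask(vol)
  body <- ph$labels$labels > 0
  expect_gte(dsc(skin, body), 0.98)
  couch_voxels <- vol$voxels > -400 & !body
  expect_equal(sum(skin & couch_voxels), 0)
  expect_error(extract_skin_mask(image_volume(array(-1000, c(4, 8, 8)))),
               "threshold")
})

test_that("fill_outside_body sets exactly the exterior to air", {
  v <- image_volume(array(100, c(3, 4, 5)))
  expect_identical(fill_outside_body(v, array(TRUE, c(3, 4, 5)))$voxels,
                   v$voxels)
  expect_true(all(fill_outside_body(v, array(FALSE, c(3, 4, 5)))$voxels == -1000))
  m <- array(FALSE, c(3, 4, 5)); m[2, 2:3, 2:4] <- TRUE
  out <- fill_outside_body(v, m)
  expect_true(all(out$voxels[!m] == -1000))
  expect_true(all(out$voxels[m] == 100))
  expect_error(fill_outside_body(v, array(TRUE, c(1, 1, 1))), "shape")
})

test_that("resampling preserves constants, identity and extent arithmetic", {
  v <- image_volume(smooth_vol(c(6, 12, 10), seed = 1), spacing = c(5, 2, 2))
  same <- resample(v, c(5, 2, 2))
  expect_equal(same$voxels, v$voxels, tolerance = 1e-6)
  const <- resample(image_volume(array(7, c(4, 6, 6)), spacing = c(5, 2, 2)),
                    c(5, 1, 1))
  expect_true(all(abs(const$voxels - 7) < 1e-9))
  up <- resample(v, c(5, 1, 1))
  expect_equal(dim(up$voxels)[2:3], c(23L, 19L))   # (n-1)*2 + 1
  expect_equal(up$spacing, c(5, 1, 1))
  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("rigid alignment recovers identity and pure translations", {
  ph <- generate_phantom(phantom_spec(seed = 23))
  vol <- ph$volume
  ra <- rigid_align(vol, vol)
  expect_lt(max(abs(ra$transform$translation)), 2)    # within one voxel (2 mm)
  expect_lt(abs(ra$transform$rotation_deg), 1)
  # moving = vol resampled under t = (0,10,-10); content shifts by -t, so
  # aligning it back must recover the inverse translation (0,-10,10)
  tr <- rigid_transform(c(0, 10, -10), 0)
  moving <- apply_rigid(vol, tr)
  ra2 <- rigid_align(moving, vol)
  expect_lt(max(abs(ra2$transform$translation - c(0, -10, 10))), 2)
  expect_gte(ra2$ncc, 0.95)
  # search never accepts a worse NCC than the centroid start
  cfg <- preprocess_config()
  clip <- function(x) pmin(pmax(x$voxels, -250), 200)
  expect_gte(ra2$ncc, ncc(clip(vol), clip(ra2$aligned)) - 1e-9)
})

test_that("centered crop hits the exact size, pads with air, keeps z extent", {
  ph <- generate_phantom(phantom_spec(seed = 24))
  skin <- ph$labels$labels > 0
  cr <- crop_centered(ph$volume, skin, c(96L, 128L))
  expect_equal(dim(cr$voxels), c(24L, 96L, 128L))
  # already-centered crop of the same size is the identity
  ctr <- floor(colMeans(which(skin, arr.ind = TRUE)))[2:3]
  expect_equal(attr(cr, "crop_offset"), unname(c(ctr[1] - 48, ctr[2] - 64)))
  small <- crop_centered(ph$volume, skin, c(120L, 160L))   # larger than grid
  expect_equal(dim(small$voxels)[2:3], c(120L, 160L))
  expect_true(any(small$voxels == -1000))
  border <- small$voxels[, 1, ]
  expect_true(all(border == -1000))
  lab_cr <- crop_centered(ph$labels, skin, c(120L, 160L))
  expect_true(all(lab_cr$labels[, 1, ] == 0L))
  expect_error(crop_centered(ph$volume, skin & FALSE, c(8L, 8L)), "empty")
})

test_that("registration normalization maps the clip range onto (-1, 1)", {
  cfg <- preprocess_config()
  v <- array(c(-1000, -250, -25, 200, 500), c(5, 1, 1))
  n <- normalize_registration(image_volume(v), cfg)
  expect_equal(as.vector(n), c(-1, -1, 0, 1, 1))
  # monotone non-decreasing in HU
  hu <- seq(-400, 400, by = 7)
  nn <- normalize_registration(array(hu, c(length(hu), 1, 1)), cfg)
  expect_true(all(diff(as.vector(nn)) >= 0))
})

test_that("tanh normalization and its inverse are exact within 0.5 HU", {
  expect_equal(normalize_tanh(array(0, c(1, 1, 1)))[1], 0)
  expect_equal(normalize_tanh(array(400, c(1, 1, 1)))[1], tanh(1))
  hu <- seq(-1000, 1000, by = 1)
  rt <- inverse_tanh(normalize_tanh(array(hu, c(length(hu), 1, 1))))
  expect_lt(max(abs(as.vector(rt) - hu)), 0.5)
  # inverse is bounded by the clamp
  expect_lte(max(abs(inverse_tanh(array(c(-1, 1), c(2, 1, 1))))), 1200 + 1e-6)
  # strictly increasing
  nt <- normalize_tanh(array(hu, c(length(hu), 1, 1)))
  expect_true(all(diff(as.vector(nt)) > 0))
})

test_that("the full preprocessing chain is deterministic and ordered", {
  pair <- fixture_pair(41, 30)
  pp1 <- preprocess_pair(pair$pct, pair$cbct, pair$pct_labels,
                         pair$cbct_labels, align = TRUE)
  pp2 <- preprocess_pair(pair$pct, pair$cbct, pair$pct_labels,
                         pair$cbct_labels, align = TRUE)
  expect_identical(pp1$pct$voxels, pp2$pct$voxels)
  expect_identical(pp1$cbct_labels$labels, pp2$cbct_labels$labels)
  expect_equal(dim(pp1$pct$voxels)[2:3], c(96L, 128L))
  # phantom pairs are generated aligned: the rigid search stays near identity
  expect_lt(max(abs(pp1$transform$translation)), 3)
})
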