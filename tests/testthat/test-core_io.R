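test_that("image volumes validate their invariants", {
  expect_error(image_volume(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(0, 1, 1)), "spacing")
  expect_error(image_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  v <- image_volume(array(0, c(2, 3, 4)), c(5, 1, 1))
  expect_identical(dim(v$voxels), c(2L, 3L, 4L))
})

test_that("NIfTI round trip preserves voxels and spacing, axis order (z,y,x)", {
  set.seed(1)
  arr <- array(round(rnorm(4 * 6 * 8) * 200), c(4, 6, 8))
  v <- image_volume(arr, spacing = c(5, 1, 1))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  v2 <- read_volume(tf)
  expect_equal(v2$voxels, v$voxels)          # exact: integer-valued floats
  expect_equal(v2$spacing, c(5, 1, 1))
  # reading twice yields the same in-memory layout
  v3 <- read_volume(tf)
  expect_identical(v2$voxels, v3$voxels)
})

test_that("label maps round trip and reject bad content", {
  lm <- label_map(array(sample(0:2, 24, TRUE), c(2, 3, 4)), spacing = c(5, 2, 2))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(lm, tf)
  lm2 <- read_volume(tf, labels = TRUE)
  expect_equal(lm2$labels, lm$labels)
  expect_error(label_map(array(-1L, c(2, 2, 2))), "non-negative")
  expect_error(label_map(array(99L, c(2, 2, 2))), "organ_table")
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume(tempfile()), "not found")
  tf <- tempfile(fileext = ".nii.gz")
  arr4 <- array(0, c(3, 3, 3, 2))
  RNifti::writeNifti(RNifti::asNifti(arr4), tf)
  expect_error(read_volume(tf), "3D")
  expect_error(write_volume(image_volume(array(0, c(2, 2, 2))),
                            file.path(tempfile(), "nested", "x.nii")),
               "directory")
})

test_that("extract_mask counts voxels and rejects unknown organs", {
  lab <- array(0L, c(4, 5, 6))
  lab[1:2, 1:3, 1:4] <- 2L                   # 24-voxel bladder
  lm <- label_map(lab, spacing = c(1, 1, 1))
  expect_equal(sum(extract_mask(lm, "bladder")), 24)
  expect_false(any(extract_mask(lm, "spinal_cord")))
  expect_error(extract_mask(lm, "prostate"), "unknown organ")
})

test_that("run configuration validates and round-trips through YAML", {
  expect_error(run_config(seed = -1), "seed")
  expect_error(run_config(scale_preset = "huge"), "arg")
  cfg <- run_config(seed = 7, scale_preset = "paper", out_dir = "o")
  tf <- tempfile(fileext = ".yaml")
  write_run_config(cfg, tf)
  cfg2 <- read_run_config(tf)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$scale_preset, "paper")
})
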