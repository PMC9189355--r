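# Loop-based oracle for the diffusion smoothness penalty.
oracle_smoothness <- function(field) {
  d <- dim(field)[1:3]
  acc <- 0; n <- 0
  for (c in 1:3) for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (z < d[1]) { acc <- acc + (field[z + 1, y, x, c] - field[z, y, x, c])^2; n <- n + 1 }
    if (y < d[2]) { acc <- acc + (field[z, y + 1, x, c] - field[z, y, x, c])^2; n <- n + 1 }
    if (x < d[3]) { acc <- acc + (field[z, y, x + 1, c] - field[z, y, x, c])^2; n <- n + 1 }
  }
  acc / n
}

test_that("warping by a zero field is the identity; labels stay label-valued", {
  v <- smooth_vol(c(5, 7, 9), seed = 1)
  f0 <- array(0, c(5, 7, 9, 3))
  expect_identical(warp(v, f0), v)
  lm <- label_map(array(sample(0:3, 315, TRUE), c(5, 7, 9)),
                  organ_table = c(body = 1L, bladder = 2L, spinal_cord = 3L))
  wl <- warp(lm, f0)
  expect_identical(wl$labels, lm$labels)
  f <- array(rnorm(5 * 7 * 9 * 3), c(5, 7, 9, 3))
  expect_true(all(warp(lm, f)$labels %in% 0:3))
  expect_error(warp(v, f0, mode = "cubic"), "mode")
})

test_that("a constant integer field matches the array-shift oracle", {
  v <- smooth_vol(c(5, 7, 9), seed = 2)
  f <- array(0, c(5, 7, 9, 3)); f[, , , 3] <- 3      # read 3 columns ahead
  w <- warp(v, f, fill = 0)
  expect_lt(max(abs(w[, , 1:6] - v[, , 4:9])), 1e-6)
  expect_true(all(w[, , 7:9] == 0))                   # out-of-bounds fill
})

test_that("field composition has an identity element and adds translations", {
  d <- c(4, 6, 8)
  f <- array(rnorm(prod(d) * 3) * 0.5, c(d, 3))
  z <- array(0, c(d, 3))
  expect_equal(compose_fields(z, f), f, tolerance = 1e-12)
  expect_equal(compose_fields(f, z), f, tolerance = 1e-12)
  a <- z; a[, , , 2] <- 0.7
  b <- z; b[, , , 3] <- -0.4
  ab <- compose_fields(a, b)
  expect_equal(ab[, , , 2], array(0.7, d), tolerance = 1e-12)
  expect_equal(ab[, , , 3], array(-0.4, d), tolerance = 1e-12)
  expect_error(compose_fields(f, array(0, c(2, 2, 2, 3))), "shape")
})

test_that("warping by a composition matches sequential warping on smooth data", {
  d <- c(24L, 96L, 128L); sp <- c(5, 2, 2)
  v <- smooth_vol(d, seed = 11, scale = 150, coarse = 8)  # smooth HU-scale volume
  f1 <- sample_deformation(deformation_spec(seed = 5, max_disp_mm = 8), d, sp)
  f2 <- sample_deformation(deformation_spec(seed = 6, max_disp_mm = 8), d, sp)
  once <- warp(v, compose_fields(f1, f2), fill = 0)
  seq2 <- warp(warp(v, f1, fill = 0), f2, fill = 0)
  expect_lt(mean(abs(once - seq2)), 1)         # < 1 HU
})

test_that("smoothness loss matches its loop oracle and scales quadratically", {
  set.seed(7)
  f <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  expect_equal(smoothness_loss(f), oracle_smoothness(f), tolerance = 1e-12)
  expect_equal(smoothness_loss(array(2.5, c(4, 4, 4, 3))), 0)
  ramp <- array(0, c(8, 8, 8, 3))
  ramp[, , , 3] <- rep(0:7, each = 64)                 # dx component = x
  expect_equal(smoothness_loss(ramp), oracle_smoothness(ramp), tolerance = 1e-12)
  expect_equal(smoothness_loss(3 * f), 9 * smoothness_loss(f), tolerance = 1e-9)
})

test_that("a fresh model predicts a near-identity field, seeded deterministically", {
  cfg <- msnet_config(base_ch = 4L, seed = 12)
  m1 <- build_msnet(cfg)
  m2 <- build_msnet(cfg)
  expect_identical(m1$nets[[1]], m2$nets[[1]])
  x <- array(tanh(rnorm(8 * 16 * 16)), c(8, 16, 16))
  fwd <- cbctqi:::msnet_stage_pass(m1$nets[[1]], x, x)
  expect_lt(mean(abs(fwd$y)), 0.1)
  expect_equal(dim(fwd$y), c(8L, 16L, 16L, 3L))
  expect_error(cbctqi:::check_msnet_dims(c(8L, 18L, 24L), c(2L, 1L)), "divisible")
})

test_that("short instance training reduces the loss and is deterministic", {
  set.seed(13)
  base <- smooth_vol(c(8, 16, 16), seed = 13, scale = 0.5)
  mv <- tanh(base)
  fx <- tanh(base[, c(2:16, 16), ])                  # ~1 voxel shift in y
  cfg <- msnet_config(stages = 1L, scales = 1L, base_ch = 4L,
                      iters = 40L, z_pool = 1L, seed = 14)
  r1 <- train_registration(list(list(moving = mv, fixed = fx)), cfg)
  expect_lt(tail(r1$history$total, 1), r1$history$total[1])
  r2 <- train_registration(list(list(moving = mv, fixed = fx)), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$fields[[1]], r2$fields[[1]])
  expect_error(train_registration(list(list(moving = mv * 3, fixed = fx)), cfg),
               "normalized")
})

test_that("register() runs all stages and self-registration stays near zero", {
  set.seed(15)
  base <- smooth_vol(c(8, 32, 32), seed = 15, scale = 0.5)
  i <- tanh(base)
  cfg <- msnet_config(base_ch = 4L, iters = c(10L, 5L, 2L), z_pool = 1L,
                      scales = c(2L, 1L), stages = 2L, seed = 16)
  tr <- train_registration(list(list(moving = i, fixed = i)), cfg)
  res <- register(tr$model, i, i)
  expect_length(res$stage_fields, 2)
  expect_lt(mean(sqrt(apply(res$field^2, 1:3, sum))), 0.5)
})

test_that("contour propagation by the true field recovers the CBCT contours", {
  pair <- fixture_pair(11, 10)
  dm <- propagate_contours(pair$pct_labels, pair$gt_field)
  expect_identical(dm$organ_table, pair$pct_labels$organ_table)
  expect_gte(dsc(extract_mask(dm, "bladder"),
                 extract_mask(pair$cbct_labels, "bladder")), 0.95)
  expect_true(all(dm$labels %in% c(0L, pair$pct_labels$organ_table)))
  expect_error(propagate_contours(pair$pct_labels, array(0, c(2, 2, 2, 3))),
               "grid")
})
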