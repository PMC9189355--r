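# Oracles live in helper-oracles.R (shared with the acceptance suite).

test_that("dsc matches closed forms and handles degenerate masks", {
  a <- array(FALSE, c(2, 4, 4)); b <- a
  a[1, 1:2, 1:4] <- TRUE                      # |a| = 8
  b[1, 1:2, 1:2] <- TRUE; b[2, 1, 1:4] <- TRUE  # |b| = 8, overlap 4
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  disj <- array(FALSE, dim(a)); disj[2, 3:4, ] <- TRUE
  expect_equal(dsc(a, disj), 0)
  expect_error(dsc(a, array(FALSE, c(1, 1, 1))), "shape")
})

test_that("dsc grows when the intersection grows at fixed mask sizes", {
  a <- array(FALSE, c(1, 4, 4)); a[1, 1:2, ] <- TRUE
  prev <- -1
  for (k in 0:4) {
    b <- array(FALSE, c(1, 4, 4))
    if (k > 0) b[1, 1, seq_len(k)] <- TRUE            # k voxels inside a
    if (k < 4) b[1, 4, seq_len(4 - k)] <- TRUE        # rest outside a
    d <- dsc(a, b)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("nmi agrees with a brute-force joint-histogram oracle", {
  set.seed(2)
  for (i in 1:3) {
    a <- array(runif(16^3, -1000, 1500), c(16, 16, 16))
    b <- a * runif(1, 0.5, 1.5) + rnorm(16^3, 0, 100)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
  }
  a <- array(rnorm(1000) * 300, c(10, 10, 10))
  expect_equal(nmi(a, a), 1, tolerance = 1e-9)
  expect_error(nmi(a, array(0, dim(a))), "degenerate")
})

test_that("nmi of independent images is near zero", {
  set.seed(3)
  cfg <- metrics_config(nmi_bins = 16L)
  a <- array(runif(1e5, -1000, 1500), c(50, 50, 40))
  b <- array(runif(1e5, -1000, 1500), c(50, 50, 40))
  expect_lt(nmi(a, b, cfg), 0.02)
})

test_that("ncc matches its oracle and affine relations", {
  set.seed(4)
  a <- array(rnorm(8^3), c(8, 8, 8))
  b <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(ncc(a, b), oracle_ncc(a, b), tolerance = 1e-12)
  expect_equal(ncc(a, a), 1, tolerance = 1e-9)
  expect_equal(ncc(a, 2.5 * a + 7), 1, tolerance = 1e-9)
  expect_equal(ncc(a, -0.5 * a + 3), -1, tolerance = 1e-9)
  expect_error(ncc(a, array(1, dim(a))), "variance")
})

test_that("error metrics match closed forms; PSNR uses the reference max", {
  a <- array(c(1000, rep(0, 99)), c(10, 10, 1))
  em <- error_metrics(a, a + 100)
  expect_equal(em$mae, 100)
  expect_equal(em$rmse, 100)
  expect_equal(em$psnr, 20)                  # 10 log10(1000^2 / 100^2)
  expect_equal(error_metrics(a, a)$psnr, Inf)
  set.seed(5)
  x <- array(rnorm(64), c(4, 4, 4)); y <- array(rnorm(64), c(4, 4, 4))
  expect_gte(error_metrics(x, y)$rmse, error_metrics(x, y)$mae)
})

test_that("ssim matches loop oracles, local and global", {
  set.seed(6)
  a <- array(rnorm(2 * 9 * 11) * 100 + 50, c(2, 9, 11))
  b <- a + array(rnorm(length(a)) * 30, dim(a))
  cfg <- metrics_config(ssim_radius = 2L)
  expect_equal(ssim(a, b, cfg), oracle_ssim_local(a, b, r = 2), tolerance = 1e-9)
  expect_equal(ssim(a, b, cfg, window = "global"), oracle_ssim_global(a, b),
               tolerance = 1e-12)
  expect_equal(ssim(a, a, cfg), 1, tolerance = 1e-9)
  expect_equal(ssim(array(5, c(2, 4, 4)), array(5, c(2, 4, 4)),
                    window = "global"), 1)
  expect_error(ssim(a, b, metrics_config(ssim_radius = 20L)), "window")
})

test_that("anti-correlated structured images give negative ssim", {
  # window-scale zero-mean oscillation: with a 7-wide window and period-7
  # structure the luminance factor stays near +c1 while the covariance term
  # flips sign, so SSIM(i, -i) is negative
  y <- matrix(rep(sin(2 * pi * (1:28) / 7), each = 28), 28, 28, byrow = TRUE)
  a <- array(0, c(2, 28, 28)); a[1, , ] <- 100 * y; a[2, , ] <- 100 * t(y)
  expect_lt(ssim(a, -a, metrics_config(ssim_radius = 3L)), 0)
})

test_that("volume difference statistic and strata match the definitions", {
  expect_equal(volume_diff(150, 100), 50)
  expect_equal(volume_diff(100, 150), 50)     # symmetric
  expect_equal(volume_diff(100, 100), 0)
  expect_equal(volume_diff(210, 100), 110)
  expect_equal(diff_stratum(110), ">100%")
  expect_equal(diff_stratum(c(5, 20, 35, 75, 150)),
               c("<20%", "<20%", "20%-50%", "50%-100%", ">100%"))
  expect_error(volume_diff(0, 10), "positive")
})

test_that("symmetric metrics are symmetric", {
  set.seed(8)
  a <- array(runif(6^3, -500, 500), c(6, 6, 6))
  b <- array(runif(6^3, -500, 500), c(6, 6, 6))
  expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  expect_equal(ncc(a, b), ncc(b, a), tolerance = 1e-12)
  expect_equal(error_metrics(a, b)$mae, error_metrics(b, a)$mae)
  expect_equal(error_metrics(a, b)$rmse, error_metrics(b, a)$rmse)
})
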