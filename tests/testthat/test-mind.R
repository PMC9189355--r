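test_that("descriptor of a constant image is 1 everywhere, channels in (0,1]", {
  p <- mind_params()
  d <- mind_descriptor(array(5, c(4, 5, 6)), p)
  expect_true(all(d == 1))
  set.seed(1)
  d2 <- mind_descriptor(array(rnorm(4 * 5 * 6), c(4, 5, 6)), p)
  expect_true(all(d2 > 0 & d2 <= 1))
  expect_equal(dim(d2), c(4L, 5L, 6L, 6L))
})

test_that("descriptor is invariant to positive affine intensity maps", {
  i <- smooth_vol(c(6, 10, 12), seed = 2)
  for (er in c(1e-6, 1)) {
    p <- mind_params(eps_rel = er)
    d1 <- mind_descriptor(i, p)
    d2 <- mind_descriptor(1.7 * i + 40, p)
    expect_lt(max(abs(d1 - d2)), 1e-6)
  }
})

test_that("mind_loss identities: zero at equality, near-zero under affine maps", {
  i <- smooth_vol(c(5, 8, 9), seed = 3)
  p <- mind_params()
  expect_identical(mind_loss(i, i, p), 0)
  expect_lt(mind_loss(i, 0.5 * i + 0.1, p), 1e-5)
  expect_gte(mind_loss(i, i[c(2:5, 1), , ], p), 0)
  expect_error(mind_loss(i, i[, , 1:2], p), "shape")
  expect_error(mind_loss(i, i, p, region = array(0, dim(i))), "empty")
})

test_that("analytic gradient matches central differences on a 5^3 input", {
  set.seed(4)
  i1 <- array(rnorm(125), c(5, 5, 5))
  i2 <- array(rnorm(125), c(5, 5, 5))
  p <- mind_params()
  g <- mind_loss(i1, i2, p, grad = TRUE)
  f <- function(v) mind_loss(i1, array(v, c(5, 5, 5)), p)
  idx <- sample(125, 25)
  for (k in idx) {
    h <- 1e-6
    v1 <- as.vector(i2); v1[k] <- v1[k] + h
    v2 <- as.vector(i2); v2[k] <- v2[k] - h
    num <- (f(v1) - f(v2)) / (2 * h)
    expect_lt(abs(num - g$grad[k]) / max(abs(num), abs(g$grad[k]), 1e-8), 1e-4)
  }
})

test_that("loss is structure-sensitive: matched pair beats slice-shuffled pair", {
  pair <- fixture_pair(11, 10)
  p <- mind_params(eps_rel = 1)
  ct <- normalize_registration(pair$cbct_clean)
  cb <- normalize_registration(pair$cbct)
  shuffled <- cb[c(13:24, 1:12), , ]
  expect_lt(mind_loss(ct, cb, p), mind_loss(ct, shuffled, p))
})

test_that("2D slice mode uses four in-plane offsets and keeps the identities", {
  p2 <- mind_params(ndim = 2)
  expect_equal(nrow(p2$offsets), 4L)
  sl <- matrix(smooth_vol(c(1, 12, 14), seed = 5), 12, 14)
  expect_identical(mind_loss(sl, sl, p2), 0)
  r <- mind_loss(sl, sl * 0.7 + 10, p2, grad = TRUE)
  expect_lt(r$loss, 1e-5)
  expect_equal(dim(r$grad), dim(sl))
})
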