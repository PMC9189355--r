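test_that("generators map slices to same-shape slices strictly inside (-1,1)", {
  for (kind in c("resnet15", "unet5")) {
    g <- build_generator(generator_config(kind, base_ch = 4L), seed = 1)
    x <- array(tanh(rnorm(96 * 128 * 2)), c(96, 128, 1, 2))
    y <- cbctqi:::gen_forward(g, x)$y
    expect_equal(dim(y), dim(x))
    expect_true(all(y > -1 & y < 1))
  }
  g2 <- build_generator(generator_config("resnet15", base_ch = 4L), seed = 1)
  g3 <- build_generator(generator_config("resnet15", base_ch = 4L), seed = 1)
  expect_identical(g2$net, g3$net)
  expect_error(cbctqi:::gen_forward(
    build_generator(generator_config("unet5", base_ch = 4L), 1),
    array(0, c(50, 60, 1, 1))), "divisible")
})

test_that("unet5 backward agrees with finite differences through the skips", {
  set.seed(2)
  g <- build_generator(generator_config("unet5", base_ch = 2L), seed = 3)
  x <- array(tanh(rnorm(32 * 32)), c(32, 32, 1, 1))
  fwd <- cbctqi:::gen_forward(g, x)
  dy <- array(rnorm(length(fwd$y)) * 0.1, dim(fwd$y))
  bk <- cbctqi:::gen_backward(g, fwd$caches, dy)
  f <- function(v) sum(cbctqi:::gen_forward(g, array(v, dim(x)))$y * dy)
  # single-precision convs: probe directional derivatives (aggregate signal
  # well above the float noise floor) instead of single components
  for (k in 1:4) {
    v <- array(rnorm(length(x)), dim(x)); v <- v / sqrt(sum(v^2))
    h <- 5e-3
    num <- (f(x + h * v) - f(x - h * v)) / (2 * h)
    an <- sum(bk$dx * v)
    expect_lt(abs(num - an) / max(abs(num), abs(an), 2e-2), 5e-2)
  }
})

test_that("discriminator yields a patch score grid, finite at extremes", {
  d <- build_discriminator(8L, seed = 4)
  x <- array(tanh(rnorm(96 * 128 * 2)), c(96, 128, 1, 2))
  s <- discriminate(d, x)
  expect_gt(dim(s)[1], 1)
  expect_gt(dim(s)[2], 1)
  expect_identical(s, discriminate(d, x))
  expect_true(all(is.finite(discriminate(d, array(1, c(96, 128, 1, 1))))))
  expect_true(all(is.finite(discriminate(d, array(-1, c(96, 128, 1, 1))))))
})

test_that("the generator objective satisfies its formula identities", {
  set.seed(5)
  mk <- function(s) list(
    g_cbct_ct = build_generator(generator_config("resnet15", base_ch = 4L), s),
    g_ct_cbct = build_generator(generator_config("resnet15", base_ch = 4L), s + 1),
    d_ct = build_discriminator(4L, s + 2),
    d_cbct = build_discriminator(4L, s + 3))
  a <- array(tanh(rnorm(32 * 32 * 2) * 0.5), c(32, 32, 1, 2))
  b <- array(tanh(rnorm(32 * 32 * 2) * 0.5), c(32, 32, 1, 2))
  cfg <- cyclegan_config(batch = 2L, epochs = 2L, seed = 6, disc_ch = 4L)
  r <- cyclegan_step(a, b, mk(10), cfg)
  expect_equal(r$losses[["l_g"]],
               r$losses[["l_adv"]] + 10 * r$losses[["l_cycle"]] +
                 10 * r$losses[["l_sc"]], tolerance = 1e-6)
  # lambda = mu = 0 reduces the objective to the adversarial term
  cfg0 <- cyclegan_config(lambda = 0, mu = 0, batch = 2L, epochs = 2L,
                          seed = 6, disc_ch = 4L)
  r0 <- cyclegan_step(a, b, mk(10), cfg0)
  expect_equal(r0$losses[["l_g"]], r0$losses[["l_adv"]])
  # identity generators on identical domains: perfect reconstruction
  rid <- cyclegan_step(a, a, mk(20), cfg)
  expect_lt(rid$losses[["l_cycle"]], 1e-4)   # fresh skip generators = identity
  expect_lt(rid$losses[["l_sc"]], 1e-4)
  expect_error(cyclegan_step(a, array(0, c(16, 16, 1, 2)), mk(10), cfg),
               "shape")
})

test_that("the step-size schedule is constant then linear to zero", {
  cfg <- cyclegan_config(epochs = 200L, seed = 1)
  expect_equal(cyclegan_lr(cfg, 1), 0.002)
  expect_equal(cyclegan_lr(cfg, 100), 0.002)
  expect_equal(cyclegan_lr(cfg, 150), 0.001)
  expect_equal(cyclegan_lr(cfg, 200), 0)
  cfg2 <- cyclegan_config(epochs = 8L, seed = 1)
  expect_equal(cyclegan_lr(cfg2, 6), 0.002 * 2 / 4)
})

test_that("a tiny training run is seed-deterministic with finite history", {
  pair <- fixture_pair(11, 10)
  cfg <- cyclegan_config(epochs = 2L, batch = 4L, slice_stride = 8L,
                         disc_ch = 8L, seed = 9)
  gcfg <- generator_config("resnet15", base_ch = 4L)
  f1 <- train_cyclegan(list(pair$cbct), list(pair$pct), cfg, gcfg)
  f2 <- train_cyclegan(list(pair$cbct), list(pair$pct), cfg, gcfg)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 2)
  expect_true(all(is.finite(as.matrix(f1$history))))
  expect_error(train_cyclegan(list(), list(pair$pct), cfg, gcfg), "empty")
})

test_that("synthesis keeps the grid and the inverse-map HU bounds", {
  pair <- fixture_pair(11, 10)
  g <- build_generator(generator_config("resnet15", base_ch = 4L), seed = 11)
  sct <- synthesize_ct(g, pair$cbct)
  expect_equal(dim(sct$voxels), dim(pair$cbct$voxels))
  expect_equal(sct$spacing, pair$cbct$spacing)
  expect_gte(min(sct$voxels), -1200 - 1e-6)
  expect_lte(max(sct$voxels), 1200 + 1e-6)
  # a fresh skip generator is the identity up to the tanh round trip, so
  # synthesis geometry follows the CBCT exactly at initialization
  body <- pair$cbct_labels$labels > 0
  expect_lt(mean(abs(sct$voxels[body] - pair$cbct$voxels[body])), 1)
})
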