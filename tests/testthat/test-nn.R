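# The conv kernels run their GEMM in single precision, so finite-difference
# probes use a wide step and relative comparison.

fd_check <- function(f, x, g, idx, h = 1e-2, tol = 5e-3) {
  for (i in idx) {
    x1 <- x; x1[i] <- x1[i] + h
    x2 <- x; x2[i] <- x2[i] - h
    num <- (f(x1) - f(x2)) / (2 * h)
    expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-6), tol)
  }
}

test_that("conv3d forward/backward agree with finite differences", {
  set.seed(1)
  x <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
  w <- rnorm(27 * 2 * 3) * 0.3; b <- rnorm(3) * 0.1
  for (stride in c(1L, 2L)) {
    y <- cbctqi:::conv3d_forward_cpp(x, dim(x), w, 3L, 3L, b, stride, 1L)
    dy <- array(rnorm(length(y)), dim(y))
    bk <- cbctqi:::conv3d_backward_cpp(x, dim(x), w, 3L, 3L, stride, 1L, dy)
    fx <- function(v) sum(cbctqi:::conv3d_forward_cpp(v, dim(x), w, 3L, 3L, b, stride, 1L) * dy)
    fw <- function(v) sum(cbctqi:::conv3d_forward_cpp(x, dim(x), v, 3L, 3L, b, stride, 1L) * dy)
    fd_check(fx, x, bk$dx, sample(length(x), 5))
    fd_check(fw, w, bk$dw, sample(length(w), 5))
  }
})

test_that("conv2d forward/backward agree with finite differences", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  w <- rnorm(16 * 2 * 2) * 0.3; b <- rnorm(2) * 0.1
  y <- cbctqi:::conv2d_forward_cpp(x, dim(x), w, 4L, 2L, b, 2L, 1L)
  expect_equal(dim(y), c(4L, 4L, 2L, 3L))
  dy <- array(rnorm(length(y)), dim(y))
  bk <- cbctqi:::conv2d_backward_cpp(x, dim(x), w, 4L, 2L, 2L, 1L, dy)
  fx <- function(v) sum(cbctqi:::conv2d_forward_cpp(v, dim(x), w, 4L, 2L, b, 2L, 1L) * dy)
  fw <- function(v) sum(cbctqi:::conv2d_forward_cpp(x, dim(x), v, 4L, 2L, b, 2L, 1L) * dy)
  fd_check(fx, x, bk$dx, sample(length(x), 6))
  fd_check(fw, w, bk$dw, sample(length(w), 6))
})

test_that("instance norm and activations backpropagate exactly", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  for (ly in list(cbctqi:::ly_in(2, 3), cbctqi:::ly_lrelu(0.2),
                  cbctqi:::ly_tanh())) {
    fwd <- cbctqi:::layer_forward(ly, x)
    dy <- array(rnorm(length(fwd$y)), dim(fwd$y))
    bk <- cbctqi:::layer_backward(ly, fwd$cache, dy)
    f <- function(v) sum(cbctqi:::layer_forward(ly, array(v, dim(x)))$y * dy)
    fd_check(f, x, bk$dx, sample(length(x), 6), h = 1e-5, tol = 1e-4)
  }
})

test_that("nearest upsampling and its backward are adjoint", {
  set.seed(4)
  x <- array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2))
  y <- cbctqi:::upsample_nearest_cpp(x, dim(x), 2L, 2L)
  expect_equal(dim(y), c(6L, 8L, 2L, 2L))
  dy <- array(rnorm(length(y)), dim(y))
  dx <- cbctqi:::upsample_nearest_backward_cpp(dy, dim(dy), 2L, 2L)
  # adjoint identity: <up(x), dy> == <x, up^T(dy)>
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-9)
  x3 <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  y3 <- cbctqi:::upsample_nearest_cpp(x3, dim(x3), 2L, 3L)
  dy3 <- array(rnorm(length(y3)), dim(y3))
  dx3 <- cbctqi:::upsample_nearest_backward_cpp(dy3, dim(dy3), 2L, 3L)
  expect_equal(sum(y3 * dy3), sum(x3 * dx3), tolerance = 1e-9)
})

test_that("average pooling averages blocks", {
  x <- array(1:24, c(2, 3, 4, 1))
  y <- cbctqi:::avgpool3d_cpp(as.double(x), dim(x), 2L, 1L, 2L)
  expect_equal(dim(y), c(1L, 3L, 2L, 1L))
  expect_equal(y[1, 1, 1, 1], mean(x[1:2, 1, c(1, 2), 1]))
})
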