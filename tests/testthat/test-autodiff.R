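# The layer gradients drive every training result downstream, so each
# compiled kernel and tape op is checked against central differences.

test_that("convolution gradients match numeric differentiation", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  for (cfg in list(c(1, 1), c(2, 1), c(1, 0))) {
    run <- function(xv, wv, bv) {
      xn <- nd_param(xv); wn <- nd_param(wv); bn <- nd_param(bv)
      l <- nd_mse(nd_conv2d(xn, wn, bn, cfg[1], cfg[2]), 0.1)
      nd_backward(l)
      list(l = l$value, gx = xn$grad, gw = wn$grad, gb = bn$grad)
    }
    r <- run(x, w, b)
    expect_lt(max(abs(r$gx - numeric_gradient(function(v) run(v, w, b)$l, x))), 1e-6)
    expect_lt(max(abs(r$gw - numeric_gradient(function(v) run(x, v, b)$l, w))), 1e-6)
    expect_lt(max(abs(r$gb - numeric_gradient(function(v) run(x, w, v)$l, b))), 1e-6)
  }
})

test_that("transposed-convolution gradients match numeric differentiation", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  w <- array(rnorm(5 * 5 * 3 * 2) * 0.2, c(5, 5, 3, 2))
  b <- rnorm(3) * 0.1
  run <- function(xv, wv, bv) {
    xn <- nd_param(xv); wn <- nd_param(wv); bn <- nd_param(bv)
    y <- nd_convt2d(xn, wn, bn, 2, 2, 1)
    stopifnot(identical(dim(y$value)[1:2], c(8L, 8L)))   # 4 * stride
    l <- nd_mse(y, 0)
    nd_backward(l)
    list(l = l$value, gx = xn$grad, gw = wn$grad, gb = bn$grad)
  }
  r <- run(x, w, b)
  expect_lt(max(abs(r$gx - numeric_gradient(function(v) run(v, w, b)$l, x))), 1e-6)
  expect_lt(max(abs(r$gw - numeric_gradient(function(v) run(x, v, b)$l, w))), 1e-6)
  expect_lt(max(abs(r$gb - numeric_gradient(function(v) run(x, w, v)$l, b))), 1e-6)
})

test_that("batch-norm, dense, resize and log-loss gradients are exact", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  ga <- runif(3, 0.5, 1.5); be <- rnorm(3) * 0.2
  run_bn <- function(xv, gv, bv) {
    xn <- nd_param(xv); gn <- nd_param(gv); bn <- nd_param(bv)
    l <- nd_mse(nd_batchnorm_train(xn, gn, bn)$node, 0.3)
    nd_backward(l)
    list(l = l$value, gx = xn$grad, gg = gn$grad, gb = bn$grad)
  }
  r <- run_bn(x, ga, be)
  expect_lt(max(abs(r$gx - numeric_gradient(function(v) run_bn(v, ga, be)$l, x))), 1e-6)
  expect_lt(max(abs(r$gg - numeric_gradient(function(v) run_bn(x, v, be)$l, ga))), 1e-6)

  w <- matrix(rnorm(32 * 2) * 0.3, 32, 2); b2 <- rnorm(2) * 0.1
  x4 <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  run_d <- function(xv, wv) {
    xn <- nd_param(xv); wn <- nd_param(wv); bn <- nd_param(b2)
    s <- nd_clamp(nd_sigmoid(nd_dense(nd_flatten(xn), wn, bn)), 1e-7, 1 - 1e-7)
    l <- nd_mean_neglog(s)
    nd_backward(l)
    list(l = l$value, gx = xn$grad, gw = wn$grad)
  }
  r <- run_d(x4, w)
  expect_lt(max(abs(r$gx - numeric_gradient(function(v) run_d(v, w)$l, x4))), 1e-6)
  expect_lt(max(abs(r$gw - numeric_gradient(function(v) run_d(x4, v)$l, w))), 1e-6)

  Mr <- matrix(rnorm(8 * 4), 8, 4); Mc <- matrix(rnorm(8 * 4), 8, 4)
  x5 <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  run_r <- function(xv) {
    xn <- nd_param(xv)
    y <- nd_resize_sep(xn, Mr, Mc)
    l <- nd_mse(nd_concat_c(list(y, nd_relu(y))), 0.2)
    nd_backward(l)
    list(l = l$value, gx = xn$grad)
  }
  r <- run_r(x5)
  expect_lt(max(abs(r$gx - numeric_gradient(function(v) run_r(v)$l, x5))), 1e-6)
})

test_that("gradients accumulate across shared use and reset between passes", {
  x <- nd_param(matrix(2, 1, 1))
  y <- nd_add(x, x)                    # dy/dx = 2
  l <- nd_mse(y, 0)                    # l = 16, dl/dx = 2 * 4 * 2 = 16
  nd_backward(l)
  expect_equal(as.numeric(x$grad), 16)
  l2 <- nd_mse(nd_add(x, x), 0)
  nd_backward(l2)
  expect_equal(as.numeric(x$grad), 16)  # not accumulated across passes
})
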