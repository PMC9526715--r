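# Gradient correctness of the compute engine, checked layer by layer with a
# smooth quadratic head against central finite differences, plus a dual-route
# check of the GEMM 1x1x1 convolution against the direct loop kernel.

ns <- asNamespace("lobeseg")

quad_gradcheck <- function(op, x0, eps = 1e-5, tol = 1e-6) {
  tgt <- array(rnorm(length(op(ns$ag_const(x0))$value)),
               dim = dim(op(ns$ag_const(x0))$value))
  f <- function(xv) {
    y <- op(ns$ag_const(array(xv, dim = dim(x0))))
    sum((y$value - tgt)^2)
  }
  xn <- ns$ag_const(x0)
  xn$requires <- TRUE                  # force gradient tracking to the input
  y <- op(xn)
  diffn <- ns$ag_node(sum((y$value - tgt)^2), parents = list(y))
  diffn$backward <- function(node) ns$ag_accumulate(y, 2 * (y$value - tgt))
  ns$ag_backward(diffn)
  g_an <- xn$grad
  idx <- sample(length(x0), min(12, length(x0)))
  for (i in idx) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g_num <- (f(xp) - f(xm)) / (2 * eps)
    expect_lt(abs(g_an[i] - g_num), tol * max(1, abs(g_num)))
  }
}

test_that("elementwise, normalization and resampling ops backpropagate exactly", {
  set.seed(31)
  x0 <- array(rnorm(4 * 4 * 6 * 6), c(4, 4, 6, 6))
  x0[abs(x0) < 0.05] <- 0.1           # keep away from the ReLU kink
  quad_gradcheck(ns$ag_relu, x0)
  quad_gradcheck(ns$ag_tanh, x0)
  g <- ns$ag_param(rnorm(4)); b <- ns$ag_param(rnorm(4))
  quad_gradcheck(function(x) ns$ag_instance_norm(x, g, b), x0, tol = 1e-5)
  quad_gradcheck(ns$ag_softmax, x0, tol = 1e-5)
  quad_gradcheck(function(x) ns$ag_maxpool(x, c(2L, 2L, 2L)), x0)
  quad_gradcheck(function(x) ns$ag_upsample_nn(x, c(2L, 2L, 2L)), x0)
  quad_gradcheck(function(x) ns$ag_concat(list(x, ns$ag_relu(x))), x0)
})

test_that("convolution gradients match finite differences for 3^3 and 1^3 kernels", {
  set.seed(32)
  for (k in list(c(3L, 3L, 3L), c(1L, 1L, 1L))) {
    x0 <- array(rnorm(3 * 4 * 5 * 5), c(3, 4, 5, 5))
    w <- ns$ag_param(array(rnorm(3 * prod(k) * 2, sd = 0.3),
                           c(3L, k, 2L)))
    b <- ns$ag_param(rnorm(2))
    quad_gradcheck(function(x) ns$ag_conv3d(x, w, b), x0, tol = 1e-5)
  }
})

test_that("the GEMM 1x1x1 convolution equals the direct loop kernel", {
  set.seed(33)
  x <- array(rnorm(5 * 4 * 6 * 7), c(5, 4, 6, 7))
  w <- array(rnorm(5 * 1 * 1 * 1 * 3), c(5, 1, 1, 1, 3))
  b <- rnorm(3)
  gemm <- ns$ag_conv3d(ns$ag_const(x), ns$ag_param(w), ns$ag_param(b))$value
  loop <- ns$.conv3d_fw(x, w, b)
  expect_equal(gemm, loop, tolerance = 1e-12)
})

test_that("AdamW decay is decoupled: lr 0 shrinks weights without a step", {
  set.seed(34)
  p <- ns$ag_param(array(rnorm(10), c(10)))
  p$grad <- array(rnorm(10), c(10))
  before <- p$value
  st <- ns$adamw_state(list(p))
  ns$adamw_step(list(p), st, lr = 0, weight_decay = 0.01)
  expect_equal(p$value, before * 0.99, tolerance = 1e-15)
})

test_that("conv + pool + upsample is covariant to full-stride translations", {
  set.seed(35)
  w <- ns$ag_param(array(rnorm(1 * 27 * 1, sd = 0.5), c(1, 3, 3, 3, 1)))
  b <- ns$ag_param(0)
  net <- function(x) ns$ag_upsample_nn(
    ns$ag_maxpool(ns$ag_conv3d(ns$ag_const(x), w, b), c(2L, 2L, 2L)),
    c(2L, 2L, 2L))$value
  x <- array(0, c(1, 8, 12, 12))
  x[1, 3:5, 4:6, 4:6] <- rnorm(27)
  y1 <- net(x)
  xs <- array(0, dim(x))
  xs[1, , , 3:12] <- x[1, , , 1:10]    # shift by one pooling stride in x
  y2 <- net(xs)
  expect_equal(y2[1, , 3:10, 5:10], y1[1, , 3:10, 3:8], tolerance = 1e-12)
})
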