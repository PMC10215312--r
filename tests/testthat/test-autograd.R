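# Gradient correctness of the autograd engine against central differences,
# on tiny tensors. Every hand-written backward used by the network layers
# is covered through composite graphs.

test_that("convolution, softmax and sigmoid gradients match numerical
           differentiation", {
  set.seed(11)
  xa <- make_random_map(c(4, 4, 2, 1))
  wa <- make_random_map(c(3, 3, 2, 3)) * 0.5
  f <- function(xv, wv) {
    y <- t_conv2d(tensor(xv), tensor(wv), 2L, 1L, 1L)
    as.numeric(t_sum(t_mul(t_softmax(y, 3L), t_sigmoid(y)), 1:4)$v)
  }
  xt <- tensor(xa, requires_grad = TRUE)
  wt <- tensor(wa, requires_grad = TRUE)
  y <- t_conv2d(xt, wt, 2L, 1L, 1L)
  backward(t_sum(t_mul(t_softmax(y, 3L), t_sigmoid(y)), 1:4))
  expect_lt(max(abs(xt$grad - num_grad(function(v) f(v, wa), xa))), 1e-6)
  expect_lt(max(abs(wt$grad - num_grad(function(v) f(xa, v), wa))), 1e-6)
})

test_that("grouped/depthwise convolution gradients are correct", {
  set.seed(12)
  xa <- make_random_map(c(5, 5, 4, 2))
  wa <- make_random_map(c(3, 3, 1, 4)) * 0.5    # depthwise: groups = 4
  f <- function(xv, wv)
    as.numeric(t_sum(t_relu(t_conv2d(tensor(xv), tensor(wv),
                                     1L, 1L, 4L)), 1:4)$v)
  xt <- tensor(xa, requires_grad = TRUE)
  wt <- tensor(wa, requires_grad = TRUE)
  backward(t_sum(t_relu(t_conv2d(xt, wt, 1L, 1L, 4L)), 1:4))
  expect_lt(max(abs(xt$grad - num_grad(function(v) f(v, wa), xa))), 1e-6)
  expect_lt(max(abs(wt$grad - num_grad(function(v) f(xa, v), wa))), 1e-6)
})

test_that("fused batch-norm gradients match the composed definition", {
  set.seed(13)
  xa <- make_random_map(c(3, 4, 2, 3))
  ga <- array(runif(2, 0.5, 1.5), c(1, 1, 2, 1))
  ba <- array(runif(2, -0.5, 0.5), c(1, 1, 2, 1))
  f <- function(xv, gv, bv) {
    r <- t_batchnorm(tensor(xv), tensor(gv), tensor(bv))
    as.numeric(t_sum(t_sigmoid(r$out), 1:4)$v)
  }
  xt <- tensor(xa, requires_grad = TRUE)
  gt <- tensor(ga, requires_grad = TRUE)
  bt <- tensor(ba, requires_grad = TRUE)
  backward(t_sum(t_sigmoid(t_batchnorm(xt, gt, bt)$out), 1:4))
  expect_lt(max(abs(xt$grad - num_grad(function(v) f(v, ga, ba), xa))), 1e-5)
  expect_lt(max(abs(gt$grad - num_grad(function(v) f(xa, v, ba), ga))), 1e-6)
  expect_lt(max(abs(bt$grad - num_grad(function(v) f(xa, ga, v), ba))), 1e-6)
})

test_that("pooling, reshaping and matmul gradients are correct", {
  set.seed(14)
  xa <- make_random_map(c(6, 6, 2, 1))
  wgt <- make_random_map(c(3, 3, 2, 1))
  f1 <- function(xv) as.numeric(
    t_sum(t_mul(t_maxpool(tensor(xv), 3L, 2L, 1L), tensor(wgt^2)), 1:4)$v)
  xt <- tensor(xa, requires_grad = TRUE)
  backward(t_sum(t_mul(t_maxpool(xt, 3L, 2L, 1L), tensor(wgt^2)), 1:4))
  expect_lt(max(abs(xt$grad - num_grad(f1, xa))), 1e-6)

  # 1-D window-2 pool + transpose + slice chain
  ea <- make_random_map(c(1, 5, 3, 2))
  f2 <- function(v) {
    z <- t_pool1d_w2(tensor(v))
    z <- t_aperm(z, c(2, 1, 3, 4))
    as.numeric(t_sum(t_mul(t_slice_c(z, 2:3), t_slice_c(z, 1:2)), 1:4)$v)
  }
  et <- tensor(ea, requires_grad = TRUE)
  z <- t_aperm(t_pool1d_w2(et), c(2, 1, 3, 4))
  backward(t_sum(t_mul(t_slice_c(z, 2:3), t_slice_c(z, 1:2)), 1:4))
  expect_lt(max(abs(et$grad - num_grad(f2, ea))), 1e-6)

  # matmul (linear layer shape)
  aa <- matrix(rnorm(6), 2, 3); bb <- matrix(rnorm(12), 3, 4)
  at <- tensor(aa, requires_grad = TRUE)
  bt <- tensor(bb, requires_grad = TRUE)
  backward(t_sum(t_sigmoid(t_matmul(at, bt)), 1:4))
  f3 <- function(v) as.numeric(
    t_sum(t_sigmoid(t_matmul(tensor(v), tensor(bb))), 1:4)$v)
  expect_lt(max(abs(array(at$grad, dim(aa)) - num_grad(f3, aa))), 1e-6)
})

test_that("broadcasting reduces gradients back to operand shapes", {
  set.seed(15)
  a <- tensor(make_random_map(c(3, 4, 2, 2)), requires_grad = TRUE)
  b <- tensor(make_random_map(c(1, 1, 2, 1)), requires_grad = TRUE)
  backward(t_sum(t_mul(t_add(a, b), b), 1:4))
  expect_identical(dim(a$grad), c(3L, 4L, 2L, 2L))
  expect_identical(dim(b$grad), c(1L, 1L, 2L, 1L))
  fb <- function(v) {
    bt <- tensor(v)
    as.numeric(t_sum(t_mul(t_add(tensor(a$v), bt), bt), 1:4)$v)
  }
  expect_lt(max(abs(b$grad - num_grad(fb, b$v))), 1e-6)
})

test_that("cross-entropy gradient and value are correct", {
  set.seed(16)
  lv <- matrix(rnorm(8), 4, 2)
  tg <- c(2L, 4L)
  lt <- tensor(lv, requires_grad = TRUE)
  loss <- t_cross_entropy(lt, tg)
  p <- softmax_probs(lv)
  expect_equal(as.numeric(loss$v), -mean(log(p[cbind(tg, 1:2)])), tolerance = 1e-12)
  backward(loss)
  f <- function(v) as.numeric(t_cross_entropy(tensor(v), tg)$v)
  expect_lt(max(abs(array(lt$grad, dim(lv)) - num_grad(f, lv))), 1e-6)
})
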