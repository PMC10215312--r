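# Multi-scale attention down-sampling: shape contract, degenerate-weight
# equivalence with plain pooling, parameter accounting, translation
# robustness.

test_that("MADM halves spatial size and sets the channel count", {
  set.seed(41)
  m <- madm_module(64, 128)
  x <- tensor(make_random_map(c(56, 56, 64, 1)))
  y <- fwd(m, x)
  expect_identical(dim(y$v), c(28L, 28L, 128L, 1L))
  # ceil semantics on odd inputs, over random sizes
  for (i in 1:5) {
    h <- sample(2:15, 1); w <- sample(2:15, 1)
    m2 <- madm_module(3, 5)
    y2 <- fwd(m2, tensor(make_random_map(c(h, w, 3, 2))))
    expect_identical(dim(y2$v),
                     c(as.integer(ceiling(h / 2)), as.integer(ceiling(w / 2)),
                       5L, 2L))
  }
  expect_error(madm_config(8, 0), "invalid-config")
  expect_error(fwd(madm_module(4, 4), tensor(array(0, c(1, 4, 4, 1)))),
               "invalid-input")
})

test_that("with zeroed DSC branches and pass-through projection MADM equals
           0.5 x strided max pooling (SE gate at sigmoid(0))", {
  set.seed(42)
  cin <- 6L
  m <- madm_module(cin, cin)
  for (b in c("dsc5", "dsc7")) {
    m$mods[[b]]$mods$dw$params$w$v[] <- 0
    m$mods[[b]]$mods$pw$params$w$v[] <- 0
  }
  m$mods$proj$params$w$v[] <- 0
  for (c in seq_len(cin)) m$mods$proj$params$w$v[1, 1, c, c] <- 1  # pool pass
  m$mods$se$mods$fc1$params$w$v[] <- 0
  m$mods$se$mods$fc2$params$w$v[] <- 0          # gate = sigmoid(0) = 0.5
  x <- make_random_map(c(9, 8, cin, 2))
  y <- fwd(m, tensor(x))
  expect_equal(y$v, 0.5 * oracle_maxpool3s2(x), tolerance = 1e-12)
  # constant map: pool branch of a constant is constant
  xc <- array(0.4, c(8, 8, cin, 1))
  yc <- fwd(m, tensor(xc))
  expect_lt(max(abs(yc$v - 0.2)), 1e-12)
})

test_that("closed-form parameter count equals weight enumeration", {
  set.seed(43)
  cfg <- madm_config(8, 8, se_reduction = 8)
  m <- madm_module(cfg)
  enum <- sum(vapply(collect_params(m), function(p) length(p$v), 1))
  # hand sum: DSC-5, DSC-7 (K^2 C + C N), projection ((C + 2N) N), SE
  expect_identical(madm_param_count(cfg),
                   (25L * 8L + 64L) + (49L * 8L + 64L) + (8L + 16L) * 8L +
                     (8L + 1L + 8L + 8L))
  expect_identical(enum, as.numeric(madm_param_count(cfg)))
  for (i in 1:20) {
    cfg <- madm_config(sample(1:24, 1), sample(1:24, 1),
                       se_reduction = sample(c(2, 4, 8, 16), 1))
    m <- madm_module(cfg)
    enum <- sum(vapply(collect_params(m), function(p) length(p$v), 1))
    expect_identical(enum, as.numeric(madm_param_count(cfg)))
  }
  # count is strictly increasing in out_channels (projection dominates)
  counts <- vapply(c(8, 16, 24, 32), function(co)
    as.numeric(madm_param_count(madm_config(16, co))), 1)
  expect_true(all(diff(counts) > 0))
})

test_that("pooling branch is parameter-free; trainable parts get gradients", {
  set.seed(44)
  m <- madm_module(6, 8, se_reduction = 2)
  # parameters live only in the DSC branches, projection and SE
  nms <- names(collect_params(m))
  expect_true(all(grepl("^(dsc5|dsc7|proj|se)\\.", nms)))
  x <- tensor(make_random_map(c(10, 10, 6, 2)))
  y <- fwd(m, x, training = TRUE)
  backward(t_sum(t_mul(y, tensor(make_random_map(dim(y$v)))), 1:4))
  ps <- collect_params(m)
  grads <- vapply(ps, function(p) if (is.null(p$grad)) 0 else max(abs(p$grad)), 1)
  expect_gt(max(grads[grepl("^dsc5", names(grads))]), 0)
  expect_gt(max(grads[grepl("^dsc7", names(grads))]), 0)
  expect_gt(max(grads[grepl("^se", names(grads))]), 0)
})

test_that("MADM in its smoothing configuration moves less than plain strided
           max pooling under a 2-pixel shift (translation robustness)", {
  # A randomly initialized MADM is not more shift-robust than pooling; the
  # module's purpose is to make an anti-aliasing down-sampler *learnable*.
  # We therefore configure the large-kernel branches to the smoothing
  # solution they are designed to converge to (uniform depthwise kernels,
  # identity pointwise, balanced fusion, neutral SE gate) and compare that
  # realizable configuration with the static pooling baseline.
  set.seed(45)
  rel_madm <- numeric(20); rel_pool <- numeric(20)
  for (i in 1:20) {
    m <- madm_module(3, 3)
    for (b in c("dsc5", "dsc7")) {
      k <- dim(m$mods[[b]]$mods$dw$params$w$v)[1]
      m$mods[[b]]$mods$dw$params$w$v[] <- 1 / (k * k)
      m$mods[[b]]$mods$pw$params$w$v[] <- 0
      for (c in 1:3) m$mods[[b]]$mods$pw$params$w$v[1, 1, c, c] <- 1
    }
    m$mods$proj$params$w$v[] <- 0
    for (c in 1:3) m$mods$proj$params$w$v[1, 1, c + c(0, 3, 6), c] <- 1 / 3
    m$mods$se$mods$fc1$params$w$v[] <- 0
    m$mods$se$mods$fc2$params$w$v[] <- 0
    tex <- make_random_map(c(20, 24, 3, 1))
    shifted <- tex[c(3:20, 19, 18), , , , drop = FALSE]
    y1 <- fwd(m, tensor(tex))$v
    y2 <- fwd(m, tensor(shifted))$v
    p1 <- oracle_maxpool3s2(tex); p2 <- oracle_maxpool3s2(shifted)
    rel_madm[i] <- sqrt(sum((y1 - y2)^2)) / sqrt(sum((y1 - mean(y1))^2))
    rel_pool[i] <- sqrt(sum((p1 - p2)^2)) / sqrt(sum((p1 - mean(p1))^2))
  }
  expect_lt(mean(rel_madm), mean(rel_pool))
})
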