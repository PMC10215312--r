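# Coordinate embedding, directional pooling, LAM and the CLAM gate.

test_that("coordinate embedding and directional pools match loop oracles", {
  # frozen arithmetic cases
  m <- array(c(1, 3, 2, 4), c(2, 2, 1))   # [[1,2],[3,4]] row-major
  expect_equal(coordinate_embed(m), 2.5)
  expect_equal(as.numeric(directional_pool_h(m)), c(1.5, 3.5))
  expect_equal(as.numeric(directional_pool_w(m)), c(2.0, 3.0))
  xc <- array(0.7, c(3, 4, 2))
  expect_equal(coordinate_embed(xc), c(0.7, 0.7))
  expect_true(all(abs(directional_pool_h(xc) - 0.7) < 1e-15))
  expect_true(all(abs(directional_pool_w(xc) - 0.7) < 1e-15))
  # random maps vs brute-force double loops
  set.seed(31)
  x1 <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  expect_equal(coordinate_embed(x1), oracle_coordinate_embed(x1),
               tolerance = 1e-6)
  x2 <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  expect_equal(directional_pool_h(x2), oracle_pool_h(x2), tolerance = 1e-6)
  expect_equal(directional_pool_w(x2), oracle_pool_w(x2), tolerance = 1e-6)
  expect_error(coordinate_embed(1:3), "array")
})

test_that("height-encoding transpose swaps axes and preserves values", {
  set.seed(32)
  z <- array(rnorm(3 * 1 * 8), c(3, 1, 8))
  zt <- transpose_h_encoding(z)
  expect_identical(dim(zt), c(1L, 3L, 8L))
  expect_equal(aperm(zt, c(2, 1, 3)), z)           # involution
  expect_equal(zt[1, 2, 5], z[2, 1, 5])
  expect_error(transpose_h_encoding(array(0, c(3, 2, 8))), "invalid-input")
})

test_that("LAM with degenerate weights squares its input; zero input gives
           zero output", {
  cc <- 4L
  lam <- lam_module(cc, pool = "none")
  # Pa = identity 1x1, C1 = identity DSC kernel
  lam$mods$fc$params$w$v[] <- 0
  for (c in seq_len(cc)) lam$mods$fc$params$w$v[1, 1, c, c] <- 1
  lam$mods$ds$mods$dw$params$w$v[] <- 0
  lam$mods$ds$mods$dw$params$w$v[2, 2, 1, ] <- 1     # center tap
  lam$mods$ds$mods$pw$params$w$v[] <- 0
  for (c in seq_len(cc)) lam$mods$ds$mods$pw$params$w$v[1, 1, c, c] <- 1
  set.seed(33)
  f <- make_random_map(c(1, 6, cc, 2))
  a <- fwd(lam, tensor(f))
  expect_equal(a$v, f * f, tolerance = 1e-12)
  # zero input (weights bias-free): product of two zero branches
  lam2 <- lam_module(cc)
  z <- fwd(lam2, tensor(array(0, c(1, 5, cc, 1))))
  expect_equal(max(abs(z$v)), 0)
  expect_identical(dim(z$v), c(1L, 5L, cc, 1L))
  expect_error(fwd(lam2, tensor(array(0, c(1, 5, 3, 1)))), "channel mismatch")
})

test_that("CLAM preserves shape and normalizes over the channel axis", {
  set.seed(34)
  cl <- clam_module(8L)
  x <- make_random_map(c(14, 9, 8, 2))
  y <- clam_forward(cl, x)
  expect_identical(dim(y$v), c(14L, 9L, 8L, 2L))
  att <- clam_attention(cl, x)
  expect_true(all(att > 0 & att < 1))
  sums <- apply(att, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # constant input + channel-symmetric weights -> constant score tensor
  # -> softmax is uniform along the channel axis
  cs <- clam_module(8L)
  for (lam in list(cs$mods$lam_a, cs$mods$lam_b)) {
    lam$mods$fc$params$w$v[] <- 1 / 8
    lam$mods$ds$mods$dw$params$w$v[] <- 0
    lam$mods$ds$mods$dw$params$w$v[2, 2, 1, ] <- 1
    lam$mods$ds$mods$pw$params$w$v[] <- 1 / 8
  }
  attc <- clam_attention(cs, array(0.3, c(6, 5, 8, 1)))
  expect_lt(max(abs(attc - 1 / 8)), 1e-6)
})

test_that("every CLAM parameter receives nonzero gradient", {
  set.seed(35)
  cl <- clam_module(6L)
  x <- tensor(make_random_map(c(7, 8, 6, 2)))
  y <- fwd(cl, x, training = TRUE)
  backward(t_sum(t_mul(y, tensor(make_random_map(dim(y$v)))), 1:4))
  for (nm in names(collect_params(cl))) {
    p <- collect_params(cl)[[nm]]
    expect_false(is.null(p$grad), info = nm)
    expect_gt(max(abs(p$grad)), 0)
  }
})

test_that("rescaled softmax gate does not collapse magnitudes", {
  set.seed(36)
  ratios <- numeric(10)
  for (i in 1:10) {
    cl <- clam_module(8L)
    x <- make_random_map(c(10, 10, 8, 2))
    y <- clam_forward(cl, x)
    ratios[i] <- mean(abs(y$v)) / mean(abs(x))
  }
  expect_true(all(ratios > 0.25 & ratios < 4))
  # sigmoid gate alternative stays in (0,1)
  cls <- clam_module(4L, gate = "sigmoid")
  a <- clam_attention(cls, make_random_map(c(5, 5, 4, 1)))
  expect_true(all(a > 0 & a < 1))
})
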