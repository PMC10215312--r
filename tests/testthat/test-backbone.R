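# Split-Attention semantics, SCM-Block residual contract, network assembly
# and parameter accounting.

test_that("split attention handles the radix-1 sigmoid case and symmetric
           splits", {
  set.seed(51)
  # r = 1, k = 1: sigmoid-gated single split
  mod <- split_attention_module(4, 1, 1)
  s <- make_random_map(c(3, 3, 4, 1))
  v <- fwd(mod, list(tensor(s)))
  w <- split_attention_weights(mod, list(s))
  expect_true(all(w[[1]] > 0 & w[[1]] < 1))
  gate <- rep(w[[1]][1, ], each = 9)
  expect_equal(as.numeric(v$v), as.numeric(s) * gate, tolerance = 1e-12)
  # r = 2, identical splits and shared per-split gate heads: the two
  # scores are equal, so the softmax yields 0.5 per channel
  mod2 <- split_attention_module(5, 2, 1)
  w2v <- mod2$mods$fc2_1$params$w$v
  w2v[1, 1, , 5 + 1:5] <- w2v[1, 1, , 1:5]      # symmetric heads
  mod2$mods$fc2_1$params$w$v <- w2v
  s2 <- make_random_map(c(4, 4, 5, 1))
  w2 <- split_attention_weights(mod2, list(s2, s2))
  expect_lt(max(abs(w2[[1]] - 0.5)), 1e-12)
  v2 <- fwd(mod2, list(tensor(s2), tensor(s2)))
  expect_equal(v2$v, s2, tolerance = 1e-12)     # 0.5 s + 0.5 s
  expect_error(fwd(mod2, list(tensor(s2))), "invalid-input")
})

test_that("split attention weights sum to one over radix and the fused map
           matches the loop oracle (r = 3, k = 2 and 50 random cases)", {
  set.seed(52)
  mod <- split_attention_module(12, 3, 2)
  splits <- lapply(1:6, function(i) make_random_map(c(4, 4, 12, 1)))
  w <- split_attention_weights(mod, splits)
  for (kk in 1:2) expect_lt(max(abs(colSums(w[[kk]]) - 1)), 1e-5)
  v <- fwd(mod, lapply(splits, tensor))
  expect_lt(max(abs(v$v - oracle_split_attention(mod, splits))), 1e-6)

  for (case in 1:50) {
    r <- sample(1:3, 1); k <- sample(1:2, 1); cc <- sample(c(2, 4, 6), 1)
    h <- sample(2:4, 1)
    mod <- split_attention_module(cc, r, k)
    splits <- lapply(seq_len(r * k), function(i)
      make_random_map(c(h, h, cc, 1)))
    v <- fwd(mod, lapply(splits, tensor))
    expect_lt(max(abs(v$v - oracle_split_attention(mod, splits))), 1e-6)
    if (r > 1) {
      w <- split_attention_weights(mod, splits)
      for (kk in seq_len(k))
        expect_lt(max(abs(colSums(w[[kk]]) - 1)), 1e-5)
    }
  }
})

test_that("SCM-Block keeps the residual contract and shapes", {
  set.seed(53)
  cfg <- block_config(2, 1, 16, 16, 16, stride = 1L)
  blk <- scm_block(cfg, "scm", "split", "dsc", "madm")
  x <- make_random_map(c(8, 8, 16, 1))
  # zero the closing 1x1: main branch contributes exactly nothing
  blk$mods$conv3$params$w$v[] <- 0
  y <- fwd(blk, tensor(x), training = FALSE)
  expect_equal(y$v, as_dim4_test(x), tolerance = 1e-12)
  # stride 2: residual equals the MADM shortcut output
  cfg2 <- block_config(2, 1, 16, 16, 32, stride = 2L)
  blk2 <- scm_block(cfg2, "scm", "split", "dsc", "madm")
  blk2$mods$conv3$params$w$v[] <- 0
  y2 <- fwd(blk2, tensor(x), training = FALSE)
  expect_identical(dim(y2$v), c(4L, 4L, 32L, 1L))
  tx <- fwd(blk2$mods$shortcut, tensor(x), training = FALSE)
  expect_equal(y2$v, tx$v, tolerance = 1e-12)
  # stride-1 shape preservation with live weights
  blk3 <- scm_block(block_config(2, 1, 16, 16, 16, 1L), "scm", "split",
                    "conv", "pool")
  expect_identical(dim(fwd(blk3, tensor(x), training = TRUE)$v), dim(as_dim4_test(x)))
})

test_that("networks build, classify, and count parameters; radix/cardinal
           trends hold", {
  set.seed(54)
  # 3x3 conv 16 -> 32 is 0.005 M; 2048 -> 1000 linear with bias is 2.049 M
  expect_equal(count_parameters(layer_conv2d(16, 32, 3)), 0.005)
  expect_equal(count_parameters(layer_linear(2048, 1000)), 2.049)
  # logits shape on the reduced preset
  m <- build_network(scheme_config("mc_scmnet_small", 4L))
  lg <- fwd(m, tensor(make_random_map(c(64, 64, 3, 2))), training = TRUE)
  expect_identical(dim(lg$v)[1:2], c(4L, 2L))
  # parameter count strictly increases with radix (cardinal 1) and with
  # cardinal (radix 2); reduced widths preserve the structural trend
  pr <- vapply(2:4, function(r) count_parameters(build_network(
    network_config("scm", "split_clam", "dsc", "madm", radix = r,
                   cardinal = 1, stage_depths = c(1, 1, 1, 1),
                   width_mult = 1 / 8))), 1)
  expect_true(all(diff(pr) > 0))
  pk <- vapply(1:3, function(k) count_parameters(build_network(
    network_config("scm", "split_clam", "dsc", "madm", radix = 2,
                   cardinal = k, stage_depths = c(1, 1, 1, 1),
                   width_mult = 1 / 8))), 1)
  expect_true(all(diff(pk) > 0))
  expect_error(network_config(stage_depths = c(1, 1, 1)), "invalid-config")
  expect_error(scheme_config(15L), "unknown scheme")
  expect_error(scheme_config("nonesuch"), "unknown scheme")
})

test_that("checkpoint save/load round-trips weights and predictions", {
  set.seed(55)
  m <- build_network(scheme_config("mc_scmnet_small", 4L))
  x <- make_random_map(c(64, 64, 3, 1))
  p1 <- softmax_probs(fwd(m, tensor(x), training = FALSE))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck, epoch = 3L, classes = letters[1:4])
  lo <- load_checkpoint(ck)
  expect_identical(lo$epoch, 3L)
  p2 <- softmax_probs(fwd(lo$model, tensor(x), training = FALSE))
  expect_equal(p1, p2, tolerance = 1e-12)
  unlink(ck)
})
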