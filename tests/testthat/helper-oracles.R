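# Independent brute-force oracles and small utilities shared by the tests.
# These deliberately avoid the package's vectorized/C++ code paths.

# central-difference numerical gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# double-loop oracle for the global per-channel mean (coordinate embedding)
oracle_coordinate_embed <- function(x) {
  d <- dim(x)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + x[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

# loop oracles for the directional poolings
oracle_pool_h <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], 1, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(d[1])) {
    s <- 0
    for (j in seq_len(d[2])) s <- s + x[i, j, c]
    out[i, 1, c] <- s / d[2]
  }
  out
}

oracle_pool_w <- function(x) {
  d <- dim(x)
  out <- array(0, c(1, d[2], d[3]))
  for (c in seq_len(d[3])) for (j in seq_len(d[2])) {
    s <- 0
    for (i in seq_len(d[1])) s <- s + x[i, j, c]
    out[1, j, c] <- s / d[1]
  }
  out
}

# loop oracle of the full Split-Attention computation, reusing the module's
# gate weights but re-implementing every step with explicit loops
oracle_split_attention <- function(mod, splits_v) {
  r <- mod$r; k <- mod$k; cc <- mod$c
  d <- dim(splits_v[[1]])
  outs <- vector("list", k)
  for (kk in seq_len(k)) {
    grp <- splits_v[((kk - 1) * r) + seq_len(r)]
    u <- array(0, d)
    for (i in seq_len(r)) u <- u + grp[[i]]
    s <- numeric(cc)
    for (c in seq_len(cc)) s[c] <- mean(u[, , c, 1])
    # G: fc1 (1x1 conv) -> BN (eval: running stats) -> ReLU -> fc2
    w1 <- mod$mods[[paste0("fc1_", kk)]]$params$w$v
    h <- numeric(dim(w1)[4])
    for (o in seq_len(dim(w1)[4])) h[o] <- sum(w1[1, 1, , o] * s)
    bn <- mod$mods[[paste0("bn_", kk)]]
    h <- (h - as.numeric(bn$run_mean)) / sqrt(as.numeric(bn$run_var) + bn$eps)
    h <- h * as.numeric(bn$params$gamma$v) + as.numeric(bn$params$beta$v)
    h <- pmax(h, 0)
    w2 <- mod$mods[[paste0("fc2_", kk)]]$params$w$v
    sc <- numeric(dim(w2)[4])
    for (o in seq_len(dim(w2)[4])) sc[o] <- sum(w2[1, 1, , o] * h)
    # channel-fastest layout: score of split i, channel c at (i-1)*cc + c
    a <- matrix(0, r, cc)
    for (c in seq_len(cc)) {
      z <- sc[(seq_len(r) - 1) * cc + c]
      if (r > 1) a[, c] <- exp(z - max(z)) / sum(exp(z - max(z)))
      else a[1, c] <- 1 / (1 + exp(-z))
    }
    v <- array(0, d)
    for (i in seq_len(r)) for (c in seq_len(cc))
      v[, , c, 1] <- v[, , c, 1] + a[i, c] * grp[[i]][, , c, 1]
    outs[[kk]] <- v
  }
  out <- array(0, c(d[1], d[2], cc * k, 1))
  for (kk in seq_len(k)) out[, , (kk - 1) * cc + seq_len(cc), 1] <-
    outs[[kk]][, , , 1]
  out
}

# one-way ANOVA oracle via explicit textbook sums of squares
oracle_anova <- function(groups) {
  v <- unlist(groups)
  grand <- mean(v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (x in g) ssw <- ssw + (x - mean(g))^2
  }
  dfb <- length(groups) - 1
  dfw <- length(v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

# strided max-pool oracle (kernel 3, stride 2, pad 1)
oracle_maxpool3s2 <- function(x) {
  d <- dim(x)
  oh <- (d[1] + 2 - 3) %/% 2 + 1; ow <- (d[2] + 2 - 3) %/% 2 + 1
  out <- array(-Inf, c(oh, ow, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      hs <- (i - 1) * 2 - 1 + 1:3; ws <- (j - 1) * 2 - 1 + 1:3
      hs <- hs[hs >= 1 & hs <= d[1]]; ws <- ws[ws >= 1 & ws <= d[2]]
      out[i, j, c, n] <- max(x[hs, ws, c, n])
    }
  out
}

# count conv weights of a module tree (convolution tensors only, by name)
conv_weight_count <- function(m) {
  ps <- collect_params(m)
  sum(vapply(ps[grepl("\\.w$|^w$", names(ps))], function(p) length(p$v), 1))
}

SYNTH_CLASSES_TEST <- c("diarrhea", "lack_of_water", "normal", "soft_stool")

as_dim4_test <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  array(as.double(x), c(d, rep(1L, 4L - length(d))))
}

# separable gaussian blur of a plain matrix (test-local texture smoothing)
gaussian_blur_mat <- function(m, sigma) {
  rad <- ceiling(3 * sigma)
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  pm <- m[c(rep(1, rad), 1:H, rep(H, rad)), ]
  acc <- matrix(0, H, W)
  for (j in seq_along(k)) acc <- acc + k[j] * pm[(j - 1) + 1:H, ]
  pm <- acc[, c(rep(1, rad), 1:W, rep(W, rad))]
  acc <- matrix(0, H, W)
  for (j in seq_along(k)) acc <- acc + k[j] * pm[, (j - 1) + 1:W]
  acc
}

make_random_map <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(d)), d)
}
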