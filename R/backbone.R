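# ---------------------------------------------------------------------------
# Split-Attention, the SCM-Block, and the four-stage backbone assembly.
#
# Split-Attention, for k cardinal groups of r splits each (every split
# carrying c channels):
#   U^k   = sum of the r splits of group k
#   s^k   = global average pool of U^k                  (c per sample)
#   G^k   = bottleneck c -> c/4 -> r*c with BN + ReLU between
#   a_i^k = softmax over the r splits when r > 1, sigmoid when r = 1
#   V^k   = sum_i a_i^k .* U_i ;  V = channel concat of the V^k
#
# Width convention: the bottleneck width of a block scales with cardinality
# (c_split = base width, total split channels = base * cardinal * radix),
# the convention under which parameter counts grow in both radix and
# cardinal.
# ---------------------------------------------------------------------------

t_slice_axis <- function(x, axis, i) {
  xd <- dim(x$v)
  idx <- lapply(seq_len(4), function(a) if (a == axis) i else seq_len(xd[a]))
  v <- do.call(`[`, c(list(x$v), idx, list(drop = FALSE)))
  node(v, list(x), function(g) {
    gx <- array(0, xd)
    gx <- do.call(`[<-`, c(list(gx), idx, list(value = g)))
    list(gx)
  })
}

#' Split-Attention module
#'
#' @param split_channels channels c carried by each split.
#' @param radix,cardinal the r and k hyperparameters; the module consumes
#'   exactly `radix * cardinal` splits, ordered group-major (all r splits of
#'   cardinal group 1 first).
#' @param reduction bottleneck reduction of the gating function G
#'   (default 4: c -> c/4 -> r*c).
#' @return a module; forward consumes a list of k*r tensors sharing one
#'   shape and returns the fused map with `cardinal * split_channels`
#'   channels.
#' @export
split_attention_module <- function(split_channels, radix, cardinal,
                                   reduction = 4L) {
  c <- as.integer(split_channels)
  r <- as.integer(radix); k <- as.integer(cardinal)
  hidden <- max(1L, c %/% as.integer(reduction))
  mods <- list()
  for (kk in seq_len(k)) {
    mods[[paste0("fc1_", kk)]] <- layer_conv2d(c, hidden, 1L)
    mods[[paste0("bn_", kk)]] <- layer_bn(hidden)
    mods[[paste0("fc2_", kk)]] <- layer_conv2d(hidden, r * c, 1L)
  }
  new_module("split_attention",
    function(self, splits, training) {
      if (!is.list(splits) || length(splits) != self$r * self$k)
        stop("invalid-input: expected ", self$r * self$k, " splits",
             call. = FALSE)
      outs <- vector("list", self$k)
      for (kk in seq_len(self$k)) {
        grp <- splits[((kk - 1) * self$r) + seq_len(self$r)]
        u <- grp[[1]]
        if (self$r > 1) for (i in 2:self$r) u <- t_add(u, grp[[i]])
        s <- t_mean(u, c(1, 2))                                  # (1,1,c,N)
        h <- t_relu(fwd(self$mods[[paste0("bn_", kk)]],
                        fwd(self$mods[[paste0("fc1_", kk)]], s, training),
                        training))
        sc <- fwd(self$mods[[paste0("fc2_", kk)]], h, training)  # (1,1,rc,N)
        n <- dim(sc$v)[4]
        if (self$r > 1) {
          a <- t_softmax(t_reshape(sc, c(self$c, self$r, 1, n)), 2L)
          v <- NULL
          for (i in seq_len(self$r)) {
            gate <- t_reshape(t_slice_axis(a, 2L, i), c(1, 1, self$c, n))
            term <- t_mul(grp[[i]], gate)
            v <- if (is.null(v)) term else t_add(v, term)
          }
        } else {
          v <- t_mul(grp[[1]], t_sigmoid(sc))
        }
        outs[[kk]] <- v
      }
      if (self$k == 1) outs[[1]] else t_concat(outs)
    },
    mods = mods, c = c, r = r, k = k, hidden = hidden)
}

#' Split-Attention attention weights
#'
#' Returns, for each cardinal group, the per-split per-channel weights
#' a_i^k(c) for one forward pass (list of k matrices, r x c, per sample n).
#'
#' @param mod a [split_attention_module()].
#' @param splits list of k*r numeric arrays (H, W, c) or (H, W, c, N).
#' @param n sample index.
#' @return list of k numeric r x c matrices.
#' @export
split_attention_weights <- function(mod, splits, n = 1L) {
  splits <- lapply(splits, function(s) tensor(as_dim4(s)))
  out <- vector("list", mod$k)
  for (kk in seq_len(mod$k)) {
    grp <- splits[((kk - 1) * mod$r) + seq_len(mod$r)]
    u <- grp[[1]]
    if (mod$r > 1) for (i in 2:mod$r) u <- t_add(u, grp[[i]])
    s <- t_mean(u, c(1, 2))
    h <- t_relu(fwd(mod$mods[[paste0("bn_", kk)]],
                    fwd(mod$mods[[paste0("fc1_", kk)]], s, FALSE), FALSE))
    sc <- fwd(mod$mods[[paste0("fc2_", kk)]], h, FALSE)
    scv <- array(sc$v[1, 1, , n], c(mod$c, mod$r))        # channel-fastest
    if (mod$r > 1) {
      e <- exp(sweep(scv, 1, apply(scv, 1, max)))
      a <- t(sweep(e, 1, rowSums(e), "/"))                # r x c
    } else {
      a <- matrix(1 / (1 + exp(-scv[, 1])), 1)
    }
    out[[kk]] <- a
  }
  out
}

#' Apply Split-Attention to a list of splits
#'
#' Functional form of [split_attention_module()]; builds a module with
#' freshly initialized gates unless one is supplied.
#'
#' @param splits list of k*r arrays/tensors sharing one shape.
#' @param radix,cardinal r and k.
#' @param mod optional pre-built module (for reproducible weights).
#' @return tensor V.
#' @export
split_attention <- function(splits, radix, cardinal, mod = NULL) {
  if (length(splits) != radix * cardinal)
    stop("invalid-input: split count must equal radix * cardinal",
         call. = FALSE)
  splits <- lapply(splits, function(s) if (is_tensor(s)) s
                   else tensor(as_dim4(s)))
  if (is.null(mod))
    mod <- split_attention_module(dim(splits[[1]]$v)[3], radix, cardinal)
  fwd(mod, splits)
}

# ---------------------------------------------------------------------------
# Coordinate attention (CA) — the published baseline mechanism, used by the
# ablation grid's "Split-Attention + CA" rows.
# ---------------------------------------------------------------------------

ca_module <- function(channels, reduction = 32L) {
  mid <- max(8L, channels %/% as.integer(reduction))
  new_module("ca",
    function(self, x, training) {
      zh <- t_mean(x, 2)                                   # (h,1,C,N)
      zw <- t_mean(x, 1)                                   # (1,w,C,N)
      fh <- t_relu(fwd(self$mods$bn1, fwd(self$mods$conv1, zh, training),
                       training))
      fw <- t_relu(fwd(self$mods$bn1, fwd(self$mods$conv1, zw, training),
                       training))
      gh <- t_sigmoid(fwd(self$mods$convh, fh, training))  # (h,1,C,N)
      gw <- t_sigmoid(fwd(self$mods$convw, fw, training))  # (1,w,C,N)
      t_mul(t_mul(x, gh), gw)
    },
    mods = list(conv1 = layer_conv2d(channels, mid, 1L),
                bn1 = layer_bn(mid),
                convh = layer_conv2d(mid, channels, 1L),
                convw = layer_conv2d(mid, channels, 1L)),
    channels = channels)
}

# ---------------------------------------------------------------------------
# Blocks
# ---------------------------------------------------------------------------

#' Block configuration for split-attention residual blocks
#'
#' @param radix,cardinal split-attention hyperparameters r and k.
#' @param in_channels,bottleneck_channels,out_channels channel plan; the
#'   bottleneck must divide into k*r splits.
#' @param stride 1 or 2.
#' @return object of class `block_config`.
#' @export
block_config <- function(radix, cardinal, in_channels, bottleneck_channels,
                         out_channels, stride = 1L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  if (bottleneck_channels %% (radix * cardinal) != 0)
    stop("bottleneck_channels must be divisible by radix * cardinal",
         call. = FALSE)
  structure(list(radix = as.integer(radix), cardinal = as.integer(cardinal),
                 in_channels = as.integer(in_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride)),
            class = "block_config")
}

# grouped 3x3 fusion over the split tensor (k*r groups), plain or DSC
split_fusion_conv <- function(channels, groups, conv, stride) {
  if (conv == "dsc") {
    m <- layer_seq(list(
      dw = layer_conv2d(channels, channels, 3L, stride = stride,
                        groups = channels),
      pw = layer_conv2d(channels, channels, 1L, groups = groups)))
    names(m$mods) <- c("dw", "pw")
    m$type <- "dsc_grouped"
    m
  } else {
    layer_conv2d(channels, channels, 3L, stride = stride, groups = groups)
  }
}

#' Residual block families
#'
#' `scm_block` builds one block of the backbone. `block` selects the family:
#' `"res"` (canonical bottleneck), `"resnest"` (split-attention bottleneck),
#' or `"scm"` (split-attention bottleneck whose stride-2 fusion and residual
#' branch use the module down-sampler, Eq-8 style). `attention` adds CA or
#' CLAM at the main-branch entry on top of split attention. SCM blocks end
#' with the bare residual sum T(X) + V (no trailing activation), so zeroing
#' the closing 1x1 convolution recovers T(X) exactly.
#'
#' @param cfg a [block_config()].
#' @param block,attention,conv,downsample ablation toggles.
#' @return a module.
#' @export
scm_block <- function(cfg, block = c("scm", "resnest", "res"),
                      attention = c("split", "none", "split_ca",
                                    "split_clam"),
                      conv = c("conv", "dsc"),
                      downsample = c("pool", "madm"),
                      pre_attention = TRUE,
                      clam_gate = c("softmax", "sigmoid")) {
  block <- match.arg(block); attention <- match.arg(attention)
  conv <- match.arg(conv); downsample <- match.arg(downsample)
  clam_gate <- match.arg(clam_gate)
  cin <- cfg$in_channels; cout <- cfg$out_channels
  b <- cfg$bottleneck_channels
  r <- cfg$radix; k <- cfg$cardinal; stride <- cfg$stride
  mods <- list()

  if (pre_attention && attention == "split_clam" && block != "res")
    mods$pre_att <- clam_module(cin, gate = clam_gate)
  if (pre_attention && attention == "split_ca" && block != "res")
    mods$pre_att <- ca_module(cin)

  use_split <- block != "res" && attention != "none"
  if (block == "res" || !use_split) {
    # canonical bottleneck (attention "none")
    mods$conv1 <- layer_conv2d(cin, b, 1L)
    mods$bn1 <- layer_bn(b)
    mods$conv2 <- if (conv == "dsc") dsc_plain(b, b, 3L, stride = stride)
                  else layer_conv2d(b, b, 3L, stride = stride)
    mods$bn2 <- layer_bn(b)
    mods$conv3 <- layer_conv2d(b, cout, 1L)
    mods$bn3 <- layer_bn(cout)
  } else {
    cs <- b %/% (k * r)            # channels per split
    mods$conv1 <- layer_conv2d(cin, b, 1L)
    mods$bn1 <- layer_bn(b)
    use_madm_fuse <- block == "scm" && stride == 2L && downsample == "madm"
    if (use_madm_fuse) {
      for (i in seq_len(k * r))
        mods[[paste0("fuse_madm_", i)]] <- madm_module(cs, cs)
    } else {
      mods$fuse <- split_fusion_conv(b, k * r, conv, stride)
    }
    mods$bn2 <- layer_bn(b)
    mods$satt <- split_attention_module(cs, r, k)
    mods$conv3 <- layer_conv2d(b %/% r, cout, 1L)
    mods$bn3 <- layer_bn(cout)
  }

  # residual branch T(X): identity, or module down-sampler per Eq 8, or a
  # 1x1 projection when only the channel count changes
  need_proj <- stride == 2L || cin != cout
  if (need_proj) {
    if (block == "scm" && stride == 2L && downsample == "madm") {
      mods$shortcut <- madm_module(cin, cout)
    } else {
      mods$shortcut <- layer_seq(list(
        conv = layer_conv2d(cin, cout, 1L, stride = stride, pad = 0L),
        bn = layer_bn(cout)))
      names(mods$shortcut$mods) <- c("conv", "bn")
    }
  }

  new_module("block",
    function(self, x, training) {
      tx <- if (is.null(self$mods$shortcut)) x
            else fwd(self$mods$shortcut, x, training)
      h <- x
      if (!is.null(self$mods$pre_att)) h <- fwd(self$mods$pre_att, h, training)
      if (self$use_split) {
        h <- t_relu(fwd(self$mods$bn1, fwd(self$mods$conv1, h, training),
                        training))
        if (!is.null(self$mods$fuse)) {
          h <- fwd(self$mods$fuse, h, training)
        } else {
          parts <- lapply(seq_len(self$k * self$r), function(i)
            fwd(self$mods[[paste0("fuse_madm_", i)]],
                t_slice_c(h, (i - 1L) * self$cs + seq_len(self$cs)), training))
          h <- t_concat(parts)
        }
        h <- t_relu(fwd(self$mods$bn2, h, training))
        splits <- lapply(seq_len(self$k * self$r), function(i)
          t_slice_c(h, (i - 1L) * self$cs + seq_len(self$cs)))
        v <- fwd(self$mods$satt, splits, training)
        v <- fwd(self$mods$bn3, fwd(self$mods$conv3, v, training), training)
      } else {
        h <- t_relu(fwd(self$mods$bn1, fwd(self$mods$conv1, h, training),
                        training))
        h <- t_relu(fwd(self$mods$bn2, fwd(self$mods$conv2, h, training),
                        training))
        v <- fwd(self$mods$bn3, fwd(self$mods$conv3, h, training), training)
      }
      if (!identical(dim(tx$v), dim(v$v)))
        stop("internal contract violation: residual shapes diverged")
      y <- t_add(tx, v)
      if (self$block_kind == "scm") y else t_relu(y)
    },
    mods = mods, cfg = cfg, block_kind = block, use_split = use_split,
    cs = if (use_split) b %/% (k * r) else b, r = r, k = k)
}

# ---------------------------------------------------------------------------
# Network assembly
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' Describes one point of the ablation grid. The four stages use output
#' widths 256/512/1024/2048 (bottleneck base 64/128/256/512) scaled by
#' `width_mult`; stage depths default to the 50-layer convention [3,4,6,3].
#'
#' @param block `"res"`, `"resnest"` or `"scm"`.
#' @param attention `"none"`, `"split"`, `"split_ca"` or `"split_clam"`.
#' @param conv `"conv"` or `"dsc"`.
#' @param downsample `"pool"` or `"madm"`.
#' @param radix,cardinal split-attention hyperparameters (defaults 2 and 1,
#'   the best-performing combination).
#' @param stage_depths four positive integers.
#' @param num_classes classifier width.
#' @param stem_channels stem width (default 64 scaled by `width_mult`).
#' @param width_mult width multiplier for desk-scale variants.
#' @return object of class `network_config`.
#' @export
network_config <- function(block = "scm", attention = "split_clam",
                           conv = "dsc", downsample = "madm",
                           radix = 2L, cardinal = 1L,
                           stage_depths = c(3L, 4L, 6L, 3L),
                           num_classes = 4L, stem_channels = NULL,
                           width_mult = 1,
                           clam_gate = c("softmax", "sigmoid")) {
  clam_gate <- match.arg(clam_gate)
  if (length(stage_depths) != 4L || any(stage_depths < 1))
    stop("invalid-config: stage_depths must be 4 positive integers",
         call. = FALSE)
  widths <- as.integer(round(c(256, 512, 1024, 2048) * width_mult))
  bneck <- as.integer(round(c(64, 128, 256, 512) * width_mult))
  kr <- radix * cardinal
  bneck <- pmax(as.integer(kr), as.integer(kr * round(bneck / kr)))
  if (is.null(stem_channels)) stem_channels <- max(8L, as.integer(64 * width_mult))
  structure(list(block = block, attention = attention, conv = conv,
                 downsample = downsample, radix = as.integer(radix),
                 cardinal = as.integer(cardinal),
                 stage_depths = as.integer(stage_depths),
                 widths = widths, bottlenecks = bneck,
                 num_classes = as.integer(num_classes),
                 stem_channels = as.integer(stem_channels),
                 width_mult = width_mult, clam_gate = clam_gate),
            class = "network_config")
}

#' Ablation-scheme presets
#'
#' Returns the [network_config()] for one of the 14 ablation schemes
#' (1 = plain 50-layer residual baseline, 8 = SCMNet, 14 = MC-SCMNet), or a
#' named preset: `"resnet_ref"`, `"scmnet"`, `"mc_scmnet"`,
#' `"mc_scmnet_small"` (width 1/16 for desk-scale training).
#'
#' @param scheme integer 1..14 or preset name.
#' @param num_classes classifier width (the reference parameter tables use
#'   1000).
#' @return a `network_config`.
#' @export
scheme_config <- function(scheme, num_classes = 4L) {
  if (is.character(scheme)) {
    return(switch(scheme,
      resnet_ref = scheme_config(1L, num_classes),
      scmnet = scheme_config(8L, num_classes),
      mc_scmnet = scheme_config(14L, num_classes),
      # desk-scale variant: width 1/16, single block per stage, sigmoid
      # CLAM gate (the rescaled channel softmax destabilizes very thin
      # networks; see the methods vignette)
      mc_scmnet_small = network_config("scm", "split_clam", "dsc", "madm",
                                       stage_depths = c(1L, 1L, 1L, 1L),
                                       num_classes = num_classes,
                                       width_mult = 1 / 16,
                                       clam_gate = "sigmoid"),
      stop("unknown scheme '", scheme, "'; available: resnet_ref, scmnet, ",
           "mc_scmnet, mc_scmnet_small or 1..14", call. = FALSE)))
  }
  scheme <- as.integer(scheme)
  if (is.na(scheme) || scheme < 1L || scheme > 14L)
    stop("unknown scheme; valid ids are 1..14", call. = FALSE)
  grid <- list(
    list("res",     "none",       "conv", "pool"),   # 1
    list("resnest", "split",      "conv", "pool"),   # 2
    list("resnest", "split_ca",   "conv", "pool"),   # 3
    list("resnest", "split_clam", "conv", "pool"),   # 4
    list("resnest", "split",      "dsc",  "pool"),   # 5
    list("resnest", "split_ca",   "dsc",  "pool"),   # 6
    list("resnest", "split_clam", "dsc",  "pool"),   # 7
    list("scm",     "split",      "conv", "pool"),   # 8
    list("scm",     "split",      "conv", "madm"),   # 9
    list("scm",     "split_ca",   "conv", "madm"),   # 10
    list("scm",     "split_clam", "conv", "madm"),   # 11
    list("scm",     "split",      "dsc",  "madm"),   # 12
    list("scm",     "split_ca",   "dsc",  "madm"),   # 13
    list("scm",     "split_clam", "dsc",  "madm"))   # 14
  g <- grid[[scheme]]
  network_config(block = g[[1]], attention = g[[2]], conv = g[[3]],
                 downsample = g[[4]], num_classes = num_classes)
}

#' Build a classification network
#'
#' Assembles stem, four stages of residual blocks (first block of stages
#' 2-4 at stride 2), global average pooling and a linear classifier. With
#' `downsample = "madm"` the stem is the enriched extraction stage (3x3
#' convolution, optional CLAM, two MADM units, /4 resolution); otherwise
#' the conventional 7x7 stride-2 convolution + max pool.
#'
#' @param cfg a [network_config()] (or a scheme id / preset name).
#' @param num_classes used when `cfg` is a scheme id.
#' @return a model module; forward maps (H, W, 3, N) to logits
#'   (num_classes, N).
#' @export
build_network <- function(cfg, num_classes = 4L) {
  if (!inherits(cfg, "network_config")) cfg <- scheme_config(cfg, num_classes)
  sc <- cfg$stem_channels
  mods <- list()
  if (cfg$downsample == "madm") {
    stem_mods <- list(conv = layer_conv2d(3L, sc, 3L),
                      bn = layer_bn(sc), relu = act_relu())
    if (cfg$attention == "split_clam")
      stem_mods$clam <- clam_module(sc, gate = cfg$clam_gate)
    stem_mods$madm1 <- madm_module(sc, sc)
    stem_mods$madm2 <- madm_module(sc, sc)
    stem <- layer_seq(stem_mods)
    names(stem$mods) <- names(stem_mods)
  } else {
    stem <- layer_seq(list(conv = layer_conv2d(3L, sc, 7L, stride = 2L),
                           bn = layer_bn(sc), relu = act_relu(),
                           pool = layer_maxpool(3L, 2L, 1L)))
    names(stem$mods) <- c("conv", "bn", "relu", "pool")
  }
  mods$stem <- stem
  cin <- sc
  canonical <- cfg$block == "res" || cfg$attention == "none"
  for (st in 1:4) {
    blocks <- list()
    for (bi in seq_len(cfg$stage_depths[st])) {
      stride <- if (st > 1 && bi == 1) 2L else 1L
      bcfg <- if (canonical)
        block_config(1L, 1L, cin, cfg$bottlenecks[st], cfg$widths[st], stride)
      else
        block_config(cfg$radix, cfg$cardinal, cin,
                     cfg$bottlenecks[st] * cfg$cardinal * cfg$radix,
                     cfg$widths[st], stride)
      # CA/CLAM sit in the stride-2 (stage-transition) blocks, where the
      # main branch fuses down-sampled features; see the methods vignette
      blocks[[paste0("b", bi)]] <- scm_block(bcfg, cfg$block, cfg$attention,
                                             cfg$conv, cfg$downsample,
                                             pre_attention = stride == 2L,
                                             clam_gate = cfg$clam_gate)
      cin <- cfg$widths[st]
    }
    stage <- layer_seq(blocks)
    names(stage$mods) <- names(blocks)
    stage$type <- "stage"
    mods[[paste0("stage", st)]] <- stage
  }
  mods$fc <- layer_linear(cfg$widths[4], cfg$num_classes, bias = TRUE)

  new_module("network",
    function(self, x, training) {
      acts <- if (isTRUE(self$record)) list() else NULL
      h <- fwd(self$mods$stem, x, training)
      if (!is.null(acts)) acts$stem <- h
      for (st in 1:4) {
        h <- fwd(self$mods[[paste0("stage", st)]], h, training)
        if (!is.null(acts)) acts[[paste0("stage", st)]] <- h
      }
      pooled <- t_reshape(t_mean(h, c(1, 2)),
                          c(dim(h$v)[3], dim(h$v)[4]))
      logits <- fwd(self$mods$fc, pooled, training)
      if (!is.null(acts)) self$acts <- acts
      logits
    },
    mods = mods, cfg = cfg, record = FALSE)
}

# bottleneck width note: for split blocks block_config receives
# bottleneck = base * cardinal * radix (total split tensor channels); each
# split then carries base channels, and conv3 maps base*cardinal -> out.
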