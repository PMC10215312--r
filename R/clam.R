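# ---------------------------------------------------------------------------
# Coordinate location attention (CLAM) and its LAM core.
#
# The input map (h x w x C) is conceptually duplicated three times:
#  - branch A: row means (direction-aware encoding along height), transposed
#    to a 1 x h x C signal, passed through LAM;
#  - branch B: column means (1 x w x C), passed through LAM;
#  - branch C: the input itself with the global per-channel descriptor
#    broadcast-added (this is where the coordinate embedding is consumed).
# LAM(F) = FC(P(F)) .* DSC3x3(P(F)) with P a width-2 stride-1 average pool.
# The branches are fused by elementwise product (broadcast to h x w x C),
# normalized by softmax along the channel axis, rescaled by C so the mean
# gate is ~1, and applied multiplicatively to the input.
# ---------------------------------------------------------------------------

as_hwc <- function(x) {
  if (is.null(dim(x))) stop("invalid-input: expected an array", call. = FALSE)
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 3L)
    stop("invalid-input: expected an h x w x C feature map", call. = FALSE)
  if (d[1] < 1 || d[2] < 1)
    stop("invalid-input: empty spatial extent", call. = FALSE)
  x
}

#' Coordinate embedding and directional pooling
#'
#' `coordinate_embed` returns the global spatial mean of each channel (a
#' length-C vector). `directional_pool_h` averages along the width, giving
#' an h x 1 x C encoding; `directional_pool_w` averages along the height,
#' giving 1 x w x C. `transpose_h_encoding` swaps the spatial axes of the
#' height encoding so both directional encodings share a 1 x L x C layout.
#'
#' @param x an h x w x C feature map (a matrix is treated as h x w x 1).
#' @return see above.
#' @export
coordinate_embed <- function(x) {
  x <- as_hwc(x)
  apply(x, 3, mean)
}

#' @rdname coordinate_embed
#' @export
directional_pool_h <- function(x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(apply(x, c(1, 3), mean), c(d[1], 1L, d[3]))
}

#' @rdname coordinate_embed
#' @export
directional_pool_w <- function(x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(apply(x, c(2, 3), mean), c(1L, d[2], d[3]))
}

#' @rdname coordinate_embed
#' @param z_h an h x 1 x C encoding from `directional_pool_h`.
#' @export
transpose_h_encoding <- function(z_h) {
  d <- dim(z_h)
  if (length(d) != 3L || d[2] != 1L)
    stop("invalid-input: expected an h x 1 x C encoding", call. = FALSE)
  aperm(z_h, c(2, 1, 3))
}

#' Location attention mechanism (LAM)
#'
#' The core unit of CLAM. Its input is a one-dimensional directional
#' encoding (1 x L x C). The encoding is average-pooled (window 2, stride 1,
#' edge-replicated — a global pool would destroy the positional structure),
#' then two branches are taken: a per-position fully-connected channel
#' transform (the same weights broadcast along the spatial axis), and a
#' 3 x 3 depthwise separable convolution. Their elementwise product is the
#' attention signal, in the same layout as the input.
#'
#' @param channels number of channels C of the encoding.
#' @param pool `"w2"` (default) or `"none"` (identity pooling, used by
#'   degenerate-weight tests).
#' @return a module; forward consumes a (1, L, C, N) tensor.
#' @export
lam_module <- function(channels, pool = c("w2", "none")) {
  pool <- match.arg(pool)
  fc <- layer_conv2d(channels, channels, 1L)     # Pa: positionwise FC
  ds <- dsc_plain(channels, channels, 3L)        # C1: 3x3 DSC, kernel fixed
  new_module("lam",
    function(self, x, training) {
      if (dim(x$v)[3] != self$channels)
        stop("invalid-input: channel mismatch between LAM config and input",
             call. = FALSE)
      p <- if (self$pool == "w2") t_pool1d_w2(x) else x
      t_mul(fwd(self$mods$fc, p, training), fwd(self$mods$ds, p, training))
    },
    mods = list(fc = fc, ds = ds), channels = channels, pool = pool)
}

#' Coordinate location attention module (CLAM)
#'
#' @param channels channel count C of the maps this module gates.
#' @param gate `"softmax"` (channel softmax rescaled by C, default) or
#'   `"sigmoid"`.
#' @return a module; forward preserves tensor shape.
#' @export
clam_module <- function(channels, gate = c("softmax", "sigmoid")) {
  gate <- match.arg(gate)
  new_module("clam",
    function(self, x, training) {
      t_mul(x, clam_gate(self, x, training))
    },
    mods = list(lam_a = lam_module(channels), lam_b = lam_module(channels)),
    channels = channels, gate = gate)
}

# the multiplicative gate F_C (already rescaled when gate = "softmax")
clam_gate <- function(self, x, training) {
  d <- dim(x$v)
  if (d[3] != self$channels)
    stop("invalid-input: channel mismatch", call. = FALSE)
  zc <- t_mean(x, c(1, 2))                                  # (1,1,C,N)
  zh <- t_aperm(t_mean(x, 2), c(2, 1, 3, 4))                # (1,h,C,N)
  zw <- t_mean(x, 1)                                        # (1,w,C,N)
  aa <- t_aperm(fwd(self$mods$lam_a, zh, training), c(2, 1, 3, 4)) # (h,1,C,N)
  ab <- fwd(self$mods$lam_b, zw, training)                  # (1,w,C,N)
  ac <- t_add(x, zc)                                        # (h,w,C,N)
  s <- t_mul(t_mul(aa, ab), ac)
  if (self$gate == "softmax") {
    t_scale(t_softmax(s, 3L), self$channels)
  } else {
    t_sigmoid(s)
  }
}

#' CLAM attention weights
#'
#' Returns the normalized attention tensor (before the C rescaling when
#' `gate = "softmax"`): entries lie in (0,1) and sum to 1 along the channel
#' axis at every spatial position and sample.
#'
#' @param mod a [clam_module()].
#' @param x input array or tensor (h, w, C) or (h, w, C, N).
#' @return numeric array of attention weights.
#' @export
clam_attention <- function(mod, x) {
  xt <- if (is_tensor(x)) x else tensor(as_dim4(x))
  g <- clam_gate(mod, xt, training = FALSE)
  if (mod$gate == "softmax") g$v / mod$channels else g$v
}

#' Apply CLAM to a feature map
#'
#' @param mod a [clam_module()].
#' @param x array or tensor, shape (h, w, C) or (h, w, C, N).
#' @param training training mode flag.
#' @return tensor of the same shape as the input.
#' @export
clam_forward <- function(mod, x, training = FALSE) {
  xt <- if (is_tensor(x)) x else tensor(as_dim4(x))
  fwd(mod, xt, training)
}
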