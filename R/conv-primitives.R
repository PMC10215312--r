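# ---------------------------------------------------------------------------
# Depthwise separable convolution (DSC) and its closed-form accounting.
#
# For input S x S x C, kernel K x K and N output channels (stride 1,
# bias-free):
#   standard conv:  W_SC  = K*K*C*N          O_SC  = S*S*K*K*C*N
#   DSC:            W_DSC = K*K*C + C*N      O_DSC = S*S*K*K*C + S*S*C*N
#   ratios:         F_W = F_O = 1/N + 1/K^2
# ---------------------------------------------------------------------------

#' Convolution shape specification
#'
#' Describes a square convolution for parameter and computation accounting.
#' Accounting is always bias-free: every convolution in this package is
#' followed by batch normalization, so instantiated layers and the closed
#' forms agree exactly.
#'
#' @param in_channels,out_channels positive integers C and N.
#' @param kernel positive integer K (square kernels only).
#' @param stride positive integer.
#' @param spatial_size positive integer S (input height = width), used only
#'   by the FLOP formulas.
#' @param include_bias must be FALSE; retained to make the convention
#'   explicit.
#' @return an object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel, stride = 1L,
                      spatial_size = 1L, include_bias = FALSE) {
  for (v in list(in_channels, out_channels, kernel, stride, spatial_size)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop("invalid conv_spec: dimensions must be positive integers",
           call. = FALSE)
  }
  if (isTRUE(include_bias))
    stop("invalid conv_spec: accounting is defined bias-free", call. = FALSE)
  structure(list(C = as.integer(in_channels), N = as.integer(out_channels),
                 K = as.integer(kernel), stride = as.integer(stride),
                 S = as.integer(spatial_size)),
            class = "conv_spec")
}

check_spec <- function(spec) {
  if (!inherits(spec, "conv_spec")) stop("expected a conv_spec", call. = FALSE)
  spec
}

#' Closed-form convolution accounting
#'
#' `count_standard` and `count_dsc` give the trainable weight counts of a
#' standard and a depthwise separable convolution; `flops_standard` and
#' `flops_dsc` the multiply counts over an S x S input; `dsc_ratios` the
#' DSC/standard ratios, which both equal 1/N + 1/K^2. The FLOP forms are
#' evaluated as stated, with S the input size regardless of stride.
#'
#' @param spec a [conv_spec()].
#' @return integer count, or for `dsc_ratios` a list with `F_W` and `F_O`.
#' @export
count_standard <- function(spec) {
  spec <- check_spec(spec)
  spec$K * spec$K * spec$C * spec$N
}

#' @rdname count_standard
#' @export
count_dsc <- function(spec) {
  spec <- check_spec(spec)
  spec$K * spec$K * spec$C + spec$C * spec$N
}

#' @rdname count_standard
#' @export
flops_standard <- function(spec) {
  spec <- check_spec(spec)
  # double arithmetic: products exceed 32-bit range at realistic sizes
  prod(as.numeric(c(spec$S, spec$S, spec$K, spec$K, spec$C, spec$N)))
}

#' @rdname count_standard
#' @export
flops_dsc <- function(spec) {
  spec <- check_spec(spec)
  s2 <- as.numeric(spec$S)^2
  s2 * spec$K * spec$K * spec$C + s2 * spec$C * spec$N
}

#' @rdname count_standard
#' @export
dsc_ratios <- function(spec) {
  spec <- check_spec(spec)
  closed <- 1 / spec$N + 1 / spec$K^2
  fw <- count_dsc(spec) / count_standard(spec)
  fo <- flops_dsc(spec) / flops_standard(spec)
  if (abs(fw - closed) > 1e-12 || abs(fo - closed) > 1e-12)
    stop("internal accounting inconsistency")           # cannot happen
  list(F_W = fw, F_O = fo)
}

#' Build a depthwise separable convolution layer
#'
#' Per-channel K x K spatial convolution (groups = C) followed by a 1 x 1
#' pointwise channel-mixing convolution; bias-free, so the trainable weight
#' count equals [count_dsc()]. Batch norm + ReLU are applied after the
#' pointwise stage by default (`bn_after = "pointwise"`), or after both
#' stages (`bn_after = "both"`).
#'
#' @param spec a [conv_spec()] (stride taken from it).
#' @param bn_after `"none"`, `"pointwise"` (default) or `"both"`.
#' @return a module whose output spatial size is `floor((S + 2*(K%/%2) - K)
#'   / stride) + 1`.
#' @export
build_dsc_layer <- function(spec, bn_after = c("pointwise", "both", "none")) {
  spec <- check_spec(spec)
  bn_after <- match.arg(bn_after)
  dw <- layer_conv2d(spec$C, spec$C, spec$K, stride = spec$stride,
                     groups = spec$C)
  pw <- layer_conv2d(spec$C, spec$N, 1L)
  mods <- list(dw = dw)
  if (bn_after == "both") {
    mods$dwbn <- layer_bn(spec$C)
    mods$dwrelu <- act_relu()
  }
  mods$pw <- pw
  if (bn_after %in% c("pointwise", "both")) {
    mods$pwbn <- layer_bn(spec$N)
    mods$pwrelu <- act_relu()
  }
  m <- layer_seq(mods)
  names(m$mods) <- names(mods)
  m$type <- "dsc"
  m$spec <- spec
  m
}

# bare DSC (no BN/ReLU), used inside attention blocks where normalization
# placement is owned by the caller
dsc_plain <- function(cin, cout, k, stride = 1L) {
  m <- layer_seq(list(dw = layer_conv2d(cin, cin, k, stride = stride,
                                        groups = cin),
                      pw = layer_conv2d(cin, cout, 1L)))
  names(m$mods) <- c("dw", "pw")
  m$type <- "dsc_plain"
  m
}

#' Squeeze-and-excitation channel attention unit
#'
#' Global average pool, bottleneck to `max(1, round(channels/reduction))`
#' features, expansion back, sigmoid gate in (0,1), multiplied channel-wise
#' into the input. Output shape always equals input shape.
#'
#' @param channels positive integer.
#' @param reduction bottleneck reduction ratio (default 16, standard SE
#'   practice).
#' @return a module.
#' @export
build_se_unit <- function(channels, reduction = 16L) {
  if (!is.numeric(channels) || channels < 1 || channels != round(channels))
    stop("invalid-spec: channels must be a positive integer", call. = FALSE)
  hidden <- max(1L, as.integer(round(channels / reduction)))
  fc1 <- layer_linear(channels, hidden, bias = TRUE)
  fc2 <- layer_linear(hidden, channels, bias = TRUE)
  new_module("se",
    function(self, x, training) {
      d <- dim(x$v)
      z <- t_reshape(t_mean(x, c(1, 2)), c(d[3], d[4]))      # (C, N)
      g <- t_sigmoid(fwd(self$mods$fc2,
                         t_relu(fwd(self$mods$fc1, z, training)), training))
      gate <- t_reshape(g, c(1, 1, d[3], d[4]))
      t_mul(x, gate)
    },
    mods = list(fc1 = fc1, fc2 = fc2), channels = channels,
    reduction = reduction, hidden = hidden)
}

se_param_count <- function(channels, reduction = 16L) {
  hidden <- max(1L, as.integer(round(channels / reduction)))
  channels * hidden + hidden + hidden * channels + channels
}
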