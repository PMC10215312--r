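# ---------------------------------------------------------------------------
# Multi-scale attention down-sampling (MADM).
#
# Three parallel stride-2 branches — 3x3 max pooling, 5x5 DSC, 7x7 DSC —
# are concatenated on the channel axis, projected to the output width by a
# bias-free 1x1 convolution, and gated by an SE unit. The two convolutional
# branches are trainable and compensate for the static nature of pooling;
# the pooling branch retains the strongest local responses. MADM carries no
# internal batch normalization: accounting is exactly the sum of its DSC,
# projection and SE weights, and normalization is owned by the surrounding
# block.
# ---------------------------------------------------------------------------

#' MADM configuration
#'
#' @param in_channels,out_channels positive integers.
#' @param se_reduction SE bottleneck reduction (default 16).
#' @return object of class `madm_config`. The branch set is fixed to
#'   \{max-pool, DSC-5, DSC-7\} and the stride to 2.
#' @export
madm_config <- function(in_channels, out_channels, se_reduction = 16L) {
  if (!is.numeric(out_channels) || out_channels < 1)
    stop("invalid-config: out_channels must be >= 1", call. = FALSE)
  if (!is.numeric(in_channels) || in_channels < 1)
    stop("invalid-config: in_channels must be >= 1", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 branch_kernels = c("pool", "5", "7"),
                 stride = 2L,
                 se_reduction = as.integer(se_reduction)),
            class = "madm_config")
}

#' Build a MADM down-sampling module
#'
#' @param cfg a [madm_config()] (or in_channels, when `out_channels` given).
#' @param out_channels,se_reduction convenience scalar interface.
#' @return a module halving spatial size: (h, w, C_in, N) ->
#'   (ceil(h/2), ceil(w/2), C_out, N).
#' @export
madm_module <- function(cfg, out_channels = NULL, se_reduction = 16L) {
  if (!inherits(cfg, "madm_config"))
    cfg <- madm_config(cfg, out_channels, se_reduction)
  cin <- cfg$in_channels; cout <- cfg$out_channels
  new_module("madm",
    function(self, x, training) {
      if (dim(x$v)[1] < 2 || dim(x$v)[2] < 2)
        stop("invalid-input: spatial extent must be >= 2", call. = FALSE)
      b_pool <- t_maxpool(x, 3L, 2L, 1L)
      b5 <- fwd(self$mods$dsc5, x, training)
      b7 <- fwd(self$mods$dsc7, x, training)
      y <- fwd(self$mods$proj, t_concat(list(b_pool, b5, b7)), training)
      fwd(self$mods$se, y, training)
    },
    mods = list(dsc5 = dsc_plain(cin, cout, 5L, stride = 2L),
                dsc7 = dsc_plain(cin, cout, 7L, stride = 2L),
                proj = layer_conv2d(cin + 2L * cout, cout, 1L),
                se = build_se_unit(cout, cfg$se_reduction)),
    cfg = cfg)
}

#' Closed-form MADM parameter count
#'
#' Sum of the two DSC branch counts (K^2*C + C*N each), the 1x1 projection
#' ((C + 2N) * N) and the SE unit; max pooling contributes nothing.
#'
#' @param cfg a [madm_config()].
#' @return integer.
#' @export
madm_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "madm_config"))
  cin <- cfg$in_channels; cout <- cfg$out_channels
  dsc5 <- 5L * 5L * cin + cin * cout
  dsc7 <- 7L * 7L * cin + cin * cout
  proj <- (cin + 2L * cout) * cout
  dsc5 + dsc7 + proj + se_param_count(cout, cfg$se_reduction)
}
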