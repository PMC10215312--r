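#' @useDynLib scmnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Tape-based reverse-mode autograd over plain R arrays.
#
# Every tensor is an environment of class "scm_tensor" holding:
#   v       the value, always a 4-D array (H, W, C, N); vectors/matrices are
#           padded with trailing unit dims on entry
#   grad    accumulated gradient (same shape), NULL until backward touches it
#   parents list of parent tensors
#   bw      function(g) -> list of gradients, one per parent (or NULL)
#   id      creation order, used for reverse-topological traversal
#   requires_grad
# ---------------------------------------------------------------------------

.scm <- new.env(parent = emptyenv())
.scm$id <- 0L

as_dim4 <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  d <- if (is.null(dim(x))) length(x) else dim(x)
  array(as.double(x), c(d, rep(1L, 4L - length(d))))
}

#' Create a tensor node
#'
#' Wraps a numeric array (up to 4 dimensions, stored internally as
#' height x width x channel x batch) as a node on the autograd tape.
#'
#' @param x numeric vector/matrix/array.
#' @param requires_grad should gradients be accumulated into this node?
#' @return an object of class `scm_tensor`.
#' @export
tensor <- function(x, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- as_dim4(x)
  e$grad <- NULL
  e$parents <- list()
  e$bw <- NULL
  .scm$id <- .scm$id + 1L
  e$id <- .scm$id
  e$requires_grad <- requires_grad
  class(e) <- "scm_tensor"
  e
}

is_tensor <- function(x) inherits(x, "scm_tensor")

#' @export
print.scm_tensor <- function(x, ...) {
  cat("<scm_tensor ", paste(dim(x$v), collapse = "x"),
      if (x$requires_grad) " grad" else "", ">\n", sep = "")
  invisible(x)
}

tval <- function(x) x$v

node <- function(v, parents, bw) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  .scm$id <- .scm$id + 1L
  e$id <- .scm$id
  e$requires_grad <- any(vapply(parents, function(p) p$requires_grad, TRUE))
  class(e) <- "scm_tensor"
  e
}

# reduce a gradient of shape `gd` back down to parent shape `pd`
reduce_grad <- function(g, pd) {
  gd <- dim(g)
  if (identical(gd, pd)) return(g)
  g <- cpp_reduce_sum(g, gd > pd)
  g
}

bcast_pair <- function(a, b) {
  da <- dim(a); db <- dim(b)
  td <- pmax(da, db)
  stopifnot(all(da == td | da == 1L), all(db == td | db == 1L))
  list(a = if (identical(da, td)) a else cpp_bcast(a, td),
       b = if (identical(db, td)) b else cpp_bcast(b, td))
}

wrapc <- function(x) if (is_tensor(x)) x else tensor(x)

up <- function(v, td) if (identical(dim(v), td)) v else cpp_bcast(v, td)

#' Elementwise tensor arithmetic with broadcasting
#'
#' `t_add`, `t_sub`, `t_mul` and `t_div` follow numpy-style broadcasting
#' over the four axes (any axis of extent 1 is stretched). Backward passes
#' re-expand operands on demand rather than pinning broadcast copies.
#'
#' @param a,b tensors or numeric arrays.
#' @return a tensor.
#' @export
t_add <- function(a, b) {
  a <- wrapc(a); b <- wrapc(b)
  da <- dim(a$v); db <- dim(b$v); td <- pmax(da, db)
  stopifnot(all(da == td | da == 1L), all(db == td | db == 1L))
  node(up(a$v, td) + up(b$v, td), list(a, b), function(g)
    list(reduce_grad(g, da), reduce_grad(g, db)))
}

#' @rdname t_add
#' @export
t_sub <- function(a, b) {
  a <- wrapc(a); b <- wrapc(b)
  da <- dim(a$v); db <- dim(b$v); td <- pmax(da, db)
  stopifnot(all(da == td | da == 1L), all(db == td | db == 1L))
  node(up(a$v, td) - up(b$v, td), list(a, b), function(g)
    list(reduce_grad(g, da), reduce_grad(-g, db)))
}

#' @rdname t_add
#' @export
t_mul <- function(a, b) {
  a <- wrapc(a); b <- wrapc(b)
  da <- dim(a$v); db <- dim(b$v); td <- pmax(da, db)
  stopifnot(all(da == td | da == 1L), all(db == td | db == 1L))
  node(up(a$v, td) * up(b$v, td), list(a, b), function(g)
    list(reduce_grad(g * up(b$v, td), da),
         reduce_grad(g * up(a$v, td), db)))
}

#' @rdname t_add
#' @export
t_div <- function(a, b) {
  a <- wrapc(a); b <- wrapc(b)
  da <- dim(a$v); db <- dim(b$v); td <- pmax(da, db)
  stopifnot(all(da == td | da == 1L), all(db == td | db == 1L))
  node(up(a$v, td) / up(b$v, td), list(a, b), function(g) {
    bv <- up(b$v, td)
    list(reduce_grad(g / bv, da),
         reduce_grad(-g * up(a$v, td) / (bv * bv), db))
  })
}

#' Elementwise nonlinearities
#'
#' @param a a tensor.
#' @return a tensor of the same shape.
#' @export
t_relu <- function(a) {
  node(pmax(a$v, 0), list(a), function(g) list(g * (a$v > 0)))
}

#' @rdname t_relu
#' @export
t_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' @rdname t_relu
#' @export
t_exp <- function(a) {
  ev <- exp(a$v)
  node(ev, list(a), function(g) list(g * ev))
}

#' @rdname t_relu
#' @export
t_sqrt <- function(a) {
  s <- sqrt(a$v)
  node(s, list(a), function(g) list(g * 0.5 / s))
}

t_scale <- function(a, k) {
  node(a$v * k, list(a), function(g) list(g * k))
}

t_shift <- function(a, k) {
  node(a$v + k, list(a), function(g) list(g))
}

#' Reductions over tensor axes
#'
#' Sum or mean over a subset of the four axes (1 = height, 2 = width,
#' 3 = channel, 4 = batch); reduced axes are kept with extent 1 so the
#' result broadcasts back naturally.
#'
#' @param a a tensor.
#' @param axes integer vector of axes to reduce.
#' @return a tensor.
#' @export
t_sum <- function(a, axes) {
  drop <- seq_len(4) %in% axes
  v <- cpp_reduce_sum(a$v, drop)
  ad <- dim(a$v)
  node(v, list(a), function(g) list(cpp_bcast(g, ad)))
}

#' @rdname t_sum
#' @export
t_mean <- function(a, axes) {
  drop <- seq_len(4) %in% axes
  n <- prod(dim(a$v)[axes])
  v <- cpp_reduce_sum(a$v, drop) / n
  ad <- dim(a$v)
  node(v, list(a), function(g) list(cpp_bcast(g / n, ad)))
}

#' Softmax along one axis
#'
#' Numerically stabilized softmax; the entries along `axis` are positive and
#' sum to one at every remaining index.
#'
#' @param a a tensor.
#' @param axis the normalization axis (1-4).
#' @return a tensor of the same shape.
#' @export
t_softmax <- function(a, axis) {
  drop <- seq_len(4) == axis
  m <- cpp_bcast(cpp_reduce_max(a$v, drop), dim(a$v))
  e <- exp(a$v - m)
  s <- cpp_bcast(cpp_reduce_sum(e, drop), dim(a$v))
  y <- e / s
  node(y, list(a), function(g) {
    gy <- g * y
    list(gy - y * cpp_bcast(cpp_reduce_sum(gy, drop), dim(y)))
  })
}

#' 2-D convolution (grouped)
#'
#' @param x input tensor (H, W, C, N).
#' @param w weight tensor (K, K, C/groups, C_out).
#' @param stride,pad,groups usual convolution hyperparameters.
#' @return output tensor (H', W', C_out, N).
#' @export
t_conv2d <- function(x, w, stride = 1L, pad = 0L, groups = 1L) {
  v <- cpp_conv2d(x$v, w$v, as.integer(stride), as.integer(pad),
                  as.integer(groups))
  node(v, list(x, w), function(g) {
    r <- cpp_conv2d_backward(x$v, w$v, g, as.integer(stride),
                             as.integer(pad), as.integer(groups),
                             x$requires_grad, w$requires_grad)
    list(if (x$requires_grad) r$gx else NULL,
         if (w$requires_grad) r$gw else NULL)
  })
}

#' Max pooling
#'
#' @param x input tensor.
#' @param k,stride,pad pooling window, stride and zero padding.
#' @return pooled tensor.
#' @export
t_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool(x$v, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$v)
  node(r$out, list(x), function(g)
    list(cpp_maxpool_backward(g, r$idx, as.integer(xd))))
}

#' Concatenate tensors along the channel axis
#'
#' @param xs list of tensors agreeing on all axes but the third.
#' @return a tensor.
#' @export
t_concat <- function(xs) {
  vs <- lapply(xs, tval)
  cs <- vapply(vs, function(v) dim(v)[3], 1L)
  d0 <- dim(vs[[1]])
  out <- array(0, c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (i in seq_along(vs)) {
    out[, , at + seq_len(cs[i]), ] <- vs[[i]]
    at <- at + cs[i]
  }
  node(out, xs, function(g) {
    at <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <<- at + cs[i]
      gi
    })
  })
}

#' Slice channels
#'
#' @param x a tensor.
#' @param idx integer channel indices to keep.
#' @return a tensor.
#' @export
t_slice_c <- function(x, idx) {
  xd <- dim(x$v)
  node(x$v[, , idx, , drop = FALSE], list(x), function(g) {
    gx <- array(0, xd)
    gx[, , idx, ] <- g
    list(gx)
  })
}

#' Reshape / permute
#'
#' `t_reshape` changes dims without reordering storage; `t_aperm`
#' transposes axes.
#'
#' @param x a tensor.
#' @param d new dim (length <= 4, padded with 1s).
#' @return a tensor.
#' @export
t_reshape <- function(x, d) {
  d <- c(d, rep(1L, 4 - length(d)))
  xd <- dim(x$v)
  stopifnot(prod(d) == prod(xd))
  v <- x$v
  dim(v) <- d
  node(v, list(x), function(g) { dim(g) <- xd; list(g) })
}

#' @rdname t_reshape
#' @param perm axis permutation of length 4.
#' @export
t_aperm <- function(x, perm) {
  inv <- order(perm)
  node(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

#' Matrix product for 2-D tensors
#'
#' Treats tensors of dim (r, c, 1, 1) as r x c matrices.
#'
#' @param a,b tensors.
#' @return tensor holding `a %*% b`.
#' @export
t_matmul <- function(a, b) {
  av <- matrix(a$v, dim(a$v)[1], dim(a$v)[2])
  bv <- matrix(b$v, dim(b$v)[1], dim(b$v)[2])
  node(as_dim4(av %*% bv), list(a, b), function(g) {
    gm <- matrix(g, nrow(av), ncol(bv))
    list(as_dim4(gm %*% t(bv)), as_dim4(crossprod(av, gm)))
  })
}

#' Moving average of window 2, stride 1, along the width axis
#'
#' Mild smoothing used by the location attention pools: out[w] is the mean
#' of positions w and w+1, with edge replication at the final position.
#'
#' @param x tensor whose spatial signal runs along axis 2.
#' @return tensor of identical shape.
#' @export
t_pool1d_w2 <- function(x) {
  L <- dim(x$v)[2]
  if (L == 1L) return(t_scale(x, 1))
  xv <- x$v
  nxt <- xv[, c(2:L, L), , , drop = FALSE]
  node((xv + nxt) / 2, list(x), function(g) {
    gx <- g / 2
    add <- gx[, c(1L, seq_len(L - 1)), , , drop = FALSE]
    add[, 1, , ] <- 0
    gx2 <- gx + add
    gx2[, L, , ] <- gx2[, L, , ] + gx[, L, , ]
    list(gx2)
  })
}

#' Fused batch normalization (training mode)
#'
#' Normalizes over axes (1, 2, 4) per channel with batch statistics and a
#' single fused backward pass, retaining one normalized copy instead of
#' the chain of intermediate arrays the composed form would keep.
#'
#' @param x input tensor (H, W, C, N).
#' @param gamma,beta affine parameter tensors of dim (1, 1, C, 1).
#' @param eps variance floor.
#' @return list: `out` tensor, `mean`, `var` (plain arrays, for running
#'   statistics).
#' @export
t_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  drop <- c(TRUE, TRUE, FALSE, TRUE)
  d <- dim(x$v)
  m <- prod(d[c(1, 2, 4)])
  mu <- cpp_reduce_sum(x$v, drop) / m
  xc <- x$v - cpp_bcast(mu, d)
  va <- cpp_reduce_sum(xc * xc, drop) / m
  isd <- 1 / sqrt(va + eps)
  xhat <- xc * cpp_bcast(isd, d)
  gv <- cpp_bcast(gamma$v, d)
  out <- node(xhat * gv + cpp_bcast(beta$v, d), list(x, gamma, beta),
              function(g) {
    dxh <- g * gv
    mdxh <- cpp_bcast(cpp_reduce_sum(dxh, drop) / m, d)
    mdxhx <- cpp_bcast(cpp_reduce_sum(dxh * xhat, drop) / m, d)
    dx <- cpp_bcast(isd, d) * (dxh - mdxh - xhat * mdxhx)
    list(dx,
         cpp_reduce_sum(g * xhat, drop),
         cpp_reduce_sum(g, drop))
  })
  list(out = out, mean = mu, var = va)
}

#' Run backpropagation from a scalar tensor
#'
#' Accumulates gradients into every reachable tensor with
#' `requires_grad = TRUE`.
#'
#' @param loss a tensor with a single element.
#' @export
backward <- function(loss) {
  stopifnot(length(loss$v) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$requires_grad || length(p$parents))
      stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, 1L), decreasing = TRUE)
  loss$grad <- array(1, dim(loss$v))
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is.null(gs[[j]])) next
      if (!p$requires_grad && !length(p$parents)) next
      g <- gs[[j]]
      if (is.null(dim(g))) dim(g) <- dim(p$v)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    # progressively release this node: drop its gradient, value and the
    # backward closure (which pins the forward intermediates it captured)
    if (!identical(nd, loss) && !nd$requires_grad) {
      nd$grad <- NULL
      nd$v <- NULL
      nd$bw <- NULL
    }
  }
  invisible(NULL)
}
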