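# ---------------------------------------------------------------------------
# Minimal neural-network module system on top of the autograd tape.
# A module is an environment with named parameter tensors, named submodules,
# optional buffers (running statistics), and a forward(self, x, training)
# function. Parameters are discovered recursively, torch-style.
# ---------------------------------------------------------------------------

new_module <- function(type, forward, params = list(), mods = list(), ...) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$forward <- forward
  m$params <- params
  m$mods <- mods
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = m)
  class(m) <- "scm_module"
  m
}

#' @export
print.scm_module <- function(x, ...) {
  cat("<scm_module ", x$type, ": ",
      format(count_parameters(x) , nsmall = 3), " M params>\n", sep = "")
  invisible(x)
}

#' Run a module forward
#'
#' @param m a module.
#' @param x input tensor (or whatever the module consumes).
#' @param training propagate training mode (batch-norm statistics).
#' @return output tensor.
#' @export
fwd <- function(m, x, training = FALSE) m$forward(m, x, training)

#' Collect all parameter tensors of a module tree
#'
#' @param m a module.
#' @param prefix internal; name prefix.
#' @return named list of `scm_tensor` parameters.
#' @export
collect_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$mods))
    out <- c(out, collect_params(m$mods[[nm]], paste0(prefix, nm, ".")))
  out
}

#' Count trainable parameters in millions
#'
#' Sums the lengths of every trainable tensor and reports millions rounded
#' to three decimals, the convention used for architecture comparison
#' tables. Batch-norm running statistics are buffers, not parameters.
#'
#' @param model a module.
#' @return numeric scalar (millions of parameters, 3 decimals).
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(collect_params(model), function(p) length(p$v), 1))
  round(n / 1e6, 3)
}

#' Exact trainable scalar count
#' @param model a module.
#' @return integer number of trainable scalars.
#' @export
count_parameters_exact <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$v), 1))
}

he_init <- function(d, fan_in) {
  array(stats::rnorm(prod(d), 0, sqrt(2 / fan_in)), d)
}

#' Convolution layer (bias-free)
#'
#' All convolutions in this package are bias-free and normally followed by
#' batch normalization, so closed-form parameter accounting and layer
#' instantiation agree.
#'
#' @param cin,cout channel counts.
#' @param k square kernel size.
#' @param stride,pad,groups convolution hyperparameters; `pad` defaults to
#'   `k %/% 2` ("same" at stride 1, exact halving of even sizes at stride 2).
#' @return a module.
#' @export
layer_conv2d <- function(cin, cout, k, stride = 1L, pad = k %/% 2L,
                         groups = 1L) {
  w <- tensor(he_init(c(k, k, cin %/% groups, cout), k * k * cin / groups),
              requires_grad = TRUE)
  new_module("conv2d",
    function(self, x, training) t_conv2d(x, self$params$w, self$stride,
                                         self$pad, self$groups),
    params = list(w = w), stride = stride, pad = pad, groups = groups,
    cin = cin, cout = cout, k = k)
}

#' Batch normalization layer
#'
#' @param c channel count.
#' @param eps,momentum numerical floor and running-statistics momentum.
#' @return a module.
#' @export
layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  g <- tensor(array(1, c(1, 1, c, 1)), requires_grad = TRUE)
  b <- tensor(array(0, c(1, 1, c, 1)), requires_grad = TRUE)
  new_module("bn",
    function(self, x, training) {
      if (training) {
        r <- t_batchnorm(x, self$params$gamma, self$params$beta, self$eps)
        self$run_mean <- (1 - self$momentum) * self$run_mean +
          self$momentum * r$mean
        self$run_var <- (1 - self$momentum) * self$run_var +
          self$momentum * r$var
        return(r$out)
      } else {
        # fused affine: y = x * scale + shift with
        # scale = gamma/sqrt(var+eps), shift = beta - mean*scale
        inv_sd <- 1 / sqrt(self$run_var + self$eps)
        scale <- t_mul(self$params$gamma, tensor(inv_sd))
        shift <- t_sub(self$params$beta,
                       t_mul(scale, tensor(self$run_mean)))
        return(t_add(t_mul(x, scale), shift))
      }
    },
    params = list(gamma = g, beta = b),
    run_mean = array(0, c(1, 1, c, 1)), run_var = array(1, c(1, 1, c, 1)),
    eps = eps, momentum = momentum, c = c)
}

#' Fully-connected layer
#'
#' Operates on (features, batch) matrices.
#'
#' @param cin,cout feature counts.
#' @param bias include a bias vector?
#' @return a module.
#' @export
layer_linear <- function(cin, cout, bias = TRUE) {
  w <- tensor(he_init(c(cout, cin), cin), requires_grad = TRUE)
  params <- list(w = w)
  if (bias) params$b <- tensor(array(0, c(cout, 1)), requires_grad = TRUE)
  new_module("linear",
    function(self, x, training) {
      y <- t_matmul(self$params$w, x)
      if (!is.null(self$params$b)) y <- t_add(y, self$params$b)
      y
    },
    params = params, cin = cin, cout = cout)
}

#' Layer containers and simple layers
#'
#' `layer_seq` chains modules; `act_relu` is a parameter-free ReLU module;
#' `layer_maxpool` / `layer_gap` wrap pooling.
#'
#' @param ... modules in order.
#' @return a module.
#' @export
layer_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "scm_module")) mods <- mods[[1]]
  names(mods) <- sprintf("s%02d", seq_along(mods))
  new_module("seq",
    function(self, x, training) {
      for (m in self$mods) x <- fwd(m, x, training)
      x
    },
    mods = mods)
}

#' @rdname layer_seq
#' @export
act_relu <- function() {
  new_module("relu", function(self, x, training) t_relu(x))
}

#' @rdname layer_seq
#' @param k,stride,pad pooling geometry.
#' @export
layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_module("maxpool",
    function(self, x, training) t_maxpool(x, self$k, self$stride, self$pad),
    k = k, stride = stride, pad = pad)
}

#' @rdname layer_seq
#' @export
layer_gap <- function() {
  new_module("gap", function(self, x, training) t_mean(x, c(1, 2)))
}

# ---------------------------------------------------------------------------
# Loss, optimizer
# ---------------------------------------------------------------------------

#' Cross-entropy loss from logits
#'
#' @param logits tensor of dim (classes, batch).
#' @param targets integer class labels in 1..classes, length batch.
#' @return scalar tensor (mean negative log-likelihood).
#' @export
t_cross_entropy <- function(logits, targets) {
  lv <- matrix(logits$v, dim(logits$v)[1], dim(logits$v)[2])
  n <- ncol(lv)
  m <- apply(lv, 2, max)
  e <- exp(sweep(lv, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  picked <- p[cbind(targets, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  node(as_dim4(loss), list(logits), function(g) {
    gr <- p
    gr[cbind(targets, seq_len(n))] <- gr[cbind(targets, seq_len(n))] - 1
    list(as_dim4(gr * (as.numeric(g) / n)))
  })
}

#' Softmax class probabilities from logits
#' @param logits tensor or matrix (classes, batch).
#' @return matrix of probabilities, columns summing to 1.
#' @export
softmax_probs <- function(logits) {
  lv <- if (is_tensor(logits)) logits$v else logits
  lv <- matrix(lv, dim(as_dim4(lv))[1])
  e <- exp(sweep(lv, 2, apply(lv, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

#' Adam optimizer
#'
#' @param params named list of parameter tensors (from [collect_params()]).
#' @param lr learning rate (training default 1e-4).
#' @param beta1,beta2,eps Adam moment decays and floor.
#' @return an optimizer object with `$step()` and `$zero_grad()`.
#' @export
optim_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p$v)))
  st$v <- lapply(params, function(p) array(0, dim(p$v)))
  st$t <- 0L
  list(
    params = params,
    step = function() {
      st$t <- st$t + 1L
      bc1 <- 1 - beta1^st$t
      bc2 <- 1 - beta2^st$t
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * p$grad
        st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * p$grad^2
        p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
      }
    },
    zero_grad = function() {
      for (p in params) p$grad <- NULL
    }
  )
}

#' Save / load model weights
#'
#' Weights are serialized as a named list of plain arrays (RDS format, the
#' R ecosystem's standard), keyed by the recursive parameter names, plus
#' batch-norm running statistics.
#'
#' @param model a module.
#' @param path file path.
#' @export
save_weights <- function(model, path) {
  ps <- collect_params(model)
  state <- lapply(ps, function(p) p$v)
  state[[".buffers"]] <- collect_buffers(model)
  saveRDS(state, path)
  invisible(path)
}

collect_buffers <- function(m, prefix = "") {
  out <- list()
  if (identical(m$type, "bn")) {
    out[[paste0(prefix, "run_mean")]] <- m$run_mean
    out[[paste0(prefix, "run_var")]] <- m$run_var
  }
  for (nm in names(m$mods))
    out <- c(out, collect_buffers(m$mods[[nm]], paste0(prefix, nm, ".")))
  out
}

restore_buffers <- function(m, bufs, prefix = "") {
  if (identical(m$type, "bn")) {
    rm_ <- bufs[[paste0(prefix, "run_mean")]]
    rv_ <- bufs[[paste0(prefix, "run_var")]]
    if (!is.null(rm_)) m$run_mean <- rm_
    if (!is.null(rv_)) m$run_var <- rv_
  }
  for (nm in names(m$mods))
    restore_buffers(m$mods[[nm]], bufs, paste0(prefix, nm, "."))
  invisible(NULL)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  state <- readRDS(path)
  bufs <- state[[".buffers"]]
  state[[".buffers"]] <- NULL
  ps <- collect_params(model)
  missing <- setdiff(names(ps), names(state))
  if (length(missing))
    stop("checkpoint is missing parameters: ",
         paste(utils::head(missing, 5), collapse = ", "))
  for (nm in names(ps)) {
    if (!identical(dim(ps[[nm]]$v), dim(state[[nm]])))
      stop("shape mismatch for ", nm)
    ps[[nm]]$v <- state[[nm]]
  }
  if (!is.null(bufs)) restore_buffers(model, bufs)
  invisible(model)
}
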