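# ---------------------------------------------------------------------------
# Training harness: run configuration, batching, the Adam training loop,
# and five-fold cross-validation.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' Defaults follow the reference training protocol: Adam, learning rate
#' 1e-4, batch size 8, 130 epochs, 224 x 224 inputs, 5 folds. Desk-scale
#' runs override epochs/size/model.
#'
#' @param command one of train, crossval, params, predict, gradcam, synth,
#'   eval.
#' @param model scheme id 1..14 or preset name (see [scheme_config()]).
#' @param learning_rate,batch_size,epochs,image_size,folds,seed protocol
#'   settings.
#' @param data_dir,out_dir,checkpoint paths.
#' @param num_classes classifier width.
#' @return object of class `run_config`.
#' @export
run_config <- function(command = "train", model = "mc_scmnet",
                       learning_rate = 1e-4, batch_size = 8L,
                       epochs = 130L, image_size = 224L, folds = 5L,
                       seed = 1L, data_dir = NULL, out_dir = ".",
                       checkpoint = NULL, num_classes = 4L) {
  structure(list(command = command, model = model, optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 image_size = as.integer(image_size),
                 folds = as.integer(folds), seed = as.integer(seed),
                 data_dir = data_dir, out_dir = out_dir,
                 checkpoint = checkpoint,
                 num_classes = as.integer(num_classes)),
            class = "run_config")
}

# stack inventory items into an (H, W, 3, n) batch, centered to [-0.5, 0.5]
batch_array <- function(inv, idx) {
  n <- length(idx)
  out <- array(0, c(inv$size, inv$size, 3L, n))
  for (j in seq_len(n)) out[, , , j] <- load_item(inv, idx[j])
  out - 0.5
}

#' Evaluate a model on inventory items
#'
#' @param model a network module.
#' @param inv a `dataset_inventory`.
#' @param idx item indices.
#' @param batch_size forward batch size.
#' @return list with `pred`, `labels`, `accuracy`, `loss`.
#' @export
evaluate_model <- function(model, inv, idx, batch_size = 8L) {
  preds <- integer(0); losses <- numeric(0)
  for (start in seq(1, length(idx), by = batch_size)) {
    bi <- idx[start:min(start + batch_size - 1, length(idx))]
    x <- tensor(batch_array(inv, bi))
    logits <- fwd(model, x, training = FALSE)
    p <- softmax_probs(logits)
    preds <- c(preds, apply(p, 2, which.max))
    losses <- c(losses, t_cross_entropy(logits, inv$items$label[bi])$v)
  }
  labels <- inv$items$label[idx]
  list(pred = preds, labels = labels,
       accuracy = mean(preds == labels), loss = mean(losses))
}

#' Train a model
#'
#' Cross-entropy loss, Adam, constant learning rate. One master seed fans
#' out to weight initialization (done at model build time by the caller)
#' and batch shuffling here.
#'
#' @param model a network module.
#' @param inv a `dataset_inventory`.
#' @param train_idx,val_idx item indices (val optional).
#' @param epochs,batch_size,lr protocol settings.
#' @param seed shuffle seed.
#' @param log_path optional CSV path (epoch, train_loss, train_acc,
#'   val_loss, val_acc), appended to when resuming.
#' @param epoch_offset starting epoch number (resume support).
#' @param verbose print one line per epoch.
#' @return data.frame training log.
#' @export
train_model <- function(model, inv, train_idx, val_idx = NULL,
                        epochs = 2L, batch_size = 8L, lr = 1e-4,
                        seed = 1L, log_path = NULL, epoch_offset = 0L,
                        verbose = FALSE) {
  params <- collect_params(model)
  opt <- optim_adam(params, lr = lr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 17L * epoch_offset)
  log <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; ep_hits <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      x <- tensor(batch_array(inv, bi))
      y <- inv$items$label[bi]
      logits <- fwd(model, x, training = TRUE)
      probs <- softmax_probs(logits)       # before backward frees the graph
      loss <- t_cross_entropy(logits, y)
      loss_v <- as.numeric(loss$v)
      opt$zero_grad()
      backward(loss)
      opt$step()
      ep_loss <- ep_loss + loss_v * length(bi)
      ep_hits <- ep_hits + sum(apply(probs, 2, which.max) == y)
      nb <- nb + length(bi)
    }
    row <- data.frame(epoch = ep + epoch_offset,
                      train_loss = ep_loss / nb, train_acc = ep_hits / nb,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val_idx) && length(val_idx)) {
      ev <- evaluate_model(model, inv, val_idx, batch_size)
      row$val_loss <- ev$loss; row$val_acc <- ev$accuracy
    }
    log[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f val_acc %s",
                      row$epoch, row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_acc), "-",
                             sprintf("%.3f", row$val_acc))))
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path)) {
    append <- file.exists(log_path) && epoch_offset > 0
    utils::write.table(log, log_path, sep = ",", row.names = FALSE,
                       col.names = !append, append = append)
  }
  log
}

#' Five-fold cross-validation
#'
#' Splits with [kfold_split()], trains a fresh model per fold, and reports
#' per-fold test accuracy and the mean, the standard protocol for final
#' performance measurement.
#'
#' @param build_fn zero-argument function returning a fresh model.
#' @param inv a `dataset_inventory`.
#' @param folds,epochs,batch_size,lr,seed protocol settings.
#' @param verbose print progress.
#' @return list: `per_fold` data.frame (fold, accuracy, n_test),
#'   `mean_accuracy`, `splits`.
#' @export
crossval <- function(build_fn, inv, folds = 5L, epochs = 2L,
                     batch_size = 8L, lr = 1e-4, seed = 1L,
                     verbose = FALSE) {
  splits <- kfold_split(inv, folds, seed)
  rows <- list()
  for (f in seq_along(splits)) {
    old <- .Random.seed_save()
    set.seed(seed + f)
    model <- build_fn()
    .Random.seed_restore(old)
    train_model(model, inv, splits[[f]]$train, epochs = epochs,
                batch_size = batch_size, lr = lr, seed = seed + 100L * f,
                verbose = verbose)
    ev <- evaluate_model(model, inv, splits[[f]]$test, batch_size)
    rows[[f]] <- data.frame(fold = f, accuracy = ev$accuracy,
                            n_test = length(splits[[f]]$test))
    if (verbose) message(sprintf("fold %d: accuracy %.3f", f, ev$accuracy))
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, mean_accuracy = mean(per_fold$accuracy),
       splits = splits)
}

#' Save / load a training checkpoint
#'
#' A checkpoint bundles the weight state, the network configuration and
#' the last finished epoch, so training can resume with continued epoch
#' numbering.
#'
#' @param model a network module.
#' @param path checkpoint path (RDS).
#' @param epoch last finished epoch.
#' @param classes class names.
#' @export
save_checkpoint <- function(model, path, epoch = 0L, classes = NULL) {
  state <- lapply(collect_params(model), function(p) p$v)
  saveRDS(list(weights = state, buffers = collect_buffers(model),
               cfg = model$cfg, epoch = epoch, classes = classes), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: list with `model`, `epoch`, `classes`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg)
  ps <- collect_params(model)
  for (nm in names(ps)) ps[[nm]]$v <- ck$weights[[nm]]
  restore_buffers(model, ck$buffers)
  list(model = model, epoch = ck$epoch, classes = ck$classes)
}
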