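# ---------------------------------------------------------------------------
# Metrics, one-way ANOVA, Grad-CAM.
#
# Per-class metrics use one-vs-rest confusion accounting:
#   accuracy  = (TP + TN) / (TP + TN + FP + FN)   (aggregate: trace/total)
#   precision = TP / (TP + FP)
#   recall    = TP / (TP + FN)
#   F1        = 2 PR / (P + R)
# Aggregates are reported in three modes: macro (unweighted class mean),
# weighted (support-weighted mean), and — the default for F1 — the
# harmonic mean of the aggregate precision and recall, the arithmetic the
# reference comparison table follows exactly.
# ---------------------------------------------------------------------------

#' Confusion matrix from label vectors
#'
#' Entry (i, j) counts items of true class i predicted as class j.
#'
#' @param labels_true,labels_pred equal-length integer (1..n_classes) or
#'   factor/character vectors.
#' @param n_classes number of classes (inferred from labels when missing).
#' @param class_names optional class names.
#' @return object of class `confusion_matrix` (an integer matrix).
#' @export
confusion <- function(labels_true, labels_pred, n_classes = NULL,
                      class_names = NULL) {
  if (length(labels_true) != length(labels_pred))
    stop("invalid-input: label vectors differ in length", call. = FALSE)
  if (is.factor(labels_true) || is.character(labels_true)) {
    lv <- if (!is.null(class_names)) class_names
          else sort(unique(c(as.character(labels_true),
                             as.character(labels_pred))))
    labels_true <- match(as.character(labels_true), lv)
    labels_pred <- match(as.character(labels_pred), lv)
    class_names <- lv
  }
  if (is.null(n_classes)) n_classes <- max(labels_true, labels_pred)
  if (any(is.na(labels_true)) || any(is.na(labels_pred)) ||
      any(labels_true < 1) || any(labels_true > n_classes) ||
      any(labels_pred < 1) || any(labels_pred > n_classes))
    stop("invalid-input: label out of range", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels_true))
    cm[labels_true[i], labels_pred[i]] <- cm[labels_true[i], labels_pred[i]] + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  dimnames(cm) <- list(true = class_names, pred = class_names)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest counts per class
#' @param cm a [confusion()] matrix.
#' @return data.frame with TP, FP, TN, FN per class.
#' @export
cm_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  data.frame(class = rownames(cm), TP = tp, FP = fp, TN = tn, FN = fn,
             support = rowSums(cm), row.names = NULL)
}

pct <- function(x) round(100 * x, 2)

#' Metrics report from a confusion matrix
#'
#' @param cm a [confusion()] matrix.
#' @return object of class `metrics_report`: `$per_class` (precision,
#'   recall, F1 in percent, 2 decimals), `$aggregate` (macro / weighted /
#'   harmonic rows), `$accuracy`, and `$f1` (default mode: harmonic F1 of
#'   the aggregate precision and recall, weighted aggregation).
#' @export
metrics_report <- function(cm) {
  if (!inherits(cm, "confusion_matrix") || sum(cm) == 0)
    stop("expected a nonempty confusion_matrix", call. = FALSE)
  cc <- cm_counts(cm)
  degen <- (cc$TP + cc$FP == 0) | (cc$TP + cc$FN == 0)
  if (any(degen))
    warning("degenerate class (zero precision or recall denominator): ",
            paste(cc$class[degen], collapse = ", "), call. = FALSE)
  sdiv <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- sdiv(cc$TP, cc$TP + cc$FP)
  rec <- sdiv(cc$TP, cc$TP + cc$FN)
  f1 <- sdiv(2 * prec * rec, prec + rec)
  per_class <- data.frame(class = cc$class, support = cc$support,
                          precision = pct(prec), recall = pct(rec),
                          F1 = pct(f1))
  w <- cc$support / sum(cc$support)
  agg <- function(p, r) {
    data.frame(precision = pct(p), recall = pct(r),
               F1_of_aggregates = pct(ifelse(p + r == 0, 0,
                                             2 * p * r / (p + r))),
               F1_mean = NA_real_)
  }
  macro <- agg(mean(prec), mean(rec)); macro$F1_mean <- pct(mean(f1))
  weighted <- agg(sum(w * prec), sum(w * rec))
  weighted$F1_mean <- pct(sum(w * f1))
  aggregate <- rbind(macro = macro, weighted = weighted)
  accuracy <- pct(sum(diag(cm)) / sum(cm))
  structure(list(per_class = per_class, aggregate = aggregate,
                 accuracy = accuracy,
                 f1 = weighted$F1_of_aggregates),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n"); print(x$per_class)
  cat("\nAggregates (%):\n"); print(x$aggregate)
  cat("\nAccuracy:", x$accuracy, "  F1 (harmonic of aggregates):",
      x$f1, "\n")
  invisible(x)
}

#' Harmonic F1 of aggregate precision and recall
#'
#' The arithmetic used by comparison tables that print aggregate precision,
#' recall and F1: F1 = 2PR/(P+R) applied to the printed aggregates.
#'
#' @param precision,recall aggregate values (percent or fraction, same
#'   scale).
#' @return F1 on the same scale, rounded to 2 decimals when in percent.
#' @export
f1_of_aggregates <- function(precision, recall) {
  v <- 2 * precision * recall / (precision + recall)
  if (max(precision, recall) > 1) round(v, 2) else v
}

#' Write a metrics report
#' @param report a `metrics_report`.
#' @param csv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(report$per_class, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}

# ---------------------------------------------------------------------------
# One-way ANOVA
# ---------------------------------------------------------------------------

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition with
#' F = MS_between / MS_within, the p-value from the F distribution, and the
#' upper-alpha critical value. A degenerate within-group variance of zero
#' returns F = 0 when all values are identical, otherwise F = Inf with
#' p = 0.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @param alpha significance level (default 0.05).
#' @return object of class `anova_result` with F, p, F_crit, dfs and SS
#'   components.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least two values", call. = FALSE)
  v <- unlist(groups)
  n <- length(v); g <- length(groups)
  grand <- mean(v)
  ss_between <- sum(vapply(groups, function(x)
    length(x) * (mean(x) - grand)^2, 1))
  ss_within <- sum(vapply(groups, function(x)
    sum((x - mean(x))^2), 1))
  df_b <- g - 1L; df_w <- n - g
  ms_b <- ss_between / df_b; ms_w <- ss_within / df_w
  if (ms_w == 0) {
    f <- if (ms_b == 0) 0 else Inf
    p <- if (ms_b == 0) 1 else 0
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = f, p = p,
                 F_crit = stats::qf(1 - alpha, df_b, df_w),
                 df_between = df_b, df_within = df_w,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = sum((v - grand)^2), alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.6g, F_crit(%.2f) = %.4f\n",
              x$df_between, x$df_within, x$F, x$p, x$alpha, x$F_crit))
  invisible(x)
}

#' Write an ANOVA table as CSV (F, p, F_crit columns)
#' @param res an `anova_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(res, path) {
  utils::write.csv(data.frame(source = "Between Groups",
                              F = round(res$F, 4),
                              p_value = signif(res$p, 4),
                              F_crit = round(res$F_crit, 4)),
                   path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Grad-CAM
# ---------------------------------------------------------------------------

#' Gradient-weighted class activation map
#'
#' Runs the model on one image, backpropagates the target class score to
#' the chosen stage output, weights each channel by its spatially averaged
#' gradient, rectifies, min-max normalizes and bilinearly upsamples to the
#' input resolution.
#'
#' @param model a network from [build_network()].
#' @param image (H, W, 3) array in [0, 1].
#' @param target_layer one of "stem", "stage1".."stage4" (default
#'   "stage4", the last block of the final stage).
#' @param target_class class index 1..K (default: the predicted class).
#' @return list with `heatmap` (H x W in [0, 1]), `class`, `probs`.
#' @export
grad_cam <- function(model, image, target_layer = "stage4",
                     target_class = NULL) {
  layers <- c("stem", paste0("stage", 1:4))
  if (!target_layer %in% layers)
    stop("invalid-input: unknown layer '", target_layer,
         "'; available: ", paste(layers, collapse = ", "), call. = FALSE)
  x <- tensor(as_dim4(image - 0.5))
  model$record <- TRUE
  on.exit(model$record <- FALSE, add = TRUE)
  logits <- fwd(model, x, training = FALSE)
  probs <- softmax_probs(logits)[, 1]
  if (is.null(target_class)) target_class <- which.max(probs)
  act <- model$acts[[target_layer]]
  act$requires_grad <- TRUE
  onehot <- matrix(0, dim(logits$v)[1], 1)
  onehot[target_class, 1] <- 1
  backward(t_sum(t_mul(logits, tensor(onehot)), 1:4))
  gr <- act$grad
  av <- act$v
  wts <- apply(gr[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(av)[1], dim(av)[2])
  for (c in seq_along(wts)) cam <- cam + wts[c] * av[, , c, 1]
  cam <- pmax(cam, 0)
  hm <- cpp_resize_bilinear(array(cam, c(dim(cam), 1L)),
                            dim(image)[1], dim(image)[2])[, , 1]
  rng <- range(hm)
  hm <- if (rng[2] > rng[1]) (hm - rng[1]) / (rng[2] - rng[1]) else hm * 0
  list(heatmap = hm, class = target_class, probs = probs)
}

#' Overlay a Grad-CAM heatmap on an image
#'
#' @param image (H, W, 3) array.
#' @param heatmap (H, W) array in [0, 1].
#' @param alpha blend factor.
#' @return (H, W, 3) array.
#' @export
gradcam_overlay <- function(image, heatmap, alpha = 0.45) {
  # simple blue->green->red colormap
  r <- pmin(pmax(1.5 * heatmap - 0.25, 0), 1)
  g <- 1 - abs(2 * heatmap - 1)
  b <- pmin(pmax(1.25 - 1.5 * heatmap, 0), 1)
  out <- image
  out[, , 1] <- (1 - alpha) * image[, , 1] + alpha * r
  out[, , 2] <- (1 - alpha) * image[, , 2] + alpha * g
  out[, , 3] <- (1 - alpha) * image[, , 3] + alpha * b
  pmin(pmax(out, 0), 1)
}
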