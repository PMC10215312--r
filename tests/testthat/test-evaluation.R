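# Confusion/metric arithmetic, ANOVA, Grad-CAM basics.

test_that("confusion matrices count correctly", {
  cm <- confusion(c(1, 2, 3, 4), c(1, 2, 3, 4), 4)
  expect_true(all(cm == diag(4)))
  cm2 <- confusion(c(1, 2, 3), c(2, 2, 2), 3)
  expect_equal(unname(colSums(cm2)), c(0, 3, 0))
  set.seed(61)
  yt <- sample(1:4, 500, replace = TRUE)
  yp <- sample(1:4, 500, replace = TRUE)
  cm3 <- confusion(yt, yp, 4)
  # brute-force counting oracle
  for (i in 1:4) for (j in 1:4) {
    cnt <- 0L
    for (q in 1:500) if (yt[q] == i && yp[q] == j) cnt <- cnt + 1L
    expect_identical(unname(cm3[i, j]), cnt)
  }
  expect_error(confusion(c(1, 5), c(1, 1), 4), "out of range")
  expect_error(confusion(1:3, 1:2), "length")
  # one-vs-rest accounting closes: TP+FP+TN+FN = total per class
  cc <- cm_counts(cm3)
  expect_true(all(cc$TP + cc$FP + cc$TN + cc$FN == 500))
  expect_identical(unname(rowSums(cm3)), cc$support)
})

test_that("metric arithmetic: perfect classifier, harmonic identities,
           degenerate classes", {
  cm <- confusion(rep(1:4, each = 5), rep(1:4, each = 5), 4)
  rep_ <- metrics_report(cm)
  expect_equal(rep_$accuracy, 100)
  expect_true(all(rep_$per_class$precision == 100))
  expect_true(all(rep_$per_class$F1 == 100))
  expect_equal(rep_$f1, 100)
  # per-class F1 is the harmonic mean of that class's precision and recall
  set.seed(62)
  cm2 <- confusion(sample(1:3, 300, TRUE), sample(1:3, 300, TRUE), 3)
  cc <- cm_counts(cm2)
  p <- cc$TP / (cc$TP + cc$FP); r <- cc$TP / (cc$TP + cc$FN)
  rep2 <- metrics_report(cm2)
  expect_equal(rep2$per_class$F1, round(100 * 2 * p * r / (p + r), 2),
               tolerance = 1e-10)
  expect_equal(rep2$accuracy, round(100 * sum(diag(cm2)) / sum(cm2), 2))
  # F1 lies between precision and recall per class
  expect_true(all(rep2$per_class$F1 >=
                    pmin(rep2$per_class$precision, rep2$per_class$recall) - 1e-9))
  expect_true(all(rep2$per_class$F1 <=
                    pmax(rep2$per_class$precision, rep2$per_class$recall) + 1e-9))
  # a never-predicted class reports 0 with a warning
  cm3 <- confusion(c(1, 1, 2, 2), c(1, 1, 1, 1), 2)
  expect_warning(rep3 <- metrics_report(cm3), "degenerate")
  expect_equal(rep3$per_class$precision[2], 0)
})

test_that("published aggregate precision/recall reproduce the published F1
           under the harmonic rule", {
  bm <- benchmark_aggregate_metrics()
  # exact for the split-attention baseline and MC-SCMNet rows; the 50-layer
  # baseline row carries a 0.01 rounding residue in its printed aggregates
  expect_equal(f1_of_aggregates(84.13, 84.05), 84.09)
  expect_equal(f1_of_aggregates(88.89, 88.93), 88.91)
  for (i in seq_len(nrow(bm)))
    expect_lt(abs(f1_of_aggregates(bm$precision[i], bm$recall[i]) - bm$F1[i]),
              0.015)
})

test_that("one-way ANOVA matches the textbook decomposition and handles
           degenerate groups", {
  # all groups identical -> F = 0
  expect_equal(one_way_anova(list(c(1, 1), c(1, 1)))$F, 0)
  # zero within-variance, distinct means -> overflow guard
  res <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
  set.seed(63)
  g <- list(rnorm(5), rnorm(7, 1), rnorm(6, 2))
  res2 <- one_way_anova(g)
  orc <- oracle_anova(g)
  expect_equal(res2$F, orc$F, tolerance = 1e-10)
  expect_equal(res2$p, orc$p, tolerance = 1e-10)
  expect_equal(res2$ss_between + res2$ss_within, res2$ss_total,
               tolerance = 1e-8 * res2$ss_total)
  expect_identical(res2$df_between, 2L)
  expect_identical(res2$df_within, 15L)
  # and against R's own linear-model ANOVA
  v <- unlist(g); fg <- factor(rep(seq_along(g), lengths(g)))
  a <- stats::anova(stats::lm(v ~ fg))
  expect_equal(res2$F, a$`F value`[1], tolerance = 1e-10)
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1, 1:2)), "two values")
})

test_that("ANOVA over the published 12 x 4 per-category accuracies
           reproduces the published F and F_crit", {
  bm <- benchmark_category_accuracies()
  groups <- lapply(seq_len(nrow(bm)), function(i) as.numeric(bm[i, -1]))
  res <- one_way_anova(groups, alpha = 0.05)
  expect_identical(res$df_between, 11L)
  expect_identical(res$df_within, 36L)
  expect_equal(round(res$F, 4), 4.1364)
  expect_equal(round(res$F_crit, 4), 2.0666)
  expect_lt(res$p, 0.05)
})

test_that("Grad-CAM heatmaps are normalized, aligned, and validate layers", {
  set.seed(64)
  m <- build_network(scheme_config("mc_scmnet_small", 4L))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  gc <- grad_cam(m, img, target_layer = "stage3")
  expect_identical(dim(gc$heatmap), c(64L, 64L))
  expect_true(all(gc$heatmap >= 0 & gc$heatmap <= 1))
  expect_equal(max(gc$heatmap), 1)
  expect_equal(sum(gc$probs), 1, tolerance = 1e-5)
  expect_error(grad_cam(m, img, target_layer = "stage9"), "available")
  ov <- gradcam_overlay(img, gc$heatmap)
  expect_identical(dim(ov), dim(img))
  expect_true(all(ov >= 0 & ov <= 1))
})
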