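# ---------------------------------------------------------------------------
# Reference DFML benchmark figures shipped with the package.
#
# These are published benchmark inputs (dataset inventory, per-category
# accuracies of twelve networks, and aggregate evaluation metrics of three
# networks on the DFML four-class task). They serve as inputs to the
# augmentation accounting and the ANOVA model comparison; the package does
# not claim to re-measure them.
# ---------------------------------------------------------------------------

#' DFML dataset inventory (originals)
#'
#' Per-class image counts of the four-class dog-feces-by-moisture-level
#' benchmark before augmentation.
#'
#' @return data.frame with `category` and `count`.
#' @export
dfml_inventory <- function() {
  data.frame(category = c("Lack of water", "Normal", "Soft stool",
                          "Diarrhea"),
             count = c(482L, 491L, 335L, 315L))
}

#' Published per-category accuracies of the twelve benchmark networks
#'
#' Four per-category accuracies (%) for each of twelve classification
#' networks on the DFML task: seven basic networks and six
#' state-of-the-art methods, with the MC-SCMNet row appearing once.
#' Used as the input of the one-way ANOVA model comparison (12 groups of
#' 4 observations).
#'
#' @return data.frame: network, diarrhea, lack_of_water, normal, soft_stool.
#' @export
benchmark_category_accuracies <- function() {
  df <- rbind(
    c("AlexNet",            65.87, 87.83, 58.73, 43.65),
    c("VGG-16",             59.52, 75.13, 76.72, 43.65),
    c("GoogleNet",          72.22, 71.95, 75.13, 55.56),
    c("ResNet-50",          88.10, 85.19, 71.43, 80.95),
    c("ResNeSt-50",         88.89, 93.12, 76.19, 77.78),
    c("SCMNet",             89.68, 93.65, 78.84, 80.16),
    c("MC-SCMNet",          93.65, 92.06, 85.71, 84.13),
    c("ResNeXt50",          87.30, 83.60, 73.54, 79.36),
    c("B-ARNet",            90.48, 84.13, 85.19, 80.16),
    c("DMS-Robust Alexnet", 88.89, 88.36, 80.95, 83.33),
    c("Swin-transformer",   91.27, 90.48, 83.07, 81.75),
    c("CA-MSNet",           89.68, 91.53, 82.54, 82.54))
  out <- data.frame(network = df[, 1],
                    diarrhea = as.numeric(df[, 2]),
                    lack_of_water = as.numeric(df[, 3]),
                    normal = as.numeric(df[, 4]),
                    soft_stool = as.numeric(df[, 5]),
                    stringsAsFactors = FALSE)
  out
}

#' Published aggregate evaluation metrics of three networks
#'
#' Aggregate precision, recall, F1 and accuracy (%) of the 50-layer
#' residual baseline, the split-attention baseline and MC-SCMNet on the
#' DFML task. The F1 column follows the harmonic-of-aggregates arithmetic
#' (see [f1_of_aggregates()]).
#'
#' @return data.frame.
#' @export
benchmark_aggregate_metrics <- function() {
  data.frame(model = c("ResNet50", "ResNeSt50", "MC-SCMNet"),
             precision = c(80.79, 84.13, 88.89),
             recall = c(81.16, 84.05, 88.93),
             F1 = c(80.98, 84.09, 88.91),
             accuracy = c(80.25, 83.64, 88.27),
             stringsAsFactors = FALSE)
}
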