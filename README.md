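# scmnet

Split-attention convolutional networks with coordinate attention and
multi-scale down-sampling, for fine-grained classification of dog feces
by moisture level (diarrhea, lack of water, normal, soft stool) in
cluttered outdoor scenes — the kind of four-class fecal scoring used for
canine gastrointestinal monitoring.

The package is a complete, self-contained R implementation:

- **conv primitives** — depthwise separable convolution (DSC) with exact
  closed-form accounting: `W_SC = K²CN`, `W_DSC = K²C + CN`,
  `F_W = F_O = 1/N + 1/K²`; a squeeze-and-excitation (SE) gate.
- **CLAM** — coordinate location attention: directional (row/column) mean
  encodings pass through a location attention unit
  (`FC(P(F)) ⊙ DSC₃ₓ₃(P(F))`), are fused with a coordinate-embedded copy
  of the input, and gate the map through a channel softmax.
- **MADM** — multi-scale attention down-sampling: parallel stride-2
  max-pool / 5×5-DSC / 7×7-DSC branches, concatenated, projected 1×1 and
  SE-gated.
- **backbone** — Split-Attention over radix `r` and cardinal `k`
  (R-Softmax: softmax over splits for `r > 1`, sigmoid for `r = 1`), the
  SCM residual block `Y = T(X) + V`, and a 14-scheme ablation grid from a
  plain 50-layer residual baseline up to MC-SCMNet.
- **data** — class-per-directory image ingestion, the augmentation
  protocol (blur, contrast, noise, brightness, affine; exactly one
  variant per original), leakage-free 5-fold splitting, and a
  deterministic synthetic 4-class image generator.
- **evaluation** — per-class/aggregate precision, recall, F1, accuracy;
  one-way ANOVA model comparison; Grad-CAM heatmaps.
- **cli** — `train`, `crossval`, `params`, `predict`, `gradcam`, `synth`,
  `eval` commands (`inst/cli/scmnet`).

There is no deep-learning framework dependency: the package ships its own
tape-based autograd over R arrays with Rcpp/Armadillo convolution
kernels, gradient-checked against numerical differentiation.

## Worked example

```r
library(scmnet)

# exact parameter accounting of the 50-layer residual reference
set.seed(1)
model <- build_network(scheme_config(1L, num_classes = 1000L))
count_parameters(model)
#> [1] 25.557        # 25,557,032 trainable scalars

# DSC saving for a 3x3, 16 -> 32 convolution
dsc_ratios(conv_spec(16, 32, 3))$F_W
#> [1] 0.1423611     # = 656 / 4608 = 1/32 + 1/9

# harmonic F1 of published aggregate precision/recall
f1_of_aggregates(88.89, 88.93)
#> [1] 88.91

# one-way ANOVA over the published 12 x 4 per-category accuracies
bm <- benchmark_category_accuracies()
res <- one_way_anova(lapply(seq_len(nrow(bm)), function(i) as.numeric(bm[i, -1])))
res
#> One-way ANOVA: F(11, 36) = 4.1364, p = 0.000578582, F_crit(0.05) = 2.0666

# end-to-end on synthetic data
spec <- synthetic_spec(image_size = 64, n_per_class = 20, seed = 1)
generate_synthetic_dataset(spec, "synth")
inv  <- augment_dataset(load_image_folder("synth", 64), seed = 1)
folds <- kfold_split(inv, folds = 5, seed = 1)
net <- build_network(scheme_config("mc_scmnet_small", 4L))
log <- train_model(net, inv, folds[[1]]$train, folds[[1]]$test,
                   epochs = 2, batch_size = 8, lr = 5e-4, seed = 1)
```

The first number is the headline check: the Scheme-1 reference network
(canonical bottleneck residual 50-layer, 1000-class head, bias-free
convolutions + batch norm) counts exactly 25.557 M trainable parameters.
The ANOVA line reproduces the published between-network comparison
(F = 4.1364 > F_crit = 2.0666, so the null of equal per-category
accuracies is rejected at α = 0.05).

## CLI

```sh
Rscript inst/cli/scmnet synth   --out data --n-per-class 50 --seed 1
Rscript inst/cli/scmnet train   --data data --model mc_scmnet_small \
                                --epochs 2 --image-size 64 --out run1
Rscript inst/cli/scmnet params  --model 1
Rscript inst/cli/scmnet predict --checkpoint run1/checkpoint.rds img.png
```

## Scope

Reproducing the published 88.27% DFML accuracy requires the original
dataset and GPU-scale training and is explicitly out of scope; the
package reproduces the desk-scale published numbers (parameter count,
metric arithmetic, ANOVA, augmentation accounting) and validates the
architecture end-to-end on synthetic data. See
`vignettes/scmnet-methods.Rmd` for the model details and design
decisions.
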