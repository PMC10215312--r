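# ---------------------------------------------------------------------------
# Image-folder ingestion, the augmentation protocol, and k-fold splitting.
#
# Augmentation protocol (one variant per original, doubling every class):
#   (1) Gaussian blur with probability 0.5, sigma ~ U[0, 0.5] px
#   (2) contrast jitter, factor ~ U[0.75, 1.25], always applied
#   (3) Gaussian noise (sigma 0.03 of dynamic range); with probability 0.5
#       one noise plane is shared across channels, otherwise per channel
#   (4) brightness shift of +-20% of dynamic range on 20% of the images
#   (5) affine transform: scale [0.9, 1.1], translation +-10%, rotation
#       +-25 deg, shear +-8 deg, always applied
# Transform parameters are sampled once when the plan is realized and
# stored on the inventory, so loading is deterministic thereafter.
# ---------------------------------------------------------------------------

#' Augmentation plan
#'
#' @param blur_prob,blur_sigma_max Gaussian blur probability and the upper
#'   end of its sigma range.
#' @param contrast_range contrast jitter factor range.
#' @param noise_sigma,noise_shared_prob Gaussian noise scale and the
#'   probability of the single-plane (channel-shared) sampling mode.
#' @param brightness_prob,brightness_delta fraction of images receiving a
#'   brightness shift, and its maximum magnitude.
#' @param affine_scale,affine_translate,affine_rotate,affine_shear affine
#'   ranges (scale interval, max |shift| fraction, max |angle| deg).
#' @param variants_per_image fixed at 1 (augmentation doubles the set).
#' @return object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(blur_prob = 0.5, blur_sigma_max = 0.5,
                              contrast_range = c(0.75, 1.25),
                              noise_sigma = 0.03, noise_shared_prob = 0.5,
                              brightness_prob = 0.2, brightness_delta = 0.2,
                              affine_scale = c(0.9, 1.1),
                              affine_translate = 0.1,
                              affine_rotate = 25, affine_shear = 8,
                              variants_per_image = 1L) {
  if (blur_sigma_max > 0.5 + 1e-12)
    stop("blur sigma range must stay within [0, 0.5]", call. = FALSE)
  if (variants_per_image != 1L)
    stop("variants_per_image is fixed at 1", call. = FALSE)
  structure(list(blur_prob = blur_prob, blur_sigma_max = blur_sigma_max,
                 contrast_range = contrast_range, noise_sigma = noise_sigma,
                 noise_shared_prob = noise_shared_prob,
                 brightness_prob = brightness_prob,
                 brightness_delta = brightness_delta,
                 affine_scale = affine_scale,
                 affine_translate = affine_translate,
                 affine_rotate = affine_rotate, affine_shear = affine_shear,
                 variants_per_image = 1L),
            class = "augmentation_plan")
}

read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) png::readPNG(path)
         else if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
         else stop("unsupported image format: ", path, call. = FALSE)
  if (is.null(dim(img)) || length(dim(img)) == 2L)
    img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load a class-per-directory image dataset
#'
#' Expects `root/<class>/*.png|jpg`; images are decoded as RGB and resized
#' to `size` x `size`. Unreadable files are skipped with a warning; an
#' empty class directory warns; a root with no images errors.
#'
#' @param root dataset directory.
#' @param size target square size (default 224).
#' @return a `dataset_inventory`: items table, class names, per-class
#'   counts, and a `load_item(inv, i)` accessor.
#' @export
load_image_folder <- function(root, size = 224L) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root,
                              call. = FALSE)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  dirs <- dirs[basename(dirs) != "masks"]
  if (!length(dirs)) stop("no class subdirectories under ", root,
                          call. = FALSE)
  items <- list()
  for (d in dirs) {
    fs <- sort(list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                          full.names = TRUE))
    if (!length(fs)) {
      warning("empty class directory: ", d, call. = FALSE)
      next
    }
    items[[length(items) + 1L]] <- data.frame(path = fs,
                                              class = basename(d),
                                              stringsAsFactors = FALSE)
  }
  if (!length(items)) stop("no images found under ", root, call. = FALSE)
  items <- do.call(rbind, items)
  classes <- sort(unique(items$class))
  items$label <- match(items$class, classes)
  items$source <- NA_integer_          # NA = original
  inv <- structure(list(items = items, classes = classes,
                        size = as.integer(size),
                        transforms = vector("list", nrow(items))),
                   class = "dataset_inventory")
  inv
}

#' @export
print.dataset_inventory <- function(x, ...) {
  cat("<dataset_inventory: ", nrow(x$items), " items, ",
      length(x$classes), " classes>\n", sep = "")
  print(inventory_counts(x))
  invisible(x)
}

#' Per-class item counts
#' @param inv a `dataset_inventory`.
#' @return named integer vector.
#' @export
inventory_counts <- function(inv) {
  vapply(inv$classes, function(cl) sum(inv$items$class == cl), 1L)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- dim(img)[1]; W <- dim(img)[2]
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    pm <- m[c(rep(1, rad), 1:H, rep(H, rad)), ]
    acc <- matrix(0, H, W)
    for (j in seq_along(k)) acc <- acc + k[j] * pm[(j - 1) + 1:H, ]
    pm <- acc[, c(rep(1, rad), 1:W, rep(W, rad))]
    acc <- matrix(0, H, W)
    for (j in seq_along(k)) acc <- acc + k[j] * pm[, (j - 1) + 1:W]
    img[, , ch] <- acc
  }
  img
}

sample_transform_record <- function(plan) {
  rec <- list()
  rec$blur <- if (stats::runif(1) < plan$blur_prob)
    stats::runif(1, 0, plan$blur_sigma_max) else 0
  rec$contrast <- stats::runif(1, plan$contrast_range[1],
                               plan$contrast_range[2])
  rec$noise_shared <- stats::runif(1) < plan$noise_shared_prob
  rec$noise_seed <- sample.int(.Machine$integer.max, 1)
  rec$noise_sigma <- plan$noise_sigma
  rec$brightness <- if (stats::runif(1) < plan$brightness_prob)
    stats::runif(1, -plan$brightness_delta, plan$brightness_delta) else 0
  rec$scale <- stats::runif(1, plan$affine_scale[1], plan$affine_scale[2])
  rec$translate <- stats::runif(2, -plan$affine_translate,
                                plan$affine_translate)
  rec$rotate <- stats::runif(1, -plan$affine_rotate, plan$affine_rotate)
  rec$shear <- stats::runif(1, -plan$affine_shear, plan$affine_shear)
  rec
}

apply_transform_record <- function(img, rec) {
  if (rec$blur > 0) img <- gaussian_blur(img, rec$blur)
  img <- (img - 0.5) * rec$contrast + 0.5
  old <- .Random.seed_save()
  set.seed(rec$noise_seed)
  if (rec$noise_shared) {
    nz <- matrix(stats::rnorm(prod(dim(img)[1:2]), 0, rec$noise_sigma),
                 dim(img)[1])
    for (ch in seq_len(dim(img)[3])) img[, , ch] <- img[, , ch] + nz
  } else {
    img <- img + array(stats::rnorm(length(img), 0, rec$noise_sigma),
                       dim(img))
  }
  .Random.seed_restore(old)
  img <- img + rec$brightness
  # inverse-map affine about the image center
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- rec$rotate * pi / 180; sh <- tan(rec$shear * pi / 180)
  fwdm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
    matrix(c(1, 0, sh, 1), 2) * rec$scale
  inv <- solve(fwdm)
  cR <- (H - 1) / 2; cC <- (W - 1) / 2
  tr <- c(rec$translate[1] * H, rec$translate[2] * W)
  off <- c(cR, cC) - inv %*% (c(cR, cC) + tr)
  A <- c(inv[1, 1], inv[2, 1], inv[1, 2], inv[2, 2], off[1], off[2])
  img <- cpp_affine_warp(img, A, 0.5)
  pmin(pmax(img, 0), 1)
}

#' Augment a dataset inventory
#'
#' Appends exactly one augmented variant per original item (per-class
#' counts double). Transform parameters are sampled here, recorded on the
#' inventory, and applied deterministically when items are loaded.
#'
#' @param inv a `dataset_inventory` of originals.
#' @param plan an [augmentation_plan()].
#' @param seed integer seed for the transform sampling.
#' @return the augmented inventory.
#' @export
augment_dataset <- function(inv, plan = augmentation_plan(), seed = 1L) {
  stopifnot(inherits(inv, "dataset_inventory"),
            inherits(plan, "augmentation_plan"))
  if (any(!is.na(inv$items$source)))
    stop("inventory is already augmented", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(inv$items)
  aug <- inv$items
  aug$source <- seq_len(n)
  recs <- lapply(seq_len(n), function(i) sample_transform_record(plan))
  inv$items <- rbind(inv$items, aug)
  inv$transforms <- c(inv$transforms, recs)
  inv$plan <- plan
  inv
}

#' Load one inventory item as an (size, size, 3) array in [0, 1]
#'
#' @param inv a `dataset_inventory`.
#' @param i item index.
#' @return numeric array.
#' @export
load_item <- function(inv, i) {
  img <- read_image_rgb(inv$items$path[i])
  if (!identical(dim(img)[1:2], c(inv$size, inv$size)))
    img <- cpp_resize_bilinear(img, inv$size, inv$size)
  rec <- inv$transforms[[i]]
  if (!is.null(rec)) img <- apply_transform_record(img, rec)
  img
}

#' k-fold cross-validation partitions
#'
#' Folds are drawn over the original images only; augmented variants are
#' assigned to the fold of their source and used for training only, so a
#' variant can never leak into a different fold than its original. Fold
#' sizes differ by at most one; their union is the full original set.
#'
#' @param inv a `dataset_inventory`.
#' @param folds number of folds (default 5).
#' @param seed shuffle seed.
#' @return list of `folds` entries, each `list(train, test)` of item
#'   indices (train includes augmented variants).
#' @export
kfold_split <- function(inv, folds = 5L, seed = 1L) {
  if (folds < 2L) stop("invalid-config: folds must be >= 2", call. = FALSE)
  orig <- which(is.na(inv$items$source))
  if (length(orig) < folds)
    stop("fewer items than folds", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(orig)
  fold_id <- integer(nrow(inv$items))
  fold_id[shuffled] <- rep_len(seq_len(folds), length(orig))
  vari <- which(!is.na(inv$items$source))
  fold_id[vari] <- fold_id[inv$items$source[vari]]
  lapply(seq_len(folds), function(f) {
    list(train = which(fold_id != f),
         test = intersect(which(fold_id == f), orig))
  })
}

#' Build a virtual inventory from per-class counts
#'
#' Creates a `dataset_inventory` whose items carry placeholder paths —
#' images are never read. Useful for augmentation and fold accounting over
#' published dataset inventories (e.g. [dfml_inventory()]) without the
#' images themselves.
#'
#' @param counts named integer vector (class name -> count).
#' @param size nominal image size.
#' @return a `dataset_inventory`.
#' @export
virtual_inventory <- function(counts, size = 224L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  classes <- sort(names(counts))
  items <- do.call(rbind, lapply(classes, function(cl)
    if (counts[[cl]] > 0)
      data.frame(path = sprintf("virtual://%s/%06d", cl,
                                seq_len(counts[[cl]])),
                 class = cl, stringsAsFactors = FALSE)))
  items$label <- match(items$class, classes)
  items$source <- NA_integer_
  structure(list(items = items, classes = classes, size = as.integer(size),
                 transforms = vector("list", nrow(items))),
            class = "dataset_inventory")
}

#' Serialize plans and specs as YAML
#'
#' @param x an `augmentation_plan`, `synthetic_spec` or `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_yaml_config <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_yaml_config
#' @export
read_yaml_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  # restore numeric vectors yaml may have split into lists
  obj <- lapply(obj, function(v) if (is.list(v)) unlist(v) else v)
  structure(obj, class = cls)
}
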