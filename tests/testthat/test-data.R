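# Synthetic generator, folder ingestion, augmentation accounting and k-fold
# splitting.

synth_root <- function(n = 4L, size = 64L, seed = 9L, ...) {
  root <- file.path(tempdir(), paste0("scmnet_t_", seed, "_", n, "_", size))
  if (!dir.exists(root))
    generate_synthetic_dataset(
      synthetic_spec(image_size = size, n_per_class = n, seed = seed, ...),
      root, write_masks = TRUE)
  root
}

test_that("the generator is byte-deterministic for identical spec + seed", {
  spec <- synthetic_spec(image_size = 64L, n_per_class = 3L, seed = 5L)
  r1 <- file.path(tempdir(), "det1"); r2 <- file.path(tempdir(), "det2")
  unlink(c(r1, r2), recursive = TRUE)
  generate_synthetic_dataset(spec, r1)
  generate_synthetic_dataset(spec, r2)
  f1 <- list.files(r1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(r2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(synthetic_spec(image_size = 32L), "invalid-spec")
  unlink(c(r1, r2), recursive = TRUE)
})

test_that("class archetypes differ morphologically: strands are more
           eccentric than hard clumps", {
  root <- synth_root(n = 15L, seed = 12L)
  ecc <- function(cl) {
    ms <- list.files(file.path(root, "masks", cl), full.names = TRUE)
    vapply(ms, function(p) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3) m <- m[, , 1]
      idx <- which(m > 0.5, arr.ind = TRUE)
      if (nrow(idx) < 10) return(1)
      ev <- eigen(stats::cov(idx), only.values = TRUE)$values
      sqrt(max(ev) / max(min(ev), 1e-9))
    }, 1)
  }
  expect_gt(mean(ecc("normal")), mean(ecc("lack_of_water")))
})

test_that("image folders load with correct counts, classes and sizes", {
  root <- synth_root(n = 4L)
  inv <- load_image_folder(root, 48L)
  expect_identical(unname(inventory_counts(inv)), rep(4L, 4))
  expect_identical(inv$classes,
                   c("diarrhea", "lack_of_water", "normal", "soft_stool"))
  img <- load_item(inv, 1L)
  expect_identical(dim(img), c(48L, 48L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_error(load_image_folder(file.path(tempdir(), "missing_root")),
               "does not exist")
  empty <- file.path(tempdir(), "emptyroot")
  dir.create(file.path(empty, "classA"), recursive = TRUE,
             showWarnings = FALSE)
  expect_error(suppressWarnings(load_image_folder(empty)), "no images")
})

test_that("augmentation appends exactly one variant per original and
           records reproducible transforms", {
  root <- synth_root(n = 3L)
  inv <- load_image_folder(root, 64L)
  aug <- augment_dataset(inv, augmentation_plan(), seed = 2L)
  expect_identical(nrow(aug$items), 2L * nrow(inv$items))
  expect_identical(unname(inventory_counts(aug)),
                   2L * unname(inventory_counts(inv)))
  # labels never change
  vari <- which(!is.na(aug$items$source))
  expect_identical(aug$items$label[vari],
                   aug$items$label[aug$items$source[vari]])
  # deterministic loading of a variant
  i <- vari[1]
  expect_identical(load_item(aug, i), load_item(aug, i))
  # a variant differs from its source (transforms actually applied)
  expect_gt(max(abs(load_item(aug, i) - load_item(aug, aug$items$source[i]))),
            0.005)
  expect_error(augment_dataset(aug), "already augmented")
  expect_error(augmentation_plan(blur_sigma_max = 0.6), "0.5")
  expect_error(augmentation_plan(variants_per_image = 2), "fixed at 1")
})

test_that("declared augmentation probabilities are hit within 5% over 2000
           draws", {
  plan <- augmentation_plan()
  set.seed(77)
  recs <- replicate(2000, scmnet:::sample_transform_record(plan),
                    simplify = FALSE)
  expect_lt(abs(mean(vapply(recs, function(r) r$blur > 0, TRUE)) - 0.5), 0.05)
  expect_lt(abs(mean(vapply(recs, function(r) r$noise_shared, TRUE)) - 0.5),
            0.05)
  expect_lt(abs(mean(vapply(recs, function(r) r$brightness != 0, TRUE)) - 0.2),
            0.05)
  sig <- vapply(recs, function(r) r$blur, 1)
  expect_true(all(sig >= 0 & sig <= 0.5))
  ctr <- vapply(recs, function(r) r$contrast, 1)
  expect_true(all(ctr >= 0.75 & ctr <= 1.25))
})

test_that("k-fold partitions are disjoint, covering, balanced and
           leakage-free", {
  root <- synth_root(n = 5L)
  inv <- augment_dataset(load_image_folder(root, 64L), seed = 3L)
  orig <- which(is.na(inv$items$source))
  sp <- kfold_split(inv, folds = 5L, seed = 4L)
  tests <- lapply(sp, `[[`, "test")
  expect_identical(sort(unlist(tests)), orig)            # cover, disjoint
  sizes <- lengths(tests)
  expect_lte(diff(range(sizes)), 1L)
  for (f in seq_along(sp)) {
    expect_length(intersect(sp[[f]]$train, tests[[f]]), 0L)
    # no augmented variant of a test item in this fold's training set
    vari_src <- inv$items$source[intersect(sp[[f]]$train,
                                           which(!is.na(inv$items$source)))]
    expect_length(intersect(vari_src, tests[[f]]), 0L)
  }
  expect_identical(kfold_split(inv, 5L, seed = 4L), sp)  # same seed, same cut
  expect_error(kfold_split(inv, 1L), "invalid-config")
  # 10 originals, 5 folds -> five test sets of 2
  inv2 <- load_image_folder(synth_root(n = 5L), 64L)
  inv2$items <- inv2$items[1:10, ]; inv2$transforms <- inv2$transforms[1:10]
  expect_identical(lengths(lapply(kfold_split(inv2, 5L, 1L), `[[`, "test")),
                   rep(2L, 5))
})

test_that("plans and specs round-trip through YAML", {
  p <- augmentation_plan(brightness_prob = 0.25)
  f <- tempfile(fileext = ".yaml")
  write_yaml_config(p, f)
  p2 <- read_yaml_config(f)
  expect_s3_class(p2, "augmentation_plan")
  expect_equal(unclass(p2)[order(names(unclass(p2)))],
               unclass(p)[order(names(unclass(p)))], tolerance = 1e-12)
  rc <- run_config(seed = 9L, epochs = 2L)
  write_yaml_config(rc, f)
  rc2 <- read_yaml_config(f)
  expect_identical(rc2$epochs, 2L)
  expect_identical(rc2$batch_size, rc$batch_size)
  unlink(f)
})
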