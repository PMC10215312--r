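# ---------------------------------------------------------------------------
# Deterministic synthetic 4-class fecal-image generator.
#
# Emulates the morphological contrasts of the four moisture-level classes
# over cluttered outdoor backgrounds so the whole pipeline can be exercised
# without any external data:
#   lack_of_water - cluster of hard-edged, near-spherical dark clumps
#   normal        - elongated segmented curved strand with visible gaps
#   soft_stool    - smooth irregular glossy blob with a specular highlight
#   diarrhea      - low-contrast diffuse amorphous stain
# Backgrounds carry leaf-, stone- and twig-like distractors plus smooth
# color variation and additive Gaussian noise. Identical spec + seed yields
# byte-identical files.
# ---------------------------------------------------------------------------

SYNTH_CLASSES <- c("diarrhea", "lack_of_water", "normal", "soft_stool")

#' Synthetic dataset specification
#'
#' @param image_size square image side in pixels (>= 64).
#' @param n_per_class images rendered per class.
#' @param distractor_density expected distractor count scale (1 = the
#'   default moderately cluttered scene; 0 disables distractors).
#' @param background_clutter_level amplitude of smooth background variation
#'   in [0, 1].
#' @param noise_sigma additive Gaussian pixel noise (fraction of dynamic
#'   range).
#' @param seed integer master seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 224L, n_per_class = 50L,
                           distractor_density = 1, background_clutter_level = 0.5,
                           noise_sigma = 0.03, seed = 1L) {
  if (image_size < 64) stop("invalid-spec: image_size must be >= 64",
                            call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 distractor_density = distractor_density,
                 background_clutter_level = background_clutter_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 classes = SYNTH_CLASSES),
            class = "synthetic_spec")
}

smoothstep <- function(x, e0, e1) {
  t <- pmin(pmax((x - e0) / (e1 - e0), 0), 1)
  t * t * (3 - 2 * t)
}

# smooth pseudo-random field from a few cosine waves, values roughly [-1,1]
cos_field <- function(xx, yy, waves = 4L, fmax = 6) {
  f <- 0
  for (i in seq_len(waves)) {
    fr <- stats::runif(2, 1, fmax)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.3, 1) * cos(2 * pi * (fr[1] * xx + fr[2] * yy) + ph)
  }
  f / waves
}

render_background <- function(xx, yy, clutter) {
  base <- c(0.52, 0.45, 0.35) + stats::runif(3, -0.05, 0.05)  # dry soil
  f <- cos_field(xx, yy)
  img <- array(0, c(dim(xx), 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] + clutter * 0.18 * f
  img
}

blend <- function(img, alpha, color) {
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - alpha) + color[ch] * alpha
  img
}

render_distractors <- function(img, xx, yy, density) {
  n <- stats::rpois(1, 3 * density)
  for (i in seq_len(n)) {
    kind <- sample(c("leaf", "stone", "twig"), 1)
    cx <- stats::runif(1, 0.05, 0.95); cy <- stats::runif(1, 0.05, 0.95)
    th <- stats::runif(1, 0, pi)
    u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    if (kind == "leaf") {
      a <- stats::runif(1, 0.04, 0.09); b <- a * stats::runif(1, 0.35, 0.55)
      d <- (u / a)^2 + (v / b)^2
      alpha <- 1 - smoothstep(d, 0.7, 1.1)
      col <- c(0.35, 0.42, 0.18) + stats::runif(3, -0.06, 0.06)
    } else if (kind == "stone") {
      a <- stats::runif(1, 0.03, 0.06); b <- a * stats::runif(1, 0.7, 1)
      d <- (u / a)^2 + (v / b)^2
      alpha <- 1 - smoothstep(d, 0.85, 1.0)
      col <- rep(stats::runif(1, 0.45, 0.65), 3)
    } else {
      len <- stats::runif(1, 0.1, 0.25); wid <- stats::runif(1, 0.004, 0.01)
      d <- pmax(abs(u) - len, 0)^2 + v^2
      alpha <- 1 - smoothstep(sqrt(d), wid * 0.6, wid * 1.6)
      col <- c(0.32, 0.24, 0.15) + stats::runif(3, -0.04, 0.04)
    }
    img <- blend(img, alpha, col)
  }
  img
}

# foreground alpha + color per class archetype; returns list(alpha, img)
render_foreground <- function(img, xx, yy, class_name) {
  alpha_total <- array(0, dim(xx))
  if (class_name == "lack_of_water") {
    ccx <- stats::runif(1, 0.35, 0.65); ccy <- stats::runif(1, 0.35, 0.65)
    nb <- sample(3:6, 1)
    col <- c(0.28, 0.19, 0.11) + stats::runif(3, -0.03, 0.03)
    for (i in seq_len(nb)) {
      cx <- ccx + stats::runif(1, -0.12, 0.12)
      cy <- ccy + stats::runif(1, -0.12, 0.12)
      rad <- stats::runif(1, 0.05, 0.09)
      d <- sqrt((xx - cx)^2 + (yy - cy)^2) / rad
      a <- 1 - smoothstep(d, 0.9, 1.02)             # hard edge
      shade <- 1 - 0.35 * smoothstep(d, 0.1, 0.95)  # convex shading
      img <- blend(img, a, col * 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + col[ch] * shade * a
      alpha_total <- pmax(alpha_total, a)
    }
  } else if (class_name == "normal") {
    # quadratic curve across the frame, thick strand with segment gaps
    p0 <- c(stats::runif(1, 0.15, 0.3), stats::runif(1, 0.2, 0.8))
    p2 <- c(stats::runif(1, 0.7, 0.85), stats::runif(1, 0.2, 0.8))
    p1 <- (p0 + p2) / 2 + stats::runif(2, -0.25, 0.25)
    ts <- seq(0, 1, length.out = 60)
    px <- (1 - ts)^2 * p0[1] + 2 * ts * (1 - ts) * p1[1] + ts^2 * p2[1]
    py <- (1 - ts)^2 * p0[2] + 2 * ts * (1 - ts) * p1[2] + ts^2 * p2[2]
    nseg <- sample(4:6, 1)
    width0 <- stats::runif(1, 0.035, 0.05)
    col <- c(0.42, 0.30, 0.17) + stats::runif(3, -0.03, 0.03)
    dmin <- array(Inf, dim(xx)); smin <- array(0, dim(xx))
    for (i in seq_along(ts)) {
      d <- sqrt((xx - px[i])^2 + (yy - py[i])^2)
      upd <- d < dmin
      smin[upd] <- ts[i]
      dmin[upd] <- d[upd]
    }
    wseg <- width0 * (0.62 + 0.38 * cos(2 * pi * smin * nseg))  # gaps
    a <- 1 - smoothstep(dmin / wseg, 0.75, 1.05)
    shade <- 1 - 0.3 * smoothstep(dmin / wseg, 0.0, 0.9)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + col[ch] * shade * a
    alpha_total <- pmax(alpha_total, a)
  } else if (class_name == "soft_stool") {
    ccx <- stats::runif(1, 0.38, 0.62); ccy <- stats::runif(1, 0.38, 0.62)
    col <- c(0.47, 0.33, 0.15) + stats::runif(3, -0.03, 0.03)
    field <- array(0, dim(xx))
    for (i in seq_len(sample(4:6, 1))) {
      cx <- ccx + stats::runif(1, -0.1, 0.1)
      cy <- ccy + stats::runif(1, -0.1, 0.1)
      a2 <- stats::runif(1, 0.06, 0.12); b2 <- stats::runif(1, 0.06, 0.12)
      th <- stats::runif(1, 0, pi)
      u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
      v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
      field <- field + exp(-((u / a2)^2 + (v / b2)^2))
    }
    a <- smoothstep(field, 0.35, 0.8)                       # smooth wide edge
    gl <- exp(-(((xx - ccx + 0.03)^2 + (yy - ccy - 0.03)^2) / 0.002))
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - a) +
        pmin(col[ch] + 0.45 * gl, 1) * a                    # glossy highlight
    alpha_total <- pmax(alpha_total, a)
  } else {  # diarrhea: diffuse low-contrast amorphous stain
    ccx <- stats::runif(1, 0.35, 0.65); ccy <- stats::runif(1, 0.35, 0.65)
    col <- c(0.45, 0.36, 0.16) + stats::runif(3, -0.04, 0.04)
    u <- xx - ccx; v <- yy - ccy
    r0 <- stats::runif(1, 0.16, 0.26)
    mod <- 1 + 0.35 * cos_field(xx, yy, waves = 3L, fmax = 4)
    d <- sqrt(u^2 + v^2) / (r0 * mod)
    a <- 0.55 * (1 - smoothstep(d, 0.3, 1.15))              # soft falloff
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + col[ch] * a
    alpha_total <- pmax(alpha_total, a / max(max(a), 1e-9))
  }
  list(img = img, alpha = alpha_total)
}

render_synthetic_image <- function(size, class_name, distractor_density,
                                   clutter, noise_sigma) {
  ax <- seq(0.5 / size, 1 - 0.5 / size, length.out = size)
  xx <- matrix(ax, size, size, byrow = TRUE)   # column coordinate
  yy <- matrix(ax, size, size)                 # row coordinate
  img <- render_background(xx, yy, clutter)
  img <- render_distractors(img, xx, yy, distractor_density)
  fg <- render_foreground(img, xx, yy, class_name)
  img <- fg$img
  img <- img + array(stats::rnorm(length(img), 0, noise_sigma), dim(img))
  list(img = pmin(pmax(img, 0), 1), mask = fg$alpha > 0.5)
}

#' Generate a synthetic class-per-directory image dataset
#'
#' Renders `n_per_class` PNG images per archetype under
#' `root/<class_name>/`, fully determined by the spec's seed. Optionally
#' writes binary foreground masks under `root/masks/<class_name>/`.
#'
#' @param spec a [synthetic_spec()].
#' @param root output directory (created if needed).
#' @param write_masks also write foreground masks (for localization tests).
#' @return (invisibly) a data.frame with path, class and mask path.
#' @export
generate_synthetic_dataset <- function(spec, root, write_masks = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[ci]
    dir.create(file.path(root, cl), showWarnings = FALSE)
    if (write_masks)
      dir.create(file.path(root, "masks", cl), recursive = TRUE,
                 showWarnings = FALSE)
    for (i in seq_len(spec$n_per_class)) {
      set.seed((spec$seed %% 100000L) * 10000L + ci * 1000L + i)
      r <- render_synthetic_image(spec$image_size, cl,
                                  spec$distractor_density,
                                  spec$background_clutter_level,
                                  spec$noise_sigma)
      path <- file.path(root, cl, sprintf("%s_%04d.png", cl, i))
      png::writePNG(r$img, path)
      mpath <- NA_character_
      if (write_masks) {
        mpath <- file.path(root, "masks", cl, sprintf("%s_%04d.png", cl, i))
        png::writePNG(r$mask * 1, mpath)
      }
      rows[[length(rows) + 1L]] <- data.frame(path = path, class = cl,
                                              mask = mpath,
                                              stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, rows))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
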