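# Deterministic synthetic imagery emulating desk-scale peppercorn data.
#
# Granules are disks with gentle radial shading and sinusoidal surface
# texture.  "Mature" granules are uniform red with a small Gaussian color
# jitter; "semi-mature" granules mix red and green hues through a smooth
# low-frequency mottle field plus a speckle term, so their grayscale
# surface is non-flat at exactly the spatial scales the vALD sorter
# measures.  Not photorealistic by design: the fixtures exercise the
# segmentation labels, the classifier's color separability, and the
# flat-mask behaviour with known ground truth.

MATURE_RGB <- c(0.78, 0.12, 0.10)
SEMI_GREEN_RGB <- c(0.35, 0.55, 0.15)

#' Specification of a synthetic cluster scene
#'
#' @param size Canvas edge in pixels (square).
#' @param n_granules Number of granules to place.
#' @param maturity_mix Fraction of granules drawn as mature.
#' @param radius_range Granule radius range in pixels.
#' @param jitter_sd Per-pixel color jitter of mature granules.
#' @param speckle_sd Per-pixel speckle of semi-mature granules.
#' @param mottle_scale Spatial scale (pixels) of the red/green mottle field.
#' @param background_noise Amplitude of the smooth background texture.
#' @param seed Seed fixing the whole scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = 192L, n_granules = 8L, maturity_mix = 0.5,
                       radius_range = c(14L, 22L), jitter_sd = 0.006,
                       speckle_sd = 0.04, mottle_scale = 8L,
                       background_noise = 0.04, seed = 1L) {
  stopifnot(maturity_mix >= 0, maturity_mix <= 1, all(radius_range > 0),
            size >= 2 * max(radius_range))
  structure(list(size = as.integer(size), n_granules = as.integer(n_granules),
                 maturity_mix = maturity_mix,
                 radius_range = as.integer(radius_range),
                 jitter_sd = jitter_sd, speckle_sd = speckle_sd,
                 mottle_scale = as.integer(mottle_scale),
                 background_noise = background_noise,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth low-frequency noise: coarse Gaussian grid, bilinear upsampling
smooth_noise <- function(H, W, scale) {
  gh <- max(2L, ceiling(H / scale) + 1L)
  gw <- max(2L, ceiling(W / scale) + 1L)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = H)
  rx <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(ry), gh - 1L); fx <- ry - y0
  x0 <- pmin(floor(rx), gw - 1L); fy <- rx - x0
  a <- g[y0, x0, drop = FALSE] * outer(1 - fx, 1 - fy) +
    g[y0 + 1L, x0, drop = FALSE] * outer(fx, 1 - fy) +
    g[y0, x0 + 1L, drop = FALSE] * outer(1 - fx, fy) +
    g[y0 + 1L, x0 + 1L, drop = FALSE] * outer(fx, fy)
  a
}

# paint one granule onto an (H, W, 3) canvas; returns the canvas
paint_granule <- function(canvas, cx, cy, r, class,
                          jitter_sd, speckle_sd, mottle_scale) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  ys <- pmax(1L, floor(cy - r)):pmin(H, ceiling(cy + r))
  xs <- pmax(1L, floor(cx - r)):pmin(W, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dist <- sqrt(dy^2 + dx^2)
  inside <- dist <= r
  if (!any(inside)) return(canvas)
  shade <- (1 - 0.12 * (dist / r)^2) *
    (1 + 0.02 * sin(2 * pi * 3 * dist / r))
  if (class == "mature") {
    for (ch in 1:3) {
      layer <- canvas[ys, xs, ch]
      val <- MATURE_RGB[ch] * shade +
        matrix(stats::rnorm(length(dist), 0, jitter_sd), nrow(dist))
      layer[inside] <- val[inside]
      canvas[ys, xs, ch] <- layer
    }
  } else {
    # centred per granule so mottle statistics are stationary across images
    f <- smooth_noise(length(ys), length(xs), mottle_scale)
    mix <- stats::plogis(3 * (f - mean(f)))
    for (ch in 1:3) {
      layer <- canvas[ys, xs, ch]
      base <- mix * MATURE_RGB[ch] + (1 - mix) * SEMI_GREEN_RGB[ch]
      val <- base * shade +
        matrix(stats::rnorm(length(dist), 0, speckle_sd), nrow(dist))
      layer[inside] <- val[inside]
      canvas[ys, xs, ch] <- layer
    }
  }
  canvas
}

#' Generate a synthetic cluster scene with granule-level polygon labels
#'
#' Renders overlapping circular granules of the two maturity classes on a
#' textured background.  Identical seeds give identical pixel values and
#' labels.
#'
#' @param spec A [scene_spec()].
#' @return List: `image` (`size x size x 3`, values in `[0, 1]`),
#'   `labels` (one 16-vertex normalized polygon matrix per granule),
#'   `classes` (character), `class_index` (0 = mature, 1 = semi-mature).
#' @export
generate_cluster_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  S <- spec$size
  canvas <- array(0, c(S, S, 3))
  bg <- c(0.32, 0.24, 0.16)
  tex <- smooth_noise(S, S, 16L) * spec$background_noise
  for (ch in 1:3)
    canvas[, , ch] <- bg[ch] + tex + stats::rnorm(S * S, 0, 0.01)
  n <- spec$n_granules
  radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  centers <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      cx <- stats::runif(1, radii[i] + 1, S - radii[i] - 1)
      cy <- stats::runif(1, radii[i] + 1, S - radii[i] - 1)
      ok <- TRUE
      if (i > 1L) for (j in seq_len(i - 1L)) {
        if (sqrt((cx - centers[j, 1])^2 + (cy - centers[j, 2])^2) <
            0.75 * (radii[i] + radii[j])) { ok <- FALSE; break }
      }
      if (ok) { centers[i, ] <- c(cx, cy); placed <- TRUE; break }
    }
    if (!placed)
      stop("generate_cluster_scene: could not pack granules after bounded retries")
  }
  n_mature <- round(spec$maturity_mix * n)
  classes <- c(rep("mature", n_mature), rep("semi-mature", n - n_mature))
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    canvas <- paint_granule(canvas, centers[i, 1], centers[i, 2], radii[i],
                            classes[i], spec$jitter_sd, spec$speckle_sd,
                            spec$mottle_scale)
    th <- seq(0, 2 * pi, length.out = 17L)[-17L]
    labels[[i]] <- cbind((centers[i, 1] + radii[i] * cos(th)) / S,
                         (centers[i, 2] + radii[i] * sin(th)) / S)
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  list(image = canvas, labels = labels, classes = classes,
       class_index = as.integer(classes != "mature"))
}

# one granule filling a square crop on a black background
granule_crop <- function(size, class, jitter_sd = 0.006, speckle_sd = 0.04,
                         mottle_scale = 8L) {
  canvas <- array(0, c(size, size, 3))
  r <- 0.42 * size * stats::runif(1, 0.92, 1.05)
  cx <- size / 2 + stats::runif(1, -1, 1)
  cy <- size / 2 + stats::runif(1, -1, 1)
  pmin(pmax(paint_granule(canvas, cx, cy, min(r, size / 2 - 1), class,
                          jitter_sd, speckle_sd, mottle_scale), 0), 1)
}

#' Generate an in-memory two-class granule-crop dataset
#'
#' Balanced mature / semi-mature crops with a train/validation split, in
#' the array form [train_smoke()] consumes.
#'
#' @param n_per_class Images per class.
#' @param size Crop edge in pixels.
#' @param split Training fraction.
#' @param seed Seed.
#' @return List `train`/`val`, each `list(x, y)` with `x` an
#'   `(size, size, 3, N)` array and `y` integer labels (1 = mature,
#'   2 = semi-mature), plus `classes`.
#' @export
generate_cls_data <- function(n_per_class = 200L, size = 64L, split = 0.8,
                              seed = 0L) {
  stopifnot(n_per_class >= 1L, split > 0, split <= 1)
  set.seed(seed)
  classes <- c("mature", "semi-mature")
  imgs <- list(); labs <- integer(0)
  for (k in 1:2)
    for (i in seq_len(n_per_class)) {
      imgs[[length(imgs) + 1L]] <- granule_crop(size, classes[k])
      labs <- c(labs, k)
    }
  ntr_per <- round(split * n_per_class)
  tr_idx <- c(seq_len(ntr_per), n_per_class + seq_len(ntr_per))
  va_idx <- setdiff(seq_along(labs), tr_idx)
  pack <- function(idx) {
    x <- array(0, c(size, size, 3L, length(idx)))
    for (i in seq_along(idx)) x[, , , i] <- imgs[[idx[i]]]
    list(x = x, y = labs[idx])
  }
  list(train = pack(tr_idx), val = pack(va_idx), classes = classes)
}

#' Write a class-foldered granule-crop dataset to disk
#'
#' Layout: `train/<class>/`, `val/<class>/` PNG folders at the requested
#' split ratio.  Identical seeds give identical file lists and bytes.
#'
#' @inheritParams generate_cls_data
#' @param dir Destination directory (created if missing).
#' @return Invisibly, a data frame manifest (path, split, class).
#' @export
generate_cls_dataset <- function(dir, n_per_class = 200L, size = 64L,
                                 split = 0.8, seed = 0L) {
  ds <- generate_cls_data(n_per_class, size, split, seed)
  manifest <- NULL
  for (part in c("train", "val")) {
    d <- ds[[part]]
    for (i in seq_along(d$y)) {
      cls <- gsub("-", "_", ds$classes[d$y[i]])
      sub <- file.path(dir, part, cls)
      if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
      path <- file.path(sub, sprintf("%s_%04d.png", cls, i))
      png::writePNG(aperm(d$x[, , , i], c(1, 2, 3)), path)
      manifest <- rbind(manifest,
                        data.frame(path = path, split = part, class = cls))
    }
  }
  invisible(manifest)
}

#' Load a class-foldered dataset written by [generate_cls_dataset()]
#'
#' @param dir Dataset root containing `train/` and `val/` class folders.
#' @return The same structure as [generate_cls_data()].
#' @export
load_cls_dataset <- function(dir) {
  read_part <- function(part) {
    root <- file.path(dir, part)
    if (!dir.exists(root)) stop(sprintf("missing split folder '%s'", part))
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    xs <- list(); ys <- integer(0)
    for (k in seq_along(classes)) {
      files <- sort(list.files(file.path(root, classes[k]),
                               pattern = "\\.png$", full.names = TRUE))
      for (f in files) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
        xs[[length(xs) + 1L]] <- img[, , 1:3]
        ys <- c(ys, k)
      }
    }
    if (length(xs) == 0L) stop("load_cls_dataset: no images found")
    d <- dim(xs[[1]])
    x <- array(0, c(d[1], d[2], 3L, length(xs)))
    for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
    list(x = x, y = ys, classes = classes)
  }
  tr <- read_part("train"); va <- read_part("val")
  list(train = tr[c("x", "y")], val = va[c("x", "y")], classes = tr$classes)
}
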