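# High-quality granule sorting by average local pixel value difference.
#
# A granule crop is converted to grayscale; each pixel's absolute deviation
# from its 3x3 neighbourhood mean (vALD) is compared to 10% of the image's
# global average absolute deviation (GAD); pixels at or below the threshold
# are flat (white), the rest non-flat (black).  A granule is accepted as
# high quality when the black (non-flat) pixels are both few overall and
# not scattered across many sliding windows.

#' Sorting configuration
#'
#' Thresholds of the flat-region sorter.  The flat fraction (10%) is the
#' method's stated rule; the window and black-proportion thresholds are
#' operating points calibrated on the synthetic fixtures.
#'
#' @param flat_fraction Fraction of GAD below which a pixel is flat.
#' @param window,stride Sliding-window size and step in pixels (defaults
#'   are disjoint 16-pixel tiles).
#' @param window_black_thresh A window "fails" when its black proportion
#'   exceeds this.
#' @param scatter_thresh Maximum tolerated fraction of failing windows.
#' @param global_thresh Maximum tolerated global black proportion.
#' @param include_center Whether the 3x3 neighbourhood mean includes the
#'   center pixel (the default reading) or only the 8 neighbours.
#' @param measure `"vald"` (compare the local difference to the threshold;
#'   matches the method's name) or `"global_diff"` (compare each pixel's
#'   deviation from the global mean instead).
#' @param both_views For front/back cluster pairs: require both views to
#'   accept (conservative fusion).
#' @return An object of class `sorting_config`.
#' @export
sorting_config <- function(flat_fraction = 0.10, window = 16L, stride = 16L,
                           window_black_thresh = 0.5, scatter_thresh = 0.25,
                           global_thresh = 0.25, include_center = TRUE,
                           measure = c("vald", "global_diff"),
                           both_views = TRUE) {
  measure <- match.arg(measure)
  for (v in c(flat_fraction, window_black_thresh, scatter_thresh,
              global_thresh))
    if (v < 0 || v > 1) stop("sorting_config: thresholds must lie in [0, 1]")
  if (window < 1L) stop("sorting_config: window size must be >= 1")
  structure(list(flat_fraction = flat_fraction, window = as.integer(window),
                 stride = as.integer(stride),
                 window_black_thresh = window_black_thresh,
                 scatter_thresh = scatter_thresh,
                 global_thresh = global_thresh,
                 include_center = include_center, measure = measure,
                 both_views = both_views),
            class = "sorting_config")
}

#' Convert an RGB image to an 8-bit-range grayscale matrix
#'
#' Standard luma weights 0.299/0.587/0.114.  Inputs in `[0, 1]` are scaled
#' to the 0-255 range.
#'
#' @param img `(H, W, 3)` array, or an already-gray matrix (returned
#'   rescaled only).
#' @return `H x W` numeric matrix with values in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  if (max(g) <= 1) g <- g * 255
  g
}

#' Average local pixel value difference and global deviation
#'
#' `vald(p) = |img(p) - mean(3x3 neighbourhood of p)|` with replicate
#' border padding; `gad` is the mean over all pixels of
#' `|img(p) - mean(img)|`.
#'
#' @param img Grayscale matrix (values 0-255).
#' @param include_center Include the center pixel in the neighbourhood mean
#'   (uniform 1/9 kernel) or use the 8 neighbours only.
#' @return Object of class `flat_stats`: list with `vald` (matrix) and
#'   `gad` (scalar).
#' @export
compute_vald <- function(img, include_center = TRUE) {
  if (!is.matrix(img) || length(img) == 0L)
    stop("compute_vald: need a nonempty grayscale matrix")
  H <- nrow(img); W <- ncol(img)
  pad <- img[c(1L, seq_len(H), H), c(1L, seq_len(W), W), drop = FALSE]
  acc <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + seq_len(H), dj + seq_len(W), drop = FALSE]
  if (include_center) {
    nbmean <- acc / 9
  } else {
    nbmean <- (acc - img) / 8
  }
  structure(list(vald = abs(img - nbmean),
                 gad = mean(abs(img - mean(img)))),
            class = "flat_stats")
}

#' Mark flat regions of a grayscale image
#'
#' A pixel is marked white (255, flat) iff its difference measure is at or
#' below `flat_fraction * gad`; black (0) otherwise.  The `<=` rule makes a
#' perfectly uniform image (gad = 0) fully flat.
#'
#' @param img Grayscale matrix.
#' @param flat_fraction Threshold fraction of the global deviation.
#' @inheritParams compute_vald
#' @param measure `"vald"` or `"global_diff"` (see [sorting_config()]).
#' @return Object of class `flat_mask`: `H x W` matrix of 0/255.
#' @export
mark_flat_regions <- function(img, flat_fraction = 0.10,
                              include_center = TRUE,
                              measure = c("vald", "global_diff")) {
  measure <- match.arg(measure)
  if (flat_fraction < 0 || flat_fraction > 1)
    stop("mark_flat_regions: flat_fraction must lie in [0, 1]")
  st <- compute_vald(img, include_center)
  diffmap <- if (measure == "vald") st$vald else abs(img - mean(img))
  mask <- ifelse(diffmap <= flat_fraction * st$gad, 255, 0)
  structure(mask, class = c("flat_mask", class(mask)))
}

#' Sliding-window black-pixel statistics of a flat mask
#'
#' @param mask A `flat_mask` (or 0/255 matrix).
#' @param config A [sorting_config()].
#' @return List: `global_black` (proportion over the whole image),
#'   `window_props` (per-window black proportions over the sliding grid),
#'   `max_window`, and `scattered_fraction` (share of windows whose black
#'   proportion exceeds `window_black_thresh`).
#' @export
assess_flat_mask <- function(mask, config = sorting_config()) {
  m <- unclass(mask)
  H <- nrow(m); W <- ncol(m)
  win <- config$window; stride <- config$stride
  if (win > H || win > W)
    stop("assess_flat_mask: window larger than the image")
  black <- m == 0
  rows <- seq(1L, H - win + 1L, by = stride)
  cols <- seq(1L, W - win + 1L, by = stride)
  props <- matrix(0, length(rows), length(cols))
  for (i in seq_along(rows)) for (j in seq_along(cols))
    props[i, j] <- mean(black[rows[i] + 0:(win - 1L), cols[j] + 0:(win - 1L)])
  list(global_black = mean(black),
       window_props = props,
       max_window = max(props),
       scattered_fraction = mean(props > config$window_black_thresh))
}

#' Accept or reject a granule from its flat mask
#'
#' Accept iff the global black proportion and the scattered-window fraction
#' are both at or below their thresholds (ties accept).  The decision is
#' monotone: blackening any pixel can only move a verdict towards
#' rejection.
#'
#' @param mask A `flat_mask`.
#' @param config A [sorting_config()].
#' @param maturity Maturity class carried into the verdict
#'   (`"mature"`/`"semi-mature"`).
#' @return Object of class `sorting_verdict`.
#' @export
select_high_quality <- function(mask, config = sorting_config(),
                                maturity = "mature") {
  st <- assess_flat_mask(mask, config)
  reason <- "ok"
  if (st$global_black > config$global_thresh) {
    reason <- "global_black_proportion"
  } else if (st$scattered_fraction > config$scatter_thresh) {
    reason <- "scattered_windows"
  }
  structure(list(maturity = maturity,
                 global_black = st$global_black,
                 max_window = st$max_window,
                 scattered_fraction = st$scattered_fraction,
                 decision = if (reason == "ok") "high-quality" else "rejected",
                 reason = reason),
            class = "sorting_verdict")
}

#' @export
print.sorting_verdict <- function(x, ...) {
  cat(sprintf("%s granule: %s (black %.3f, max window %.3f, scattered %.3f%s)\n",
              x$maturity, x$decision, x$global_black, x$max_window,
              x$scattered_fraction,
              if (x$reason == "ok") "" else paste0("; reason: ", x$reason)))
  invisible(x)
}

#' Sort one granule image
#'
#' Grayscale conversion, flat-region marking and the accept/reject
#' decision in one step.
#'
#' @param img `(H, W, 3)` RGB array (values in `[0, 1]` or 0-255) or a
#'   grayscale matrix.
#' @param config A [sorting_config()].
#' @param maturity Maturity class label carried into the verdict.
#' @return A `sorting_verdict`.  The flat mask is attached as attribute
#'   `"mask"`.
#' @export
sort_granule <- function(img, config = sorting_config(),
                         maturity = "mature") {
  g <- to_grayscale(img)
  mask <- mark_flat_regions(g, config$flat_fraction, config$include_center,
                            config$measure)
  v <- select_high_quality(mask, config, maturity)
  attr(v, "mask") <- mask
  v
}

#' Sort a front/back view pair of one cluster
#'
#' Conservative fusion: the cluster is accepted only when both views'
#' verdicts accept (configurable via `config$both_views`; otherwise one
#' accepting view suffices).
#'
#' @param front,back RGB arrays or grayscale matrices of the two views.
#' @param config A [sorting_config()].
#' @param maturity Maturity class label.
#' @return List with the two per-view verdicts and the fused `decision`.
#' @export
sort_cluster_pair <- function(front, back, config = sorting_config(),
                              maturity = "mature") {
  vf <- sort_granule(front, config, maturity)
  vb <- sort_granule(back, config, maturity)
  ok_f <- vf$decision == "high-quality"
  ok_b <- vb$decision == "high-quality"
  ok <- if (config$both_views) ok_f && ok_b else ok_f || ok_b
  list(front = vf, back = vb,
       decision = if (ok) "high-quality" else "rejected")
}
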