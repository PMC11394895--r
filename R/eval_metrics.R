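# Evaluation metrics: convolution GFLOPs, precision/recall, mAP50, FPS.

#' GFLOPs of one convolution layer
#'
#' `X * Y * Cout * ((Cin / groups) * kh * kw + 1) / 1e9` — the
#' multiply-accumulate count of a dense convolution (the `+ 1` is the bias
#' add per output element).  For whole models use [model_gflops()], which
#' traces per-layer spatial sizes through the strides.
#'
#' @param X,Y Output width and height in pixels.
#' @param cin,cout Input and output channel counts.
#' @param k Kernel side (scalar) or `c(kh, kw)`.
#' @param groups Convolution groups (depthwise = `cin`).
#' @return Giga-operations (numeric scalar).
#' @examples
#' conv_gflops(640, 640, 3, 16, 3)  # 0.1835008
#' @export
conv_gflops <- function(X, Y, cin, cout, k, groups = 1L) {
  stopifnot(X >= 0, Y >= 0, cin >= 0, cout >= 0, all(k >= 0))
  k <- rep(k, length.out = 2L)
  X * Y * cout * ((cin / groups) * k[1] * k[2] + 1) / 1e9
}

#' Per-layer and total GFLOPs of an assembled model
#'
#' Runs one traced forward pass on a zero image of the configured input
#' size and applies the convolution cost formula to every convolution and
#' affine layer encountered.
#'
#' @param model A `pepper_model`.
#' @param input_size Square input edge (defaults to the configured size).
#' @return Data frame of per-layer costs with attribute `"total"` (GFLOPs).
#' @export
model_gflops <- function(model, input_size = NULL) {
  stopifnot(inherits(model, "pepper_model"))
  size <- as.integer(input_size %||% model$config$input_size)
  ctx <- new_ctx(training = FALSE, trace = TRUE)
  x <- ag_node(ctx$tape, array(0, c(size, size, 3L, 1L)))
  if (model$config$task == "classification") cls_forward_node(model, ctx, x)
  else seg_forward_node(model, ctx, x)
  tab <- do.call(rbind, ctx$tape$trace)
  tab$gflops <- mapply(function(X, Y, ci, co, kh, kw, g)
    conv_gflops(X, Y, ci, co, c(kh, kw), g),
    tab$X, tab$Y, tab$Cin, tab$Cout, tab$kh, tab$kw, tab$groups)
  attr(tab, "total") <- sum(tab$gflops)
  tab
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.  A zero
#' denominator is an explicit error naming the undefined metric.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named list `precision`, `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) stop("precision undefined: TP + FP = 0")
  if (tp + fn == 0) stop("recall undefined: TP + FN = 0")
  list(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

#' Frames per second from inference durations
#'
#' `1 / mean(durations)`.
#'
#' @param durations Positive per-image inference times in seconds.
#' @return FPS (numeric scalar).
#' @export
fps_from_times <- function(durations) {
  if (length(durations) == 0L) stop("fps_from_times: empty timing record")
  if (any(durations <= 0)) stop("fps_from_times: durations must be positive")
  1 / mean(durations)
}

#' Mean average precision at IoU 0.5
#'
#' Per class, predictions are ranked by confidence (ties broken stably in
#' input order), matched greedily to unmatched same-image ground truths at
#' IoU >= `iou`, and the precision-recall curve is integrated with
#' all-points interpolation.  Classes without ground truth are excluded
#' from the mean with a warning.
#'
#' @param pred Data frame with columns `image`, `class`, `conf` and (for
#'   `shape = "box"`) `x1, y1, x2, y2`.
#' @param truth Data frame with columns `image`, `class` and box columns
#'   for `shape = "box"`.
#' @param pred_shapes,truth_shapes For `shape = "polygon"` or `"mask"`:
#'   lists (aligned with the data frame rows) of normalized `n x 2` vertex
#'   matrices or logical mask matrices.
#' @param shape `"box"`, `"polygon"` or `"mask"`; polygon IoU is computed
#'   on masks rasterized at `mask_dim`.
#' @param iou IoU match threshold.
#' @param mask_dim Rasterization grid `c(H, W)` for polygon IoU.
#' @return mAP50 (numeric scalar), with per-class APs as attribute `"ap"`.
#' @export
map50 <- function(pred, truth, pred_shapes = NULL, truth_shapes = NULL,
                  shape = c("box", "polygon", "mask"), iou = 0.5,
                  mask_dim = c(64L, 64L)) {
  shape <- match.arg(shape)
  if (nrow(truth) == 0L) stop("map50: need at least one ground truth")
  if (shape == "polygon") {
    pred_shapes <- lapply(pred_shapes, rasterize_polygon,
                          H = mask_dim[1], W = mask_dim[2])
    truth_shapes <- lapply(truth_shapes, rasterize_polygon,
                           H = mask_dim[1], W = mask_dim[2])
    shape <- "mask"
  }
  classes <- sort(unique(truth$class))
  all_classes <- sort(unique(c(truth$class, pred$class)))
  if (length(setdiff(all_classes, classes)))
    warning("map50: classes without ground truth excluded from the mean: ",
            paste(setdiff(all_classes, classes), collapse = ", "))
  aps <- vapply(classes, function(cl) {
    t_idx <- which(truth$class == cl)
    p_idx <- which(pred$class == cl)
    n_gt <- length(t_idx)
    if (length(p_idx) == 0L) return(0)
    ord <- p_idx[order(-pred$conf[p_idx])]
    matched <- logical(n_gt)
    tp <- fp <- numeric(length(ord))
    for (r in seq_along(ord)) {
      i <- ord[r]
      cand <- t_idx[truth$image[t_idx] == pred$image[i] & !matched]
      best_iou <- 0; best <- NA_integer_
      for (j in cand) {
        v <- if (shape == "box")
          box_iou(as.numeric(pred[i, c("x1", "y1", "x2", "y2")]),
                  as.numeric(truth[j, c("x1", "y1", "x2", "y2")]))
        else mask_iou(pred_shapes[[i]], truth_shapes[[j]])
        if (v > best_iou) { best_iou <- v; best <- j }
      }
      if (!is.na(best) && best_iou >= iou) {
        tp[r] <- 1
        matched[match(best, t_idx)] <- TRUE
      } else fp[r] <- 1
    }
    ap_allpoints(tp, fp, n_gt)
  }, 0)
  structure(mean(aps), ap = stats::setNames(aps, classes))
}

# all-points interpolated average precision from ranked TP/FP indicators
ap_allpoints <- function(tp, fp, n_gt) {
  rec <- cumsum(tp) / n_gt
  prec <- cumsum(tp) / pmax(cumsum(tp) + cumsum(fp), 1e-12)
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

#' Rasterize a normalized polygon onto a pixel grid
#'
#' Even-odd (crossing-number) test at pixel centers.
#'
#' @param poly `n x 2` matrix of normalized `(x, y)` vertices.
#' @param H,W Grid size.
#' @return `H x W` logical matrix.
#' @export
rasterize_polygon <- function(poly, H, W) {
  if (is.matrix(poly) && nrow(poly) >= 3L) {
    cx <- (rep(seq_len(W), each = H) - 0.5) / W
    cy <- (rep(seq_len(H), times = W) - 0.5) / H
    inside <- rep(FALSE, H * W)
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      crosses <- ((yi > cy) != (yj > cy)) &
        (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    matrix(inside, H, W)
  } else matrix(FALSE, H, W)
}

mask_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}
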