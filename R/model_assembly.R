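# Assembly of the MultiDomain YOLOv8-style networks.
#
# The classification network is a staged backbone (stem + per-stage
# downsample and feature block) with MS-DFFM inserted after the shallow
# stages and MSF3M after the deepest stage, followed by global average
# pooling and an affine classifier.  The segmentation network shares the
# backbone, adds SPPELAN at the top, an upsampling neck (deep Fourier
# up-sampling by default, nearest-neighbour as the reference comparator)
# and a prototype-mask head in the YOLO-seg convention.

#' Model configuration
#'
#' Captures the architecture switches and the training hyperparameter
#' defaults (epochs 300, batch size 16, SGD, patience 50, no pretraining,
#' weight decay 5e-4, 4 workers, lr0 0.01, lrf 0.01, momentum 0.937).
#' Stage widths default to the nano-scale convention: base widths
#' `c(64, 128, 256, 512, 1024)` scaled by `width_multiple`; pass `widths`
#' directly for scaled-down experiments.
#'
#' @param task `"classification"` or `"segmentation"`.
#' @param nc Number of classes (>= 1).
#' @param input_size Square input edge in pixels.
#' @param width_multiple,depth_multiple Channel / block-repeat multipliers.
#' @param widths Integer vector of stem + stage widths (overrides the
#'   multiplier-derived defaults).  `length(widths) - 1` stages are built.
#' @param use_repncspelan4,use_adown,use_c2fse,use_sppelan,use_fourier_upsample
#'   Block catalog toggles.  The GELAN-family blocks default on for
#'   segmentation (the backbone that carries them) and off for
#'   classification, whose base is the plain YOLOv8-cls layout plus the two
#'   fusion modules.
#' @param msdffm_stages Stages after whose feature block MS-DFFM is
#'   inserted (default: stages 1-2, the shallow network).
#' @param msf3m_stages Stages receiving MSF3M (default: the deepest stage).
#' @param nm Number of mask-prototype coefficients (segmentation).
#' @param conf_thresh,mask_thresh Decode thresholds for segmentation.
#' @param epochs,batch_size,optimizer,patience,pretrained,weight_decay,workers,lr0,lrf,momentum
#'   Training defaults.
#' @param seed Integer seed fixing parameter initialization and training
#'   shuffles.
#' @return An object of class `pepper_config`.
#' @export
model_config <- function(task = c("classification", "segmentation"),
                         nc = 2L, input_size = 640L,
                         width_multiple = 0.25, depth_multiple = 0.33,
                         widths = NULL,
                         use_repncspelan4 = (task == "segmentation"),
                         use_adown = (task == "segmentation"),
                         use_c2fse = (task == "segmentation"),
                         use_sppelan = (task == "segmentation"),
                         use_fourier_upsample = TRUE,
                         msdffm_stages = NULL, msf3m_stages = NULL,
                         nm = 8L, conf_thresh = 0.25, mask_thresh = 0.5,
                         epochs = 300L, batch_size = 16L, optimizer = "SGD",
                         patience = 50L, pretrained = FALSE,
                         weight_decay = 5e-4, workers = 4L,
                         lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                         seed = 0L) {
  task <- match.arg(task)
  if (nc < 1L) stop("model_config: class count must be >= 1")
  if (width_multiple <= 0 || depth_multiple <= 0)
    stop("model_config: multipliers must be positive")
  if (is.null(widths))
    widths <- pmax(4L, as.integer(round(c(64, 128, 256, 512, 1024) *
                                          width_multiple)))
  widths <- as.integer(widths)
  nstages <- length(widths) - 1L
  if (nstages < 1L) stop("model_config: need at least one stage")
  if (task == "segmentation" && nstages < 3L)
    stop("model_config: segmentation needs >= 3 stages")
  if (is.null(msdffm_stages)) msdffm_stages <- seq_len(min(2L, nstages))
  if (is.null(msf3m_stages)) msf3m_stages <- nstages
  for (s in c(msdffm_stages, msf3m_stages))
    if (s < 1L || s > nstages)
      stop(sprintf("model_config: insertion stage %d invalid for depth %d",
                   s, nstages))
  structure(list(
    task = task, nc = as.integer(nc), input_size = as.integer(input_size),
    width_multiple = width_multiple, depth_multiple = depth_multiple,
    widths = widths, nstages = nstages,
    n_repeat = max(1L, as.integer(round(3 * depth_multiple))),
    use_repncspelan4 = use_repncspelan4, use_adown = use_adown,
    use_c2fse = use_c2fse, use_sppelan = use_sppelan,
    use_fourier_upsample = use_fourier_upsample,
    msdffm_stages = as.integer(msdffm_stages),
    msf3m_stages = as.integer(msf3m_stages),
    nm = as.integer(nm), conf_thresh = conf_thresh,
    mask_thresh = mask_thresh,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    optimizer = optimizer, patience = as.integer(patience),
    pretrained = pretrained, weight_decay = weight_decay,
    workers = as.integer(workers), lr0 = lr0, lrf = lrf,
    momentum = momentum, seed = as.integer(seed)
  ), class = "pepper_config")
}

#' Build a MultiDomain network from a configuration
#'
#' Construction is deterministic given `config$seed`: identical seeds yield
#' bitwise-identical initial parameters.
#'
#' @param config A [model_config()] object.
#' @return An object of class `pepper_model` (an environment holding the
#'   block tree, its parameters and the configuration).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "pepper_config"))
  set.seed(config$seed)
  w <- config$widths
  ns <- config$nstages
  backbone <- list(list(type_tag = "stem", blk = nn_conv(3L, w[1], 3L, stride = 2L)))
  taps <- integer(ns)
  for (s in seq_len(ns)) {
    cin <- w[s]; cout <- w[s + 1L]
    down <- if (config$use_adown && s > 1L) nn_adown(cin, cout)
            else nn_conv(cin, cout, 3L, stride = 2L)
    backbone[[length(backbone) + 1L]] <- list(type_tag = "down", blk = down)
    feat <- if (s == 1L && config$use_repncspelan4)
      nn_repncspelan4(cout, cout, n = config$n_repeat)
    else nn_c2f(cout, cout, n = config$n_repeat,
                se = config$use_c2fse && s > 1L)
    backbone[[length(backbone) + 1L]] <- list(type_tag = "feat", blk = feat)
    if (config$task == "segmentation" && s == ns && config$use_sppelan)
      backbone[[length(backbone) + 1L]] <- list(type_tag = "sppelan",
                                                blk = nn_sppelan(cout, cout))
    if (s %in% config$msdffm_stages)
      backbone[[length(backbone) + 1L]] <- list(type_tag = "msdffm",
                                                blk = nn_msdffm(cout))
    if (s %in% config$msf3m_stages)
      backbone[[length(backbone) + 1L]] <- list(type_tag = "msf3m",
                                                blk = nn_msf3m(cout))
    taps[s] <- length(backbone)
  }
  blocks <- list(backbone = backbone)
  if (config$task == "classification") {
    # YOLOv8-cls style head: 1x1 conv (+BN+SiLU) -> GAP -> affine; the
    # batch norm here also sets the scale of the MSF3M product features
    hw <- max(2L * w[ns + 1L], as.integer(round(1280 * config$width_multiple)))
    blocks$head <- list(conv = nn_conv(w[ns + 1L], hw, 1L),
                        fc = nn_linear(hw, config$nc))
  } else {
    c5 <- w[ns + 1L]; c4 <- w[ns]; c3 <- w[ns - 1L]
    up <- function(ch) if (config$use_fourier_upsample) nn_fourier_up(ch)
                       else nn_upsample_nearest()
    blocks$neck <- list(
      up1 = up(c5),
      fuse1 = nn_c2f(c5 + c4, c4, n = config$n_repeat),
      up2 = up(c4),
      fuse2 = nn_c2f(c4 + c3, c3, n = config$n_repeat)
    )
    head_conv <- nn_conv(c3, c3, 3L)
    head_out <- nn_conv(c3, 4L + config$nc + config$nm, 1L,
                        act = "none", bn = FALSE, bias = TRUE)
    # detection-style prior: start class logits strongly negative so an
    # untrained model predicts nothing above the confidence threshold
    head_out$b$value[4L + seq_len(config$nc)] <- -4
    blocks$head <- list(conv = head_conv, out = head_out,
                        proto1 = nn_conv(c3, c3, 3L),
                        proto2 = nn_conv(c3, config$nm, 1L, act = "relu",
                                         bn = FALSE, bias = TRUE))
  }
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$blocks <- blocks
  model$taps <- taps
  model$params <- collect_params(blocks)
  class(model) <- "pepper_model"
  model
}

# forward through the backbone, returning every tagged block's output node
backbone_forward <- function(model, ctx, x) {
  outs <- vector("list", length(model$blocks$backbone))
  for (i in seq_along(model$blocks$backbone)) {
    x <- block_forward(model$blocks$backbone[[i]]$blk, ctx, x)
    outs[[i]] <- x
  }
  outs
}

# classification logits node (nc, N)
cls_forward_node <- function(model, ctx, x) {
  outs <- backbone_forward(model, ctx, x)
  h <- block_forward(model$blocks$head$conv, ctx, outs[[length(outs)]])
  ag_linear(ag_gap(h),
            ag_leaf(ctx$tape, model$blocks$head$fc$w),
            ag_leaf(ctx$tape, model$blocks$head$fc$b))
}

seg_forward_node <- function(model, ctx, x) {
  cfg <- model$config
  outs <- backbone_forward(model, ctx, x)
  p5 <- outs[[model$taps[cfg$nstages]]]
  p4 <- outs[[model$taps[cfg$nstages - 1L]]]
  p3 <- outs[[model$taps[cfg$nstages - 2L]]]
  nk <- model$blocks$neck
  n4 <- block_forward(nk$fuse1, ctx,
                      ag_concat_c(list(block_forward(nk$up1, ctx, p5), p4)))
  n3 <- block_forward(nk$fuse2, ctx,
                      ag_concat_c(list(block_forward(nk$up2, ctx, n4), p3)))
  hd <- model$blocks$head
  feat <- block_forward(hd$conv, ctx, n3)
  list(head = block_forward(hd$out, ctx, feat),
       protos = block_forward(hd$proto2, ctx,
                              block_forward(hd$proto1, ctx, n3)))
}

new_ctx <- function(training = FALSE, trace = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- ag_tape()
  ctx$training <- training
  if (trace) ctx$tape$trace <- list()
  ctx
}

#' Predict with an assembled model
#'
#' Classification returns an `N x nc` matrix of class probabilities (rows
#' sum to one).  Segmentation returns one element per image: a list with a
#' `detections` data frame (class, confidence, box), normalized `polygons`,
#' and binary `masks`; images with nothing above the confidence threshold
#' yield zero-row results.
#'
#' @param object A `pepper_model`.
#' @param x Image array `(H, W, 3, N)` (or `(H, W, 3)` for one image),
#'   values in `[0, 1]`.
#' @param ... Unused.
#' @return See description.
#' @export
predict.pepper_model <- function(object, x, ...) {
  g4 <- to4d(as_grid_array(x))
  ctx <- new_ctx(training = FALSE)
  xn <- ag_node(ctx$tape, g4$a)
  if (object$config$task == "classification") {
    logits <- cls_forward_node(object, ctx, xn)$value
    ex <- exp(sweep(logits, 2, apply(logits, 2, max)))
    t(sweep(ex, 2, colSums(ex), "/"))
  } else {
    out <- seg_forward_node(object, ctx, xn)
    decode_seg(object$config, out$head$value, out$protos$value,
               dim(g4$a)[1:2])
  }
}

# decode the dense segmentation head into per-instance predictions
decode_seg <- function(cfg, head, protos, img_hw) {
  N <- dim(head)[4]
  lapply(seq_len(N), function(n) {
    h <- head[, , , n, drop = FALSE]
    Hs <- dim(h)[1]; Ws <- dim(h)[2]
    cls_logit <- h[, , 4L + seq_len(cfg$nc), 1, drop = FALSE]
    probs <- 1 / (1 + exp(-cls_logit))
    conf <- apply(probs, c(1, 2), max)
    cls <- apply(probs, c(1, 2), which.max)
    keep <- which(conf > cfg$conf_thresh, arr.ind = TRUE)
    if (nrow(keep) == 0L) return(empty_seg_result())
    sig <- function(v) 1 / (1 + exp(-v))
    cand <- data.frame(
      row = keep[, 1], col = keep[, 2],
      conf = conf[keep], class = cls[keep] - 1L)
    cand$cx <- (cand$col - 1 + sig(h[cbind(keep, 2, 1)])) / Ws
    cand$cy <- (cand$row - 1 + sig(h[cbind(keep, 1, 1)])) / Hs
    cand$w <- sig(h[cbind(keep, 3, 1)])
    cand$h <- sig(h[cbind(keep, 4, 1)])
    cand <- cand[order(-cand$conf), , drop = FALSE]
    boxes <- cbind(cand$cx - cand$w / 2, cand$cy - cand$h / 2,
                   cand$cx + cand$w / 2, cand$cy + cand$h / 2)
    keep_idx <- nms_boxes(boxes, iou = 0.5)
    cand <- cand[keep_idx, , drop = FALSE]
    boxes <- boxes[keep_idx, , drop = FALSE]
    masks <- vector("list", nrow(cand))
    polys <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      co <- h[cand$row[i], cand$col[i], 4L + cfg$nc + seq_len(cfg$nm), 1]
      m <- 1 / (1 + exp(-apply(sweep(protos[, , , n, drop = FALSE], 3, co,
                                     "*"), c(1, 2), sum)))
      big <- m[rep(seq_len(Hs), each = img_hw[1] %/% Hs),
               rep(seq_len(Ws), each = img_hw[2] %/% Ws)]
      bin <- big > cfg$mask_thresh
      bin <- crop_mask_to_box(bin, boxes[i, ])
      masks[[i]] <- bin
      polys[[i]] <- mask_to_polygon(bin)
    }
    list(detections = data.frame(class = cand$class, conf = cand$conf,
                                 x1 = boxes[, 1], y1 = boxes[, 2],
                                 x2 = boxes[, 3], y2 = boxes[, 4]),
         polygons = polys, masks = masks)
  })
}

empty_seg_result <- function() {
  list(detections = data.frame(class = integer(0), conf = numeric(0),
                               x1 = numeric(0), y1 = numeric(0),
                               x2 = numeric(0), y2 = numeric(0)),
       polygons = list(), masks = list())
}

crop_mask_to_box <- function(mask, box) {
  H <- nrow(mask); W <- ncol(mask)
  rs <- pmin(pmax(floor(box[c(2, 4)] * H), 0), H)
  cs <- pmin(pmax(floor(box[c(1, 3)] * W), 0), W)
  out <- matrix(FALSE, H, W)
  if (rs[2] > rs[1] && cs[2] > cs[1])
    out[(rs[1] + 1):rs[2], (cs[1] + 1):cs[2]] <-
      mask[(rs[1] + 1):rs[2], (cs[1] + 1):cs[2]]
  out
}

# convex-hull polygon of a binary mask, normalized to [0, 1]
mask_to_polygon <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < 3L) return(matrix(numeric(0), 0, 2))
  xy <- cbind((px[, 2] - 0.5) / ncol(mask), (px[, 1] - 0.5) / nrow(mask))
  hull <- grDevices::chull(xy)
  xy[hull, , drop = FALSE]
}

nms_boxes <- function(boxes, iou = 0.5) {
  n <- nrow(boxes)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < n) for (j in (i + 1):n) {
      if (alive[j] && box_iou(boxes[i, ], boxes[j, ]) > iou) alive[j] <- FALSE
    }
  }
  which(keep)
}

box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Count learnable parameters
#'
#' @param model A `pepper_model`, a block, or any nested list of blocks.
#' @return Integer count of learnable scalars, with attribute `"MB"` (the
#'   count at 4 bytes per parameter, in megabytes).
#' @export
param_count <- function(model) {
  params <- if (inherits(model, "pepper_model")) model$params
            else collect_params(model)
  n <- sum(vapply(params, function(p) length(p$value), 0))
  structure(n, MB = n * 4 / 1e6)
}

#' @export
print.pepper_model <- function(x, ...) {
  n <- param_count(x)
  cat(sprintf("MultiDomain %s network: %d stages, widths [%s], %d parameters (%.3f MB)\n",
              x$config$task, x$config$nstages,
              paste(x$config$widths, collapse = ", "),
              as.integer(n), attr(n, "MB")))
  invisible(x)
}

#' Smoke-train a classification model with SGD
#'
#' Runs plain SGD (classical momentum, L2 weight decay, linear learning-rate
#' schedule from `lr0` to `lr0 * lrf`) with the configuration's training
#' defaults, early-stopping when the monitored validation accuracy fails to
#' improve for `patience` consecutive epochs.  The first `warmup_epochs`
#' ramp the learning rate per batch from zero and the momentum from 0.8 to
#' its configured value, the stabilisation the YOLO training stack applies
#' when training from scratch.  Single-threaded and deterministic for a
#' fixed seed.
#'
#' @param model A classification `pepper_model`.
#' @param dataset Either a directory produced by [generate_cls_dataset()]
#'   or a list `list(train = list(x, y), val = list(x, y))` with `x` an
#'   `(H, W, 3, N)` array and `y` an integer class vector (1-based).
#' @param epochs,patience,batch_size,lr0,lrf Overrides of the config values.
#' @param stop_acc Optional validation-accuracy target at which training
#'   halts early.
#' @param verbose Print one line per epoch.
#' @return A list with `history` (data frame: epoch, lr, train_loss,
#'   val_loss, val_acc), `best_acc`, and `epochs_run`.  The model's
#'   parameters are left at the best-validation-accuracy state.
#' @export
train_smoke <- function(model, dataset, epochs = NULL, patience = NULL,
                        batch_size = NULL, lr0 = NULL, lrf = NULL,
                        warmup_epochs = 3, stop_acc = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pepper_model"),
            model$config$task == "classification")
  if (is.character(dataset)) dataset <- load_cls_dataset(dataset)
  ntr <- length(dataset$train$y)
  if (ntr == 0L) stop("train_smoke: empty dataset")
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  patience <- patience %||% cfg$patience
  batch_size <- batch_size %||% cfg$batch_size
  lr0 <- lr0 %||% cfg$lr0
  lrf <- lrf %||% cfg$lrf
  set.seed(cfg$seed)
  params <- model$params
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- -Inf; stale <- 0L
  best_values <- NULL
  for (epoch in seq_len(epochs)) {
    lr <- if (epochs == 1L) lr0
          else lr0 * (1 - (epoch - 1) / (epochs - 1) * (1 - lrf))
    idx <- sample(ntr)
    losses <- numeric(0)
    nb <- ceiling(ntr / batch_size)
    warm_batches <- warmup_epochs * nb
    for (start in seq(1L, ntr, by = batch_size)) {
      bi <- (epoch - 1L) * nb + (start - 1L) %/% batch_size + 1L
      frac <- if (warm_batches > 0) min(1, bi / warm_batches) else 1
      lr_b <- lr * frac
      mom_b <- cfg$momentum + (0.8 - cfg$momentum) * (1 - frac)
      b <- idx[start:min(start + batch_size - 1L, ntr)]
      ctx <- new_ctx(training = TRUE)
      xb <- dataset$train$x[, , , b, drop = FALSE]
      logits <- cls_forward_node(model, ctx, ag_node(ctx$tape, xb))
      loss <- ag_cross_entropy(logits, dataset$train$y[b])
      ag_zero_grads(params)
      ag_backward(ctx$tape, loss)
      sgd_step(params, lr_b, mom_b, cfg$weight_decay)
      losses <- c(losses, loss$value)
    }
    ev <- evaluate_cls(model, dataset$val, batch_size)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses),
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %d  lr %.4g  train %.4f  val %.4f  acc %.3f",
                      epoch, lr, mean(losses), ev$loss, ev$acc))
    if (ev$acc > best) {
      best <- ev$acc; stale <- 0L
      best_values <- lapply(params, function(p) p$value)
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
    if (!is.null(stop_acc) && best >= stop_acc) break
  }
  if (!is.null(best_values))
    for (i in seq_along(params)) params[[i]]$value <- best_values[[i]]
  list(history = hist, best_acc = best, epochs_run = nrow(hist))
}

evaluate_cls <- function(model, split, batch_size = 16L) {
  n <- length(split$y)
  losses <- numeric(0); correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    b <- start:min(start + batch_size - 1L, n)
    ctx <- new_ctx(training = FALSE)
    logits <- cls_forward_node(model, ctx,
                               ag_node(ctx$tape,
                                       split$x[, , , b, drop = FALSE]))
    losses <- c(losses, ag_cross_entropy(logits, split$y[b])$value)
    correct <- correct + sum(apply(logits$value, 2, which.max) == split$y[b])
  }
  list(loss = mean(losses), acc = correct / n)
}

#' Save / load model weights
#'
#' Checkpoints are a serialized list of parameter arrays plus the sidecar
#' configuration; the format has no framework-specific content.
#'
#' @param model A `pepper_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   rebuilt `pepper_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value),
               bn = bn_states(model$blocks)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  for (i in seq_along(model$params)) model$params[[i]]$value <- ck$values[[i]]
  restore_bn_states(model$blocks, ck$bn)
  model
}

bn_states <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$state) && is.environment(x$state))
      return(list(list(mean = x$state$mean, var = x$state$var)))
    return(do.call(c, c(lapply(x, bn_states), list(list()))))
  }
  list()
}

restore_bn_states <- function(x, states, at = 1L) {
  if (is.list(x)) {
    if (!is.null(x$state) && is.environment(x$state)) {
      x$state$mean <- states[[at]]$mean
      x$state$var <- states[[at]]$var
      return(at + 1L)
    }
    for (el in x) at <- restore_bn_states(el, states, at)
  }
  at
}
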