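# Reverse-mode automatic differentiation on dense arrays.
#
# A tape records every operation of a forward pass; ag_backward() walks it in
# reverse, accumulating gradients into parent nodes and, for leaves bound to
# an ag_param, into the parameter's $grad slot.  Arrays use the package-wide
# (H, W, C, N) column-major layout; complex-valued nodes (spectra) store a
# complex array and carry gradients as dL/d(re) + 1i * dL/d(im).
#
# This engine is internal: it exists because the frequency-domain layers and
# the training harness need end-to-end gradients, and it only implements the
# operations those layers use.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ag_tape"
  e
}

ag_node <- function(tape, value, parents = list(), backfn = NULL,
                    param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  nd$tape <- tape
  class(nd) <- "ag_node"
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' @noRd
ag_param <- function(value, decay = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$mom <- NULL
  p$decay <- decay
  class(p) <- "ag_param"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_leaf <- function(tape, x) {
  if (inherits(x, "ag_param")) ag_node(tape, x$value, param = x) else ag_node(tape, x)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- p$value * 0
  invisible(params)
}

ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) nd$param$grad <- nd$param$grad + nd$grad
    if (is.null(nd$backfn)) next
    gs <- nd$backfn(nd)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

## ---- elementwise arithmetic -------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$tape, a$value + b$value, list(a, b),
          function(nd) list(nd$grad, nd$grad))
}

ag_mul <- function(a, b) {
  ag_node(a$tape, a$value * b$value, list(a, b),
          function(nd) list(nd$grad * nd$parents[[2]]$value,
                            nd$grad * nd$parents[[1]]$value))
}

ag_scale <- function(a, k) {
  ag_node(a$tape, a$value * k, list(a), function(nd) list(nd$grad * k))
}

## ---- activations ------------------------------------------------------------

ag_relu <- function(a) {
  ag_node(a$tape, pmax(a$value, 0), list(a),
          function(nd) list(nd$grad * (nd$parents[[1]]$value > 0)))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  nd <- ag_node(a$tape, s, list(a), NULL)
  nd$backfn <- function(nd) list(nd$grad * nd$value * (1 - nd$value))
  nd
}

ag_silu <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  nd <- ag_node(a$tape, a$value * s, list(a), NULL)
  nd$saved <- s
  nd$backfn <- function(nd) {
    x <- nd$parents[[1]]$value; s <- nd$saved
    list(nd$grad * (s + x * s * (1 - s)))
  }
  nd
}

# tanh-approximation GELU (the common neural-network form)
ag_gelu <- function(a) {
  x <- a$value
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  nd <- ag_node(a$tape, 0.5 * x * (1 + t), list(a), NULL)
  nd$saved <- t
  nd$backfn <- function(nd) {
    x <- nd$parents[[1]]$value; t <- nd$saved
    dt <- (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2)
    list(nd$grad * (0.5 * (1 + t) + 0.5 * x * dt))
  }
  nd
}

# hard sigmoid clamp((t + 3) / 6, 0, 1)
ag_hsigmoid <- function(a) {
  x <- a$value
  nd <- ag_node(a$tape, pmin(pmax((x + 3) / 6, 0), 1), list(a), NULL)
  nd$backfn <- function(nd) {
    x <- nd$parents[[1]]$value
    list(nd$grad * ((x > -3 & x < 3) / 6))
  }
  nd
}

ag_cos <- function(a) {
  ag_node(a$tape, cos(a$value), list(a),
          function(nd) list(-nd$grad * sin(nd$parents[[1]]$value)))
}

ag_sin <- function(a) {
  ag_node(a$tape, sin(a$value), list(a),
          function(nd) list(nd$grad * cos(nd$parents[[1]]$value)))
}

## ---- convolution and pooling ------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  xv <- x$value; wv <- w$value
  kh <- dim(wv)[1]; kw <- dim(wv)[2]
  if (is.null(pad)) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  bv <- if (is.null(b)) numeric(0) else b$value
  y <- conv2d_fwd_cpp(xv, dim(xv), wv, dim(wv), bv,
                      as.integer(stride), as.integer(pad[1]),
                      as.integer(pad[2]), as.integer(groups))
  if (!is.null(x$tape$trace)) {
    d <- dim(y)
    x$tape$trace[[length(x$tape$trace) + 1L]] <- data.frame(
      X = d[2], Y = d[1], Cin = dim(xv)[3], Cout = dim(wv)[4],
      kh = kh, kw = kw, groups = groups)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  nd <- ag_node(x$tape, y, parents, NULL)
  nd$backfn <- function(nd) {
    gr <- conv2d_bwd_cpp(nd$parents[[1]]$value, dim(nd$parents[[1]]$value),
                         nd$parents[[2]]$value, dim(nd$parents[[2]]$value),
                         nd$grad, dim(nd$value),
                         as.integer(stride), as.integer(pad[1]),
                         as.integer(pad[2]), as.integer(groups),
                         length(nd$parents) == 3L)
    if (length(nd$parents) == 3L) list(gr$gx, gr$gw, gr$gb)
    else list(gr$gx, gr$gw)
  }
  nd
}

ag_maxpool <- function(x, k, stride = k, pad = 0L) {
  r <- maxpool2d_fwd_cpp(x$value, dim(x$value), as.integer(k),
                         as.integer(stride), as.integer(pad))
  nd <- ag_node(x$tape, r$y, list(x), NULL)
  nd$saved <- r$arg
  nd$backfn <- function(nd)
    list(maxpool2d_bwd_cpp(nd$grad, nd$saved, dim(nd$parents[[1]]$value)))
  nd
}

ag_avgpool <- function(x, k, stride = k, pad = 0L) {
  y <- avgpool2d_fwd_cpp(x$value, dim(x$value), as.integer(k),
                         as.integer(stride), as.integer(pad))
  nd <- ag_node(x$tape, y, list(x), NULL)
  nd$backfn <- function(nd)
    list(avgpool2d_bwd_cpp(nd$grad, dim(nd$value), dim(nd$parents[[1]]$value),
                           as.integer(k), as.integer(stride), as.integer(pad)))
  nd
}

## ---- shape ops --------------------------------------------------------------

ag_concat_c <- function(xs) {
  vals <- lapply(xs, `[[`, "value")
  d <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], 0)
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  nd <- ag_node(xs[[1]]$tape, out, xs, NULL)
  nd$saved <- cs
  nd$backfn <- function(nd) {
    cs <- nd$saved
    at <- 0L
    out <- vector("list", length(cs))
    for (i in seq_along(cs)) {
      out[[i]] <- nd$grad[, , at + seq_len(cs[i]), , drop = FALSE]
      at <- at + cs[i]
    }
    out
  }
  nd
}

ag_slice_c <- function(x, channels) {
  nd <- ag_node(x$tape, x$value[, , channels, , drop = FALSE], list(x), NULL)
  nd$saved <- channels
  nd$backfn <- function(nd) {
    g <- array(0, dim(nd$parents[[1]]$value))
    g[, , nd$saved, ] <- nd$grad
    list(g)
  }
  nd
}

# multiply every (H, W) slice of channel c, sample n by s[c, n]
ag_scale_channels <- function(x, s) {
  d <- dim(x$value)
  sf <- array(rep(as.vector(s$value), each = d[1] * d[2]), d)
  nd <- ag_node(x$tape, x$value * sf, list(x, s), NULL)
  nd$saved <- sf
  nd$backfn <- function(nd) {
    d <- dim(nd$parents[[1]]$value)
    gs <- colSums(matrix(nd$grad * nd$parents[[1]]$value, nrow = d[1] * d[2]))
    list(nd$grad * nd$saved, matrix(gs, d[3], d[4]))
  }
  nd
}

# global average pool (H, W, C, N) -> (C, N)
ag_gap <- function(x) {
  d <- dim(x$value)
  y <- matrix(colMeans(matrix(x$value, nrow = d[1] * d[2])), d[3], d[4])
  nd <- ag_node(x$tape, y, list(x), NULL)
  nd$backfn <- function(nd) {
    d <- dim(nd$parents[[1]]$value)
    list(array(rep(as.vector(nd$grad), each = d[1] * d[2]), d) / (d[1] * d[2]))
  }
  nd
}

# (C, N) gate vector expanded and multiplied is ag_scale_channels; a dense
# affine map on (C, N) matrices:
ag_linear <- function(x, w, b = NULL) {
  y <- w$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  if (!is.null(x$tape$trace))
    x$tape$trace[[length(x$tape$trace) + 1L]] <- data.frame(
      X = 1, Y = 1, Cin = nrow(x$value), Cout = nrow(y),
      kh = 1, kw = 1, groups = 1)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  nd <- ag_node(x$tape, y, parents, NULL)
  nd$backfn <- function(nd) {
    gx <- t(nd$parents[[2]]$value) %*% nd$grad
    gw <- nd$grad %*% t(nd$parents[[1]]$value)
    if (length(nd$parents) == 3L) list(gx, gw, rowSums(nd$grad))
    else list(gx, gw)
  }
  nd
}

## ---- batch normalisation ----------------------------------------------------

# state: env with $mean, $var (running), updated in training mode
ag_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  per_slice <- matrix(colMeans(matrix(x$value, nrow = d[1] * d[2])), d[3], d[4])
  if (training) {
    mu <- rowMeans(per_slice)
    xc <- x$value - bc_channel(mu, d)
    v <- rowMeans(matrix(colMeans(matrix(xc^2, nrow = d[1] * d[2])), d[3], d[4]))
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * m / max(1, m - 1)
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x$value - bc_channel(mu, d)
  }
  sd_ <- sqrt(v + eps)
  xhat <- xc / bc_channel(sd_, d)
  y <- xhat * bc_channel(gamma$value, d) + bc_channel(beta$value, d)
  nd <- ag_node(x$tape, y, list(x, gamma, beta), NULL)
  nd$saved <- list(xhat = xhat, sd = sd_, training = training, m = m)
  nd$backfn <- function(nd) {
    s <- nd$saved
    d <- dim(nd$value)
    gy <- nd$grad
    ggamma <- chan_sum(gy * s$xhat, d)
    gbeta <- chan_sum(gy, d)
    gxh <- gy * bc_channel(nd$parents[[2]]$value, d)
    if (s$training) {
      mean_gxh <- chan_sum(gxh, d) / s$m
      mean_gxh_xh <- chan_sum(gxh * s$xhat, d) / s$m
      gx <- (gxh - bc_channel(mean_gxh, d) -
               s$xhat * bc_channel(mean_gxh_xh, d)) / bc_channel(s$sd, d)
    } else {
      gx <- gxh / bc_channel(s$sd, d)
    }
    list(gx, ggamma, gbeta)
  }
  nd
}

bc_channel <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

chan_sum <- function(x, d) {
  rowSums(matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4]))
}

## ---- Fourier ops ------------------------------------------------------------

# 2-D unnormalized forward DFT over (H, W), per channel and sample.
# Gradient of the (linear) transform: unnormalized inverse DFT of the
# complex-packed output gradient.
ag_fft2 <- function(x) {
  z <- apply_fft(x$value, inverse = FALSE, normalize = FALSE)
  nd <- ag_node(x$tape, z, list(x), NULL)
  nd$backfn <- function(nd)
    list(Re(apply_fft(nd$grad, inverse = TRUE, normalize = FALSE)))
  nd
}

# real part of the 1/(NM)-normalized inverse DFT of a complex node
ag_ifft2_real <- function(z) {
  y <- Re(apply_fft(z$value, inverse = TRUE, normalize = TRUE))
  nd <- ag_node(z$tape, y, list(z), NULL)
  nd$backfn <- function(nd) {
    d <- dim(nd$value)
    list(apply_fft(nd$grad + 0i, inverse = FALSE, normalize = FALSE) /
           (d[1] * d[2]))
  }
  nd
}

ag_magnitude <- function(z, eps = 1e-12) {
  m <- Mod(z$value)
  nd <- ag_node(z$tape, m, list(z), NULL)
  nd$backfn <- function(nd) {
    zz <- nd$parents[[1]]$value
    m <- pmax(nd$value, eps)
    list(nd$grad * (Re(zz) / m) + 1i * (nd$grad * (Im(zz) / m)))
  }
  nd
}

ag_phase <- function(z, eps = 1e-12) {
  nd <- ag_node(z$tape, Arg(z$value), list(z), NULL)
  nd$backfn <- function(nd) {
    zz <- nd$parents[[1]]$value
    m2 <- pmax(Mod(zz)^2, eps)
    list(nd$grad * (-Im(zz) / m2) + 1i * (nd$grad * (Re(zz) / m2)))
  }
  nd
}

ag_complex <- function(re, im) {
  nd <- ag_node(re$tape, re$value + 1i * im$value, list(re, im), NULL)
  nd$backfn <- function(nd) list(Re(nd$grad), Im(nd$grad))
  nd
}

# 2x2 periodic tiling of the spatial axes: (H, W, C, N) -> (2H, 2W, C, N)
ag_tile2 <- function(x) {
  v <- x$value
  d <- dim(v)
  ih <- rep(seq_len(d[1]), 2)
  iw <- rep(seq_len(d[2]), 2)
  y <- v[ih, iw, , , drop = FALSE]
  nd <- ag_node(x$tape, y, list(x), NULL)
  nd$backfn <- function(nd) {
    d <- dim(nd$parents[[1]]$value)
    g <- nd$grad
    h <- seq_len(d[1]); w <- seq_len(d[2])
    list(g[h, w, , , drop = FALSE] + g[d[1] + h, w, , , drop = FALSE] +
           g[h, d[2] + w, , , drop = FALSE] +
           g[d[1] + h, d[2] + w, , , drop = FALSE])
  }
  nd
}

# apply stats::fft to each (H, W) slice of a (H, W, C, N) array
apply_fft <- function(x, inverse, normalize) {
  d <- dim(x)
  out <- array(0i, d)
  nm <- d[1] * d[2]
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3])) {
      z <- stats::fft(x[, , c, n], inverse = inverse)
      out[, , c, n] <- if (normalize && inverse) z / nm else z
    }
  out
}

## ---- losses -----------------------------------------------------------------

# logits: (K, N) node; labels: integer vector in 1..K; returns mean NLL scalar
ag_cross_entropy <- function(logits, labels) {
  lv <- logits$value
  K <- nrow(lv); N <- ncol(lv)
  mx <- apply(lv, 2, max)
  ex <- exp(sweep(lv, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  nd <- ag_node(logits$tape, loss, list(logits), NULL)
  nd$saved <- list(p = p, labels = labels)
  nd$backfn <- function(nd) {
    p <- nd$saved$p
    N <- ncol(p)
    g <- p
    g[cbind(nd$saved$labels, seq_len(N))] <-
      g[cbind(nd$saved$labels, seq_len(N))] - 1
    list(nd$grad * g / N)
  }
  nd
}

## ---- optimiser --------------------------------------------------------------

# SGD with classical momentum and decoupled-from-nothing L2 weight decay
# (decay added to the raw gradient, as the YOLO training stack does).
sgd_step <- function(params, lr, momentum = 0.937, weight_decay = 5e-4) {
  for (p in params) {
    g <- p$grad
    if (p$decay && weight_decay > 0) g <- g + weight_decay * p$value
    if (is.null(p$mom)) p$mom <- p$value * 0
    p$mom <- momentum * p$mom + g
    p$value <- p$value - lr * p$mom
  }
  invisible(params)
}
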