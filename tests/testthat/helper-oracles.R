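# Independent brute-force oracles used across the suite.  These implement
# the defining formulas literally (double sums, per-pixel loops) and are
# deliberately separate from the package's computation paths.

# unnormalized forward 2-D DFT by literal double sum
naive_dft2 <- function(x) {
  N <- nrow(x); M <- ncol(x)
  out <- matrix(0i, N, M)
  for (k in 0:(N - 1)) for (l in 0:(M - 1)) {
    acc <- 0i
    for (a in 0:(N - 1)) for (b in 0:(M - 1))
      acc <- acc + x[a + 1, b + 1] * exp(-2i * pi * (k * a / N + l * b / M))
    out[k + 1, l + 1] <- acc
  }
  out
}

# 1/(NM)-normalized inverse 2-D DFT by literal double sum
naive_idft2 <- function(z) {
  N <- nrow(z); M <- ncol(z)
  out <- matrix(0i, N, M)
  for (a in 0:(N - 1)) for (b in 0:(M - 1)) {
    acc <- 0i
    for (k in 0:(N - 1)) for (l in 0:(M - 1))
      acc <- acc + z[k + 1, l + 1] * exp(2i * pi * (k * a / N + l * b / M))
    out[a + 1, b + 1] <- acc / (N * M)
  }
  out
}

# dense/grouped 2-D convolution by literal loops ((H, W, C, N) layout)
naive_conv2d <- function(x, w, b, stride = 1L, ph = NULL, pw = NULL,
                         groups = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  if (is.null(ph)) ph <- (kh - 1L) %/% 2L
  if (is.null(pw)) pw <- (kw - 1L) %/% 2L
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  cpg <- dim(w)[3]; Cout <- dim(w)[4]
  coutpg <- Cout / groups
  Ho <- (H + 2 * ph - kh) %/% stride + 1L
  Wo <- (W + 2 * pw - kw) %/% stride + 1L
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1L) %/% coutpg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (length(b)) b[co] else 0
      for (cl in 1:cpg) {
        ci <- g * cpg + cl
        for (j in 1:kw) for (i in 1:kh) {
          hi <- (ho - 1L) * stride - ph + i
          wi <- (wo - 1L) * stride - pw + j
          if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
            acc <- acc + x[hi, wi, ci, n] * w[i, j, cl, co]
        }
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# vALD / GAD by per-pixel loops with replicate padding
oracle_vald <- function(img, include_center = TRUE) {
  H <- nrow(img); W <- ncol(img)
  v <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1L), H)
      jj <- min(max(j + dj, 1L), W)
      acc <- acc + img[ii, jj]
    }
    nb <- if (include_center) acc / 9 else (acc - img[i, j]) / 8
    v[i, j] <- abs(img[i, j] - nb)
  }
  list(vald = v, gad = mean(abs(img - mean(img))))
}

oracle_flat_mask <- function(img, flat_fraction = 0.10,
                             include_center = TRUE) {
  st <- oracle_vald(img, include_center)
  ifelse(st$vald <= flat_fraction * st$gad, 255, 0)
}

# sliding-window black-proportion statistics by loops
oracle_windows <- function(mask, win, stride, window_thresh) {
  H <- nrow(mask); W <- ncol(mask)
  rows <- seq(1L, H - win + 1L, by = stride)
  cols <- seq(1L, W - win + 1L, by = stride)
  props <- c()
  for (r in rows) for (cc in cols) {
    blk <- mask[r:(r + win - 1L), cc:(cc + win - 1L)]
    props <- c(props, mean(blk == 0))
  }
  list(global_black = mean(mask == 0), props = props,
       max_window = max(props),
       scattered_fraction = mean(props > window_thresh))
}

# all-points PR integration from an explicit ranked TP/FP sequence
oracle_ap <- function(tp_seq, n_gt) {
  tp <- cumsum(tp_seq)
  fp <- cumsum(1 - tp_seq)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  ap <- 0
  for (i in seq_len(length(mrec) - 1L))
    if (mrec[i + 1L] != mrec[i]) ap <- ap + (mrec[i + 1L] - mrec[i]) * mpre[i + 1L]
  ap
}

# multiply-accumulate counter that walks every output position of a conv
oracle_mac_count <- function(X, Y, cin, cout, k, groups = 1L) {
  k <- rep(k, length.out = 2L)
  ops <- 0
  for (x in seq_len(X)) for (y in seq_len(Y)) for (co in seq_len(cout))
    ops <- ops + (cin / groups) * k[1] * k[2] + 1
  ops / 1e9
}

# straight-line reimplementation of the dual-domain attention layer on top
# of the loop convolution oracle
oracle_ms_dffm <- function(x, w) {
  d <- dim(x)
  C <- d[3]
  pooled <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  h <- pmax(w$se1$w$value %*% pooled + w$se1$b$value, 0)
  gates <- pmin(pmax((w$se2$w$value %*% h + w$se2$b$value + 3) / 6, 0), 1)
  g <- x * array(rep(as.vector(gates), each = d[1] * d[2]), d)
  pre <- naive_conv2d(g, w$entry$w$value, w$entry$b$value)
  gelu <- function(t) 0.5 * t * (1 + tanh(sqrt(2 / pi) * (t + 0.044715 * t^3)))
  u <- gelu(pre)
  agg <- naive_conv2d(u, w$base$w$value, w$base$b$value, groups = C)
  for (s in w$strips) {
    hh <- naive_conv2d(u, s$h$w$value, s$h$b$value, groups = C)
    agg <- agg + naive_conv2d(hh, s$v$w$value, s$v$b$value, groups = C)
  }
  att <- naive_conv2d(agg, w$exit$w$value, w$exit$b$value)
  if (w$combine == "multiply") x + att * u else x + att + u
}

rand_grid <- function(H, W, C = NULL, N = NULL) {
  if (is.null(C)) matrix(stats::rnorm(H * W), H, W)
  else if (is.null(N)) array(stats::rnorm(H * W * C), c(H, W, C))
  else array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}
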