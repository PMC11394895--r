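# Network building blocks.
#
# Each block is a plain list: $type plus parameters (ag_param leaves) and
# nested sub-blocks.  block_forward() dispatches on $type with a context
# `ctx` (environment holding $tape, $training and an optional $trace list
# that accumulates per-convolution cost rows for GFLOPs reporting).
# RepNCSPELAN4 / ADown / SPPELAN follow their GELAN-family reference
# designs; C2f-SE is the standard C2f with a squeeze-excitation gate on
# each bottleneck output.

new_bn <- function(channels) {
  state <- new.env(parent = emptyenv())
  state$mean <- numeric(channels)
  state$var <- rep(1, channels)
  list(gamma = ag_param(rep(1, channels), decay = FALSE),
       beta = ag_param(numeric(channels), decay = FALSE),
       state = state)
}

conv_init <- function(kh, kw, cpg, cout) {
  bound <- sqrt(6 / (kh * kw * cpg))
  array(stats::runif(kh * kw * cpg * cout, -bound, bound),
        c(kh, kw, cpg, cout))
}

# standard Conv unit: conv2d (+BN) (+activation)
nn_conv <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                    act = "silu", bn = TRUE, bias = !bn, pad = NULL,
                    bias_init = 0) {
  k <- rep(as.integer(k), length.out = 2L)
  blk <- list(type = "conv", cin = cin, cout = cout, k = k,
              stride = as.integer(stride), groups = as.integer(groups),
              act = act, pad = pad,
              w = ag_param(conv_init(k[1], k[2], cin %/% groups, cout)))
  if (bias) blk$b <- ag_param(rep(bias_init, cout), decay = FALSE)
  if (bn) blk$bn <- new_bn(cout)
  blk
}

nn_linear <- function(cin, cout, bias_init = 0) {
  bound <- sqrt(6 / cin)
  list(type = "linear", cin = cin, cout = cout,
       w = ag_param(matrix(stats::runif(cin * cout, -bound, bound), cout, cin)),
       b = ag_param(rep(bias_init, cout), decay = FALSE))
}

nn_se_unit <- function(channels, reduction = 16L) {
  cr <- max(min(8L, channels), channels %/% reduction)
  list(type = "se_unit",
       fc1 = nn_linear(channels, cr),
       fc2 = nn_linear(cr, channels))
}

nn_bottleneck <- function(channels, shortcut = TRUE, se = FALSE) {
  list(type = "bottleneck", shortcut = shortcut,
       cv1 = nn_conv(channels, channels, 3L),
       cv2 = nn_conv(channels, channels, 3L),
       se = if (se) nn_se_unit(channels))
}

nn_c2f <- function(cin, cout, n = 1L, se = FALSE) {
  ch <- cout %/% 2L
  list(type = "c2f", ch = ch,
       cv1 = nn_conv(cin, 2L * ch, 1L),
       m = lapply(seq_len(n), function(i) nn_bottleneck(ch, TRUE, se)),
       cv2 = nn_conv((2L + n) * ch, cout, 1L))
}

nn_repconv <- function(cin, cout) {
  list(type = "repconv",
       cv3 = nn_conv(cin, cout, 3L, act = "none"),
       cv1 = nn_conv(cin, cout, 1L, act = "none"))
}

nn_repbottleneck <- function(cin, cout) {
  list(type = "repbottleneck", shortcut = cin == cout,
       cv1 = nn_repconv(cin, cout),
       cv2 = nn_conv(cout, cout, 3L))
}

nn_repncsp <- function(cin, cout, n = 1L) {
  ch <- max(1L, cout %/% 2L)
  list(type = "repncsp",
       cv1 = nn_conv(cin, ch, 1L),
       cv2 = nn_conv(cin, ch, 1L),
       m = lapply(seq_len(n), function(i) nn_repbottleneck(ch, ch)),
       cv3 = nn_conv(2L * ch, cout, 1L))
}

nn_repncspelan4 <- function(cin, cout, c3 = NULL, c4 = NULL, n = 1L) {
  if (is.null(c3)) c3 <- cout
  if (is.null(c4)) c4 <- max(2L, c3 %/% 2L)
  list(type = "repncspelan4", c3 = c3, c4 = c4,
       cv1 = nn_conv(cin, c3, 1L),
       cv2a = nn_repncsp(c3 %/% 2L, c4, n),
       cv2b = nn_conv(c4, c4, 3L),
       cv3a = nn_repncsp(c4, c4, n),
       cv3b = nn_conv(c4, c4, 3L),
       cv4 = nn_conv(c3 + 2L * c4, cout, 1L))
}

nn_adown <- function(cin, cout) {
  ch <- cout %/% 2L
  list(type = "adown", ch_in = cin %/% 2L,
       cv1 = nn_conv(cin %/% 2L, ch, 3L, stride = 2L),
       cv2 = nn_conv(cin - cin %/% 2L, cout - ch, 1L))
}

nn_sppelan <- function(cin, cout, c3 = NULL) {
  if (is.null(c3)) c3 <- max(2L, cout %/% 2L)
  list(type = "sppelan", c3 = c3,
       cv1 = nn_conv(cin, c3, 1L),
       cv5 = nn_conv(4L * c3, cout, 1L))
}

nn_msf3m <- function(channels) {
  list(type = "msf3m", wts = msf3m_weights(channels))
}

nn_msdffm <- function(channels, reduction = 16L) {
  list(type = "msdffm", wts = ms_dffm_weights(channels, reduction))
}

nn_fourier_up <- function(channels, conv = TRUE) {
  list(type = "fourier_up",
       wts = if (conv) fourier_upsample_weights(channels))
}

nn_upsample_nearest <- function() list(type = "upsample_nearest")

## ---- forward dispatch -------------------------------------------------------

block_forward <- function(blk, ctx, x) {
  switch(blk$type,
    conv = fwd_conv(blk, ctx, x),
    linear = ag_linear(x, ag_leaf(ctx$tape, blk$w), ag_leaf(ctx$tape, blk$b)),
    se_unit = fwd_se_unit(blk, ctx, x),
    bottleneck = fwd_bottleneck(blk, ctx, x),
    c2f = fwd_c2f(blk, ctx, x),
    repconv = ag_silu(ag_add(fwd_conv(blk$cv3, ctx, x),
                             fwd_conv(blk$cv1, ctx, x))),
    repbottleneck = fwd_repbottleneck(blk, ctx, x),
    repncsp = fwd_repncsp(blk, ctx, x),
    repncspelan4 = fwd_repncspelan4(blk, ctx, x),
    adown = fwd_adown(blk, ctx, x),
    sppelan = fwd_sppelan(blk, ctx, x),
    msf3m = msf3m_node(ctx$tape, x, blk$wts),
    msdffm = ms_dffm_node(ctx$tape, x, blk$wts),
    fourier_up = fourier_upsample_node(ctx$tape, x, blk$wts),
    upsample_nearest = ag_upsample_nearest(x),
    stop(sprintf("unknown block type '%s'", blk$type))
  )
}

fwd_conv <- function(blk, ctx, x) {
  y <- ag_conv2d(x, ag_leaf(ctx$tape, blk$w),
                 if (!is.null(blk[["b"]])) ag_leaf(ctx$tape, blk[["b"]]),
                 stride = blk$stride, pad = blk$pad, groups = blk$groups)
  if (!is.null(blk$bn))
    y <- ag_batchnorm(y, ag_leaf(ctx$tape, blk$bn$gamma),
                      ag_leaf(ctx$tape, blk$bn$beta),
                      blk$bn$state, ctx$training)
  switch(blk$act, silu = ag_silu(y), relu = ag_relu(y), none = y)
}

fwd_se_unit <- function(blk, ctx, x) {
  pooled <- ag_gap(x)
  h <- ag_relu(block_forward(blk$fc1, ctx, pooled))
  g <- ag_hsigmoid(block_forward(blk$fc2, ctx, h))
  ag_scale_channels(x, g)
}

fwd_bottleneck <- function(blk, ctx, x) {
  y <- block_forward(blk$cv2, ctx, block_forward(blk$cv1, ctx, x))
  if (!is.null(blk$se)) y <- fwd_se_unit(blk$se, ctx, y)
  if (blk$shortcut) ag_add(x, y) else y
}

fwd_c2f <- function(blk, ctx, x) {
  y <- block_forward(blk$cv1, ctx, x)
  ch <- blk$ch
  ys <- list(ag_slice_c(y, seq_len(ch)), ag_slice_c(y, ch + seq_len(ch)))
  for (m in blk$m) ys[[length(ys) + 1L]] <- block_forward(m, ctx, ys[[length(ys)]])
  block_forward(blk$cv2, ctx, ag_concat_c(ys))
}

fwd_repbottleneck <- function(blk, ctx, x) {
  y <- block_forward(blk$cv2, ctx, block_forward(blk$cv1, ctx, x))
  if (blk$shortcut) ag_add(x, y) else y
}

fwd_repncsp <- function(blk, ctx, x) {
  a <- block_forward(blk$cv1, ctx, x)
  for (m in blk$m) a <- block_forward(m, ctx, a)
  b <- block_forward(blk$cv2, ctx, x)
  block_forward(blk$cv3, ctx, ag_concat_c(list(a, b)))
}

fwd_repncspelan4 <- function(blk, ctx, x) {
  y <- block_forward(blk$cv1, ctx, x)
  half <- blk$c3 %/% 2L
  a <- ag_slice_c(y, seq_len(half))
  b <- ag_slice_c(y, half + seq_len(blk$c3 - half))
  p <- block_forward(blk$cv2b, ctx, block_forward(blk$cv2a, ctx, b))
  q <- block_forward(blk$cv3b, ctx, block_forward(blk$cv3a, ctx, p))
  block_forward(blk$cv4, ctx, ag_concat_c(list(a, b, p, q)))
}

fwd_adown <- function(blk, ctx, x) {
  x <- ag_avgpool(x, 2L, stride = 1L, pad = 0L)
  cin <- dim(x$value)[3]
  x1 <- ag_slice_c(x, seq_len(blk$ch_in))
  x2 <- ag_slice_c(x, (blk$ch_in + 1L):cin)
  a <- block_forward(blk$cv1, ctx, x1)
  b <- block_forward(blk$cv2, ctx, ag_maxpool(x2, 3L, stride = 2L, pad = 1L))
  ag_concat_c(list(a, b))
}

fwd_sppelan <- function(blk, ctx, x) {
  y1 <- block_forward(blk$cv1, ctx, x)
  y2 <- ag_maxpool(y1, 5L, stride = 1L, pad = 2L)
  y3 <- ag_maxpool(y2, 5L, stride = 1L, pad = 2L)
  y4 <- ag_maxpool(y3, 5L, stride = 1L, pad = 2L)
  block_forward(blk$cv5, ctx, ag_concat_c(list(y1, y2, y3, y4)))
}

# nearest-neighbour 2x upsample (reference comparator for Fourier upsampling)
ag_upsample_nearest <- function(x) {
  d <- dim(x$value)
  ih <- rep(seq_len(d[1]), each = 2L)
  iw <- rep(seq_len(d[2]), each = 2L)
  nd <- ag_node(x$tape, x$value[ih, iw, , , drop = FALSE], list(x), NULL)
  nd$backfn <- function(nd) {
    d <- dim(nd$parents[[1]]$value)
    g <- nd$grad
    list(g[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
           g[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
           g[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
           g[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE])
  }
  nd
}

# recursively collect every ag_param in a block tree
collect_params <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.list(x)) return(do.call(c, c(lapply(x, collect_params), list(list()))))
  list()
}
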