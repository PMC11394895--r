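# Deep Fourier up-sampling: resolution doubling with global support.
#
# The spectrum of the input is converted to magnitude/phase, both components
# are cyclically padded (2x2 periodic tiling) in the H and W dimensions, an
# optional depthwise 3x3 convolution processes the padded pair, and the
# inverse transform at the doubled size returns to the spatial domain.  With
# the convolution bypassed the operation is exactly zero-interleaving:
# tiling the spectrum 2x2 and inverting at size (2H, 2W) with the 1/(4NM)
# normalization places x(i, j) at output (2i, 2j) and zeros elsewhere.

#' Cyclically pad a polar spectrum to twice its extent
#'
#' Output entry `(k, l)` equals input `(k mod H, l mod W)` for both
#' magnitude and phase: a 2x2 periodic tiling along the spatial axes.
#'
#' @param polar A [polar_spectrum] over an `H x W` grid (channel/batch axes
#'   allowed).
#' @return A [polar_spectrum] over `2H x 2W`.
#' @export
cyclic_pad_spectrum <- function(polar) {
  stopifnot(inherits(polar, "polar_spectrum"))
  polar_spectrum(tile2_array(polar$magnitude), tile2_array(polar$phase),
                 attended = polar$attended)
}

tile2_array <- function(x) {
  x <- as_grid_array(x)
  d <- dim(x)
  ih <- rep(seq_len(d[1]), 2L)
  iw <- rep(seq_len(d[2]), 2L)
  if (length(d) == 2L) x[ih, iw]
  else if (length(d) == 3L) x[ih, iw, , drop = FALSE]
  else x[ih, iw, , , drop = FALSE]
}

#' Weights for the post-padding convolution of Fourier up-sampling
#'
#' A depthwise 3x3 pair applied to the padded magnitude and phase
#' separately.
#'
#' @param channels Feature channel count.
#' @param init `"kaiming"`, `"zero"`, or `"identity"` (identity impulses,
#'   under which the convolution is a no-op and the layer equals its
#'   conv-bypass form).
#' @return An object of class `fourier_upsample_weights`.
#' @export
fourier_upsample_weights <- function(channels,
                                     init = c("kaiming", "zero", "identity")) {
  init <- match.arg(init)
  structure(list(
    channels = channels,
    magnitude = dw_conv_param(3L, 3L, channels, init),
    phase = dw_conv_param(3L, 3L, channels, init)
  ), class = "fourier_upsample_weights")
}

fourier_upsample_node <- function(tape, x, weights = NULL) {
  C <- dim(x$value)[3]
  z <- ag_fft2(x)
  stage_check(z$value, "fft")
  m <- ag_tile2(ag_magnitude(z))
  p <- ag_tile2(ag_phase(z))
  if (!is.null(weights)) {
    if (weights$channels != C)
      stop(sprintf("fourier upsample: input has %d channels, weights expect %d",
                   C, weights$channels))
    m <- ag_conv2d(m, ag_leaf(tape, weights$magnitude$w),
                   ag_leaf(tape, weights$magnitude$b), groups = C)
    p <- ag_conv2d(p, ag_leaf(tape, weights$phase$w),
                   ag_leaf(tape, weights$phase$b), groups = C)
    stage_check(m$value, "conv")
  }
  re <- ag_mul(m, ag_cos(p))
  im <- ag_mul(m, ag_sin(p))
  zc <- ag_complex(re, im)
  stage_check(zc$value, "reconstruction")
  y <- ag_ifft2_real(zc)
  stage_check(y$value, "ifft")
  y
}

#' Deep Fourier up-sampling forward pass
#'
#' Doubles the spatial resolution of `x`: FFT, polar split, cyclic 2x2
#' spectrum padding, optional depthwise convolution on the padded
#' magnitude/phase pair, polar reconstruction, inverse FFT at the doubled
#' size.  With `weights = NULL` (conv-bypass mode) the output is exactly the
#' zero-interleaved input.
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, N)`.
#' @param weights A [fourier_upsample_weights()] object, or `NULL` to bypass
#'   the convolution.
#' @return Array of shape `(2H, 2W, C[, N])`.
#' @examples
#' x <- array(stats::rnorm(4 * 4 * 1), c(4, 4, 1))
#' y <- fourier_upsample_forward(x)     # bypass mode
#' max(abs(y[c(1, 3, 5, 7), c(1, 3, 5, 7), 1] - x[, , 1]))  # ~1e-16
#' @export
fourier_upsample_forward <- function(x, weights = NULL) {
  g4 <- to4d(as_grid_array(x))
  if (length(g4$d) < 3L)
    stop("fourier_upsample_forward: input needs a channel axis")
  check_finite_grid(g4$a, "fourier_upsample_forward")
  tape <- ag_tape()
  out <- fourier_upsample_node(tape, ag_node(tape, g4$a), weights)
  d2 <- g4$d
  d2[1:2] <- d2[1:2] * 2L
  restore_dim(out$value, d2)
}
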