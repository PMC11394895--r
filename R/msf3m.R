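# Multi-scale frequency-domain feature fusion (MSF3M).
#
# Pipeline: FFT -> magnitude/phase split -> per-component multi-scale strip
# convolutions (5x5 depthwise base, then 1x7/7x1, 1x11/11x1, 1x21/21x1
# depthwise pairs, summed with the base, fused by a pointwise 1x1) -> polar
# reconstruction -> inverse FFT -> elementwise multiplication with the
# original input.  Magnitude and phase paths share the structure but not the
# parameters.  The phase-path output is not re-wrapped into (-pi, pi]:
# cos/sin downstream are 2*pi-periodic, so wrapping would be a no-op.

#' Weights for one magnitude- or phase-path branch of MSF3M
#'
#' @param channels Number of feature channels the branch operates on.
#' @param strip_sizes Strip kernel lengths (each spawns a 1 x k then k x 1
#'   depthwise pair).
#' @param init `"kaiming"` for fan-in-scaled uniform random weights,
#'   `"zero"` for all-zero weights, `"identity"` for the delta-kernel
#'   construction under which the branch is the identity map.
#' @return An object of class `msf3m_branch`.
#' @export
msf3m_branch_weights <- function(channels,
                                 strip_sizes = c(7L, 11L, 21L),
                                 init = c("kaiming", "zero", "identity")) {
  init <- match.arg(init)
  br <- list(
    channels = channels,
    strip_sizes = as.integer(strip_sizes),
    base = dw_conv_param(5L, 5L, channels, init),
    strips = lapply(strip_sizes, function(k) list(
      h = dw_conv_param(1L, k, channels, init),
      v = dw_conv_param(k, 1L, channels, init)
    )),
    fuse = pw_conv_param(channels, channels, init,
                         identity_gain = 1 / (length(strip_sizes) + 1))
  )
  class(br) <- "msf3m_branch"
  br
}

#' Weight pair for a full MSF3M layer
#'
#' Separate, unshared branches for the magnitude and the phase path.
#'
#' @inheritParams msf3m_branch_weights
#' @return An object of class `msf3m_weights` with elements `magnitude` and
#'   `phase`.
#' @export
msf3m_weights <- function(channels, strip_sizes = c(7L, 11L, 21L),
                          init = "kaiming") {
  structure(list(
    magnitude = msf3m_branch_weights(channels, strip_sizes, init),
    phase = msf3m_branch_weights(channels, strip_sizes, init)
  ), class = "msf3m_weights")
}

#' Delta-kernel MSF3M weights (the layer reduces to elementwise squaring)
#'
#' Every convolution is an identity impulse and the 1x1 fusion averages the
#' aggregated terms, so each branch passes its input through unchanged and
#' the layer computes `ifft(fft(x)) * x = x * x`.
#'
#' @param channels Number of feature channels.
#' @return An `msf3m_weights` object.
#' @export
msf3m_identity_weights <- function(channels) {
  msf3m_weights(channels, init = "identity")
}

# depthwise kernel (kh, kw, 1, C) + bias
dw_conv_param <- function(kh, kw, channels, init) {
  w <- array(0, c(kh, kw, 1L, channels))
  if (init == "kaiming") {
    bound <- sqrt(6 / (kh * kw))
    w[] <- stats::runif(length(w), -bound, bound)
  } else if (init == "identity") {
    w[(kh + 1L) %/% 2L, (kw + 1L) %/% 2L, 1L, ] <- 1
  }
  list(w = ag_param(w), b = ag_param(numeric(channels), decay = FALSE))
}

# pointwise kernel (1, 1, Cin, Cout) + bias
pw_conv_param <- function(cin, cout, init, identity_gain = 1) {
  w <- array(0, c(1L, 1L, cin, cout))
  if (init == "kaiming") {
    bound <- sqrt(6 / cin)
    w[] <- stats::runif(length(w), -bound, bound)
  } else if (init == "identity") {
    stopifnot(cin == cout)
    for (c in seq_len(cin)) w[1L, 1L, c, c] <- identity_gain
  }
  list(w = ag_param(w), b = ag_param(numeric(cout), decay = FALSE))
}

# tape-level branch forward; x is an ag_node (H, W, C, N)
msf3m_branch_node <- function(tape, x, br) {
  C <- dim(x$value)[3]
  if (C != br$channels)
    stop(sprintf("msf3m branch: input has %d channels, weights expect %d",
                 C, br$channels))
  base <- ag_conv2d(x, ag_leaf(tape, br$base$w), ag_leaf(tape, br$base$b),
                    groups = C)
  agg <- base
  for (s in br$strips) {
    h <- ag_conv2d(base, ag_leaf(tape, s$h$w), ag_leaf(tape, s$h$b), groups = C)
    v <- ag_conv2d(h, ag_leaf(tape, s$v$w), ag_leaf(tape, s$v$b), groups = C)
    agg <- ag_add(agg, v)
  }
  ag_conv2d(agg, ag_leaf(tape, br$fuse$w), ag_leaf(tape, br$fuse$b))
}

#' Multi-scale convolution branch applied to one spectral component
#'
#' Runs the 5x5 base convolution, the three parallel strip-convolution
#' pairs, their sum-aggregation with the base output, and the 1x1 fusion on
#' a magnitude or phase grid.  Shape is preserved ("same" zero padding).
#'
#' @param component Numeric array `(H, W, C)` or `(H, W, C, N)`.
#' @param spec An [msf3m_branch_weights()] object.
#' @return Array of the same shape as `component`.
#' @export
multiscale_freq_branch <- function(component, spec) {
  stopifnot(inherits(spec, "msf3m_branch"))
  g4 <- to4d(as_grid_array(component))
  if (length(g4$d) < 3L)
    stop("multiscale_freq_branch: component needs a channel axis")
  tape <- ag_tape()
  out <- msf3m_branch_node(tape, ag_node(tape, g4$a), spec)
  restore_dim(out$value, g4$d)
}

# full layer on the tape (used standalone and inside assembled models)
msf3m_node <- function(tape, x, weights) {
  z <- ag_fft2(x)
  stage_check(z$value, "fft")
  m <- ag_magnitude(z)
  p <- ag_phase(z)
  m_att <- msf3m_branch_node(tape, m, weights$magnitude)
  p_att <- msf3m_branch_node(tape, p, weights$phase)
  stage_check(m_att$value, "branch")
  re <- ag_mul(m_att, ag_cos(p_att))
  im <- ag_mul(m_att, ag_sin(p_att))
  zc <- ag_complex(re, im)
  stage_check(zc$value, "reconstruction")
  y <- ag_ifft2_real(zc)
  stage_check(y$value, "ifft")
  ag_mul(y, x)
}

#' MSF3M forward pass
#'
#' The full frequency-domain fusion layer: transform, attend to magnitude
#' and phase with separate multi-scale branches, reconstruct the spectrum,
#' invert, and multiply the result elementwise with the original input.
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, N)`.
#' @param weights An [msf3m_weights()] object matching `x`'s channel count.
#' @return Array of the same shape as `x`.
#' @examples
#' x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
#' w <- msf3m_identity_weights(2)
#' max(abs(msf3m_forward(x, w) - x * x))  # ~0 by construction
#' @export
msf3m_forward <- function(x, weights) {
  stopifnot(inherits(weights, "msf3m_weights"))
  g4 <- to4d(as_grid_array(x))
  if (length(g4$d) < 3L) stop("msf3m_forward: input needs a channel axis")
  check_finite_grid(g4$a, "msf3m_forward")
  tape <- ag_tape()
  out <- msf3m_node(tape, ag_node(tape, g4$a), weights)
  restore_dim(out$value, g4$d)
}

stage_check <- function(v, stage) {
  if (!all(is.finite(Mod(v))))
    stop(sprintf("non-finite activations at stage %s", stage))
}
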