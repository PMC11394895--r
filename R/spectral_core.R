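# Exact 2-D Fourier transforms and Cartesian/polar spectrum conversion.
#
# Convention ("backward" normalization): the forward transform is the
# unnormalized double sum
#   Xhat(k, l) = sum_x sum_y X(x, y) * exp(-2i*pi*(k*x/N + l*y/M)),
# and the inverse carries the 1/(N*M) factor.  Arrays are laid out with the
# two spatial axes first: (H, W), (H, W, C) or (H, W, C, N); transforms act
# on each (H, W) slice independently, never mixing channel or batch axes.

#' Complex frequency-domain spectrum
#'
#' Container pairing the real and imaginary parts of a 2-D discrete Fourier
#' transform.  Both components share the shape of the originating spatial
#' grid.
#'
#' @param re,im Numeric arrays of identical shape (real and imaginary parts).
#' @return An object of class `complex_spectrum` with elements `re` and `im`.
#' @export
complex_spectrum <- function(re, im) {
  stopifnot(identical(dim(re) %||% length(re), dim(im) %||% length(im)))
  check_finite(re, "re")
  check_finite(im, "im")
  structure(list(re = re, im = im), class = "complex_spectrum")
}

#' Polar (magnitude/phase) spectrum
#'
#' @param magnitude Nonnegative array of spectral magnitudes.
#' @param phase Array of angles; raw spectra lie in (-pi, pi], attended
#'   (convolution-processed) variants may leave that range and are consumed
#'   through the 2*pi-periodic `cos`/`sin` only.
#' @param attended Logical flag distinguishing raw from processed spectra.
#' @return An object of class `polar_spectrum`.
#' @export
polar_spectrum <- function(magnitude, phase, attended = FALSE) {
  check_finite(magnitude, "magnitude")
  check_finite(phase, "phase")
  if (any(magnitude < 0))
    stop("polar_spectrum: magnitude must be nonnegative everywhere")
  structure(list(magnitude = magnitude, phase = phase, attended = attended),
            class = "polar_spectrum")
}

#' Forward 2-D discrete Fourier transform
#'
#' Computes the unnormalized forward DFT of a real grid over its two spatial
#' axes (the first two array dimensions), independently per channel and
#' sample.
#'
#' @param grid Numeric array of shape `(H, W)`, `(H, W, C)` or
#'   `(H, W, C, N)` with all values finite.
#' @return A [complex_spectrum] of the same shape.
#' @examples
#' sp <- fft2d(matrix(3, 2, 2))
#' sp$re[1, 1]   # DC term = 12; every other entry is 0
#' @export
fft2d <- function(grid) {
  grid <- as_grid_array(grid)
  check_finite_grid(grid, "fft2d")
  g4 <- to4d(grid)
  z <- apply_fft(g4$a, inverse = FALSE, normalize = FALSE)
  complex_spectrum(restore_dim(Re(z), g4$d), restore_dim(Im(z), g4$d))
}

#' Inverse 2-D discrete Fourier transform
#'
#' Applies the 1/(N*M)-normalized inverse DFT and returns the real part.
#' The magnitude of the discarded imaginary residue is attached as the
#' `"imag_residue"` attribute; a residue above `1e-4 * max(abs(output))`
#' raises a warning, since for spectra of real images it should vanish to
#' rounding error and a large value signals upstream corruption.
#'
#' @param spec A [complex_spectrum].
#' @return Real array of the originating shape.
#' @export
ifft2d <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  if (length(spec$re) == 0L) stop("ifft2d: spectrum has zero extent")
  g4 <- to4d(as_grid_array(spec$re))
  i4 <- to4d(as_grid_array(spec$im))
  z <- apply_fft(g4$a + 1i * i4$a, inverse = TRUE, normalize = TRUE)
  out <- restore_dim(Re(z), g4$d)
  residue <- max(abs(Im(z)))
  scale <- max(abs(out))
  if (scale > 0 && residue > 1e-4 * scale)
    warning(sprintf(
      "ifft2d: imaginary residue %.3g exceeds 1e-4 of output scale %.3g",
      residue, scale))
  attr(out, "imag_residue") <- residue
  out
}

#' Convert a complex spectrum to magnitude and phase
#'
#' Magnitude is `sqrt(re^2 + im^2)`; phase is the quadrant-aware
#' two-argument angle `atan2(im, re)` in (-pi, pi].
#'
#' @param spec A [complex_spectrum].
#' @return A [polar_spectrum] with `attended = FALSE`.
#' @export
to_polar <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  polar_spectrum(sqrt(spec$re^2 + spec$im^2), atan2(spec$im, spec$re))
}

#' Reconstruct a complex spectrum from magnitude and phase
#'
#' `re = magnitude * cos(phase)`, `im = magnitude * sin(phase)`.
#'
#' @param polar A [polar_spectrum]; negative magnitudes are rejected.
#' @return A [complex_spectrum].
#' @export
from_polar <- function(polar) {
  stopifnot(inherits(polar, "polar_spectrum"))
  if (any(polar$magnitude < 0))
    stop("from_polar: negative magnitude entries violate the polar form")
  complex_spectrum(polar$magnitude * cos(polar$phase),
                   polar$magnitude * sin(polar$phase))
}

## ---- shape helpers ----------------------------------------------------------

as_grid_array <- function(x) {
  if (is.null(dim(x))) stop("expected a matrix or array with >= 2 dimensions")
  if (length(dim(x)) > 4L) stop("at most 4 dimensions (H, W, C, N) supported")
  x
}

# canonicalize to (H, W, C, N), remembering the original dim
to4d <- function(x) {
  d <- dim(x)
  a <- x
  dim(a) <- c(d, rep(1L, 4L - length(d)))
  list(a = a, d = d)
}

restore_dim <- function(a, d) {
  dim(a) <- d
  a
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
}

# diagnostic naming the offending axis position
check_finite_grid <- function(x, where) {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    stop(sprintf("%s: non-finite value at (%s)", where,
                 paste(bad[1, ], collapse = ", ")))
  }
}
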