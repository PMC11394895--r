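test_that("constant and impulse inputs have the expected spectra", {
  sp <- fft2d(matrix(3, 2, 2))
  expect_equal(sp$re[1, 1], 12, tolerance = 1e-12)
  expect_lt(max(abs(sp$re[-1])), 1e-12)
  expect_lt(max(abs(sp$im)), 1e-12)

  imp <- matrix(0, 4, 4); imp[1, 1] <- 1
  sp2 <- fft2d(imp)
  expect_equal(sp2$re, matrix(1, 4, 4), tolerance = 1e-12)
  expect_lt(max(abs(sp2$im)), 1e-12)
})

test_that("forward transform matches the literal double-sum on all grids up to 8x8", {
  set.seed(11)
  for (H in 1:8) for (W in 1:8) {
    x <- rand_grid(H, W)
    sp <- fft2d(x)
    z <- naive_dft2(x)
    expect_lt(max(abs(sp$re - Re(z))), 1e-9)
    expect_lt(max(abs(sp$im - Im(z))), 1e-9)
  }
})

test_that("inverse transform matches the literal double-sum and the DC case", {
  set.seed(12)
  zr <- rand_grid(8, 8); zi <- rand_grid(8, 8)
  # an arbitrary complex spectrum legitimately carries an imaginary residue
  expect_warning(got <- ifft2d(complex_spectrum(zr, zi)),
                 "imaginary residue")
  want <- naive_idft2(zr + 1i * zi)
  expect_lt(max(abs(got - Re(want))), 1e-9)
  expect_equal(attr(got, "imag_residue"), max(abs(Im(want))),
               tolerance = 1e-9)

  dc <- matrix(0, 5, 3); dc[1, 1] <- 5 * 3 * 2.5
  expect_equal(ifft2d(complex_spectrum(dc, dc * 0)),
               matrix(2.5, 5, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("round trip and Parseval hold for grids up to 64x64", {
  set.seed(13)
  for (H in c(3, 16, 33, 64)) {
    x <- rand_grid(H, H)
    sp <- fft2d(x)
    back <- ifft2d(sp)
    expect_lt(max(abs(back - x)) / max(abs(x)), 1e-6)
    expect_equal(sum(x^2), sum(sp$re^2 + sp$im^2) / (H * H),
                 tolerance = 1e-5)
  }
  # channel/batch axes are handled independently
  x4 <- rand_grid(8, 8, 3, 2)
  back4 <- ifft2d(fft2d(x4))
  expect_lt(max(abs(back4 - x4)), 1e-6)
  one <- ifft2d(fft2d(x4[, , 2, 1]))
  expect_lt(max(abs(back4[, , 2, 1] - one)), 1e-10)
})

test_that("polar conversion is quadrant-aware and lossless", {
  sp <- complex_spectrum(matrix(3, 1, 1), matrix(4, 1, 1))
  p <- to_polar(sp)
  expect_equal(p$magnitude[1, 1], 5)
  expect_equal(p$phase[1, 1], atan2(4, 3), tolerance = 1e-7)
  expect_equal(p$phase[1, 1], 0.9272952, tolerance = 1e-6)

  neg <- to_polar(complex_spectrum(matrix(-2, 1, 1), matrix(0, 1, 1)))
  expect_equal(neg$magnitude[1, 1], 2)
  expect_equal(neg$phase[1, 1], pi)

  set.seed(14)
  sp3 <- complex_spectrum(rand_grid(6, 7), rand_grid(6, 7))
  p3 <- to_polar(sp3)
  expect_lt(max(abs(p3$magnitude^2 - (sp3$re^2 + sp3$im^2))), 1e-9)

  back <- from_polar(polar_spectrum(matrix(5, 1, 1),
                                    matrix(0.92729522, 1, 1)))
  expect_equal(back$re[1, 1], 3, tolerance = 1e-6)
  expect_equal(back$im[1, 1], 4, tolerance = 1e-6)

  z <- from_polar(polar_spectrum(matrix(0, 2, 2), rand_grid(2, 2)))
  expect_true(all(z$re == 0) && all(z$im == 0))

  for (i in 1:100) {
    spr <- complex_spectrum(rand_grid(4, 5), rand_grid(4, 5))
    rt <- from_polar(to_polar(spr))
    expect_lt(max(abs(rt$re - spr$re), abs(rt$im - spr$im)), 1e-9)
  }
})

test_that("invalid spectra and grids are rejected with diagnostics", {
  x <- matrix(1, 3, 3); x[2, 3] <- NaN
  expect_error(fft2d(x), "non-finite value at \\(2, 3\\)")
  expect_error(from_polar(polar_spectrum(matrix(1, 2, 2), matrix(0, 2, 2))),
               NA)
  expect_error(polar_spectrum(matrix(-1, 2, 2), matrix(0, 2, 2)),
               "nonnegative")
  bad <- structure(list(re = matrix(numeric(0), 0, 0),
                        im = matrix(numeric(0), 0, 0)),
                   class = "complex_spectrum")
  expect_error(ifft2d(bad), "zero extent")
})
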