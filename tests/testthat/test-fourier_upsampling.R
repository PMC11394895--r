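test_that("cyclic padding is a 2x2 periodic tiling", {
  set.seed(41)
  p <- to_polar(fft2d(rand_grid(4, 4, 1)))
  pp <- cyclic_pad_spectrum(p)
  expect_equal(dim(pp$magnitude), c(8, 8, 1))
  for (qr in 0:1) for (qc in 0:1) {
    expect_equal(pp$magnitude[qr * 4 + 1:4, qc * 4 + 1:4, 1],
                 p$magnitude[, , 1])
    expect_equal(pp$phase[qr * 4 + 1:4, qc * 4 + 1:4, 1], p$phase[, , 1])
  }
  # index arithmetic: entry (2, 3) 1-based replicates at the four offsets
  v <- pp$magnitude[2, 3, 1]
  expect_equal(pp$magnitude[6, 3, 1], v)
  expect_equal(pp$magnitude[2, 7, 1], v)
  expect_equal(pp$magnitude[6, 7, 1], v)

  # odd sizes against an explicit double-loop tiling
  m <- rand_grid(5, 7); ph <- rand_grid(5, 7)
  pol <- polar_spectrum(abs(m), ph)
  t2 <- cyclic_pad_spectrum(pol)
  for (k in 1:10) for (l in 1:14) {
    expect_equal(t2$magnitude[k, l], abs(m)[(k - 1) %% 5 + 1, (l - 1) %% 7 + 1])
    expect_equal(t2$phase[k, l], ph[(k - 1) %% 5 + 1, (l - 1) %% 7 + 1])
  }
})

test_that("conv-bypass up-sampling is exactly zero-interleaving", {
  set.seed(42)
  for (H in c(3, 8, 17, 32)) {
    x <- rand_grid(H, H, 2, 1)
    y <- fourier_upsample_forward(x)
    expect_equal(dim(y), c(2 * H, 2 * H, 2, 1))
    ev <- seq(1, 2 * H, by = 2)
    od <- seq(2, 2 * H, by = 2)
    expect_lt(max(abs(y[ev, ev, , , drop = FALSE] - x)), 1e-6)
    expect_lt(max(abs(y[od, , , , drop = FALSE])), 1e-6)
    expect_lt(max(abs(y[, od, , , drop = FALSE])), 1e-6)
    expect_equal(sum(y^2), sum(x^2), tolerance = 1e-6)
  }
})

test_that("zero input, shape contract and identity convolution", {
  set.seed(43)
  z <- fourier_upsample_forward(array(0, c(8, 8, 3, 1)))
  expect_true(all(z == 0))

  x <- rand_grid(16, 16, 3, 1)
  w <- fourier_upsample_weights(3)
  y <- fourier_upsample_forward(x, w)
  expect_equal(dim(y), c(32, 32, 3, 1))
  expect_true(all(is.finite(y)))

  wid <- fourier_upsample_weights(3, init = "identity")
  expect_lt(max(abs(fourier_upsample_forward(x, wid) -
                      fourier_upsample_forward(x))), 1e-8)

  expect_error(fourier_upsample_forward(x, fourier_upsample_weights(5)),
               "channels")
})
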