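test_that("vALD and GAD match hand computations", {
  u <- matrix(42, 6, 6)
  st <- compute_vald(u)
  expect_true(all(st$vald == 0))
  expect_equal(st$gad, 0)

  img <- matrix(0, 3, 3); img[2, 2] <- 90
  st2 <- compute_vald(img)
  expect_equal(st2$vald[2, 2], 80)  # centre mean 90/9 = 10
  expect_error(compute_vald(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("vALD, flat mask and window statistics reproduce the loop oracles exactly", {
  set.seed(61)
  for (rep in 1:100) {
    H <- sample(8:16, 1); W <- sample(8:16, 1)
    img <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    inc <- rep %% 2 == 0
    st <- compute_vald(img, include_center = inc)
    o <- oracle_vald(img, include_center = inc)
    expect_identical(st$vald, o$vald)
    expect_identical(st$gad, o$gad)

    mk <- mark_flat_regions(img, include_center = inc)
    expect_identical(unclass(mk), oracle_flat_mask(img, include_center = inc))

    cfg <- sorting_config(window = 4L, stride = 2L)
    a <- assess_flat_mask(mk, cfg)
    ow <- oracle_windows(unclass(mk), 4L, 2L, cfg$window_black_thresh)
    expect_identical(a$global_black, ow$global_black)
    expect_identical(as.vector(t(a$window_props)), ow$props)
    expect_identical(a$max_window, ow$max_window)
    expect_identical(a$scattered_fraction, ow$scattered_fraction)
  }
})

test_that("uniform images are fully flat and checkerboards fully non-flat", {
  expect_true(all(unclass(mark_flat_regions(matrix(7, 5, 5))) == 255))
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) * 255)
  expect_true(all(unclass(mark_flat_regions(cb)) == 0))
})

test_that("flat marking is invariant to adding a constant", {
  set.seed(62)
  img <- matrix(sample(0:200, 100, replace = TRUE), 10, 10)
  expect_identical(unclass(mark_flat_regions(img)),
                   unclass(mark_flat_regions(img + 37)))
})

test_that("window statistics on canonical masks", {
  cfg <- sorting_config(window = 4L, stride = 4L)
  white <- matrix(255, 8, 8)
  a <- assess_flat_mask(white, cfg)
  expect_equal(a$global_black, 0)
  expect_true(all(a$window_props == 0))

  black <- matrix(0, 8, 8)
  b <- assess_flat_mask(black, cfg)
  expect_equal(b$global_black, 1)
  expect_true(all(b$window_props == 1))

  quarter <- matrix(255, 8, 8); quarter[1:4, 1:4] <- 0
  q <- assess_flat_mask(quarter, cfg)
  expect_equal(q$global_black, 0.25)
  expect_setequal(as.vector(q$window_props), c(1, 0, 0, 0))

  expect_error(assess_flat_mask(matrix(0, 4, 4), sorting_config(window = 8L)),
               "window larger")
})

test_that("the accept decision follows the documented tie rules and reasons", {
  cfg <- sorting_config(window = 4L, stride = 4L, global_thresh = 0.25,
                        scatter_thresh = 0.25)
  white <- matrix(255, 8, 8)
  expect_equal(select_high_quality(white, cfg)$decision, "high-quality")

  black <- matrix(0, 8, 8)
  v <- select_high_quality(black, cfg)
  expect_equal(v$decision, "rejected")
  expect_equal(v$reason, "global_black_proportion")

  # global proportion exactly at the threshold is accepted (<= convention)
  quarter <- matrix(255, 8, 8); quarter[1:4, 1:4] <- 0
  vq <- select_high_quality(quarter, cfg)
  expect_equal(vq$global_black, 0.25)
  expect_equal(vq$decision, "high-quality")
})

test_that("blackening pixels never flips a rejection to acceptance", {
  set.seed(63)
  cfg <- sorting_config(window = 4L, stride = 4L)
  for (rep in 1:50) {
    mask <- matrix(sample(c(0, 255), 64, replace = TRUE, prob = c(0.4, 0.6)),
                   8, 8)
    v0 <- select_high_quality(mask, cfg)
    whites <- which(mask == 255)
    if (v0$decision == "rejected" && length(whites)) {
      mask[sample(whites, 1)] <- 0
      expect_equal(select_high_quality(mask, cfg)$decision, "rejected")
    }
  }
})

test_that("grayscale conversion uses the standard luma weights", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- 1
  expect_equal(to_grayscale(img), matrix(0.299 * 255, 2, 2))
  img[, , 2] <- 1; img[, , 3] <- 1
  expect_equal(to_grayscale(img), matrix(255, 2, 2))
})

test_that("uniform fixtures are accepted and mottled fixtures rejected", {
  set.seed(64)
  acc <- rej <- 0L
  for (i in 1:40) {
    if (sort_granule(peppersort:::granule_crop(64, "mature"))$decision ==
        "high-quality") acc <- acc + 1L
    if (sort_granule(peppersort:::granule_crop(64, "semi-mature"))$decision ==
        "rejected") rej <- rej + 1L
  }
  expect_gte(acc / 40, 0.95)
  expect_gte(rej / 40, 0.95)
})

test_that("front/back pair fusion is conservative", {
  set.seed(65)
  good <- peppersort:::granule_crop(64, "mature")
  bad <- peppersort:::granule_crop(64, "semi-mature")
  expect_equal(sort_cluster_pair(good, good)$decision, "high-quality")
  expect_equal(sort_cluster_pair(good, bad)$decision, "rejected")
  one_sided <- sorting_config(both_views = FALSE)
  expect_equal(sort_cluster_pair(good, bad, one_sided)$decision,
               "high-quality")
})
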