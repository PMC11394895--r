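test_that("cluster scenes honour the spec contract and are deterministic", {
  sp <- scene_spec(size = 96, n_granules = 5, seed = 7)
  s1 <- generate_cluster_scene(sp)
  expect_length(s1$labels, 5)
  for (poly in s1$labels) {
    expect_gte(nrow(poly), 8)
    expect_true(all(poly >= 0 & poly <= 1))
  }
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  s2 <- generate_cluster_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$classes, s2$classes)

  all_mat <- generate_cluster_scene(scene_spec(size = 96, n_granules = 4,
                                               maturity_mix = 1, seed = 3))
  expect_true(all(all_mat$classes == "mature"))
  expect_true(all(all_mat$class_index == 0L))
})

test_that("every polygon rasterizes to a nonempty region inside the canvas", {
  sp <- scene_spec(size = 128, n_granules = 6, seed = 11)
  s <- generate_cluster_scene(sp)
  for (poly in s$labels) {
    m <- rasterize_polygon(poly, 128, 128)
    expect_gt(sum(m), 0)
    # nothing on the canvas border
    expect_true(all(poly > 0 & poly < 1))
  }
})

test_that("impossible packings fail after bounded retries", {
  sp <- scene_spec(size = 64, n_granules = 40, radius_range = c(14, 16),
                   seed = 1)
  expect_error(generate_cluster_scene(sp), "pack")
})

test_that("class-conditional color statistics are widely separated", {
  set.seed(81)
  gmean <- function(cl) replicate(20, {
    img <- peppersort:::granule_crop(32, cl)
    mean(img[, , 2][img[, , 1] > 0.05])   # green channel on the granule
  })
  mat <- gmean("mature"); semi <- gmean("semi-mature")
  gap <- abs(mean(semi) - mean(mat))
  noise <- max(stats::sd(mat), stats::sd(semi))
  expect_gte(gap / noise, 5)
})

test_that("the on-disk dataset has the requested split and identical bytes per seed", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_cls_dataset(d1, n_per_class = 10, size = 24, split = 0.8,
                             seed = 4)
  m2 <- generate_cls_dataset(d2, n_per_class = 10, size = 24, split = 0.8,
                             seed = 4)
  tr <- list.files(file.path(d1, "train"), recursive = TRUE)
  va <- list.files(file.path(d1, "val"), recursive = TRUE)
  expect_length(tr, 16)
  expect_length(va, 4)
  expect_equal(sum(grepl("^mature", tr)), 8)

  f1 <- sort(list.files(d1, recursive = TRUE, full.names = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_identical(lapply(f1, function(f) readBin(f, "raw", 1e6)),
                   lapply(f2, function(f) readBin(f, "raw", 1e6)))

  ds <- load_cls_dataset(d1)
  expect_equal(dim(ds$train$x), c(24, 24, 3, 16))
  expect_equal(sort(unique(ds$train$y)), c(1, 2))
})
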