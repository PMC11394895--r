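smoke_cfg <- function(widths = c(4L, 8L), seed = 1L, ...) {
  model_config("classification", nc = 2, input_size = 16, widths = widths,
               use_repncspelan4 = FALSE, use_adown = FALSE,
               use_c2fse = FALSE, seed = seed, ...)
}

tiny_ds <- function(n = 8L, size = 16L, seed = 5L) {
  generate_cls_data(n_per_class = n, size = size, split = 0.5, seed = seed)
}

test_that("parameter counting matches hand counts", {
  set.seed(51)
  conv <- peppersort:::nn_conv(3, 16, 3, bn = FALSE, bias = TRUE)
  expect_equal(as.integer(param_count(conv)), 3 * 3 * 3 * 16 + 16)
  aff <- peppersort:::nn_linear(10, 2)
  expect_equal(as.integer(param_count(aff)), 22)
  expect_equal(as.integer(param_count(list())), 0)
  expect_equal(attr(param_count(aff), "MB"), 22 * 4 / 1e6)
})

test_that("classification output is a probability distribution and batch-stable", {
  m <- build_model(smoke_cfg())
  set.seed(52)
  x <- array(stats::runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  p <- predict(m, x)
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(is.finite(p)))
  # per-sample independence under permutation (eval-mode batch norm)
  p2 <- predict(m, x[, , , c(3, 1, 2), drop = FALSE])
  expect_equal(p2, p[c(3, 1, 2), ], tolerance = 1e-10)
})

test_that("construction is deterministic given the seed", {
  vals <- function(m) lapply(m$params, function(p) p$value)
  expect_identical(vals(build_model(smoke_cfg(seed = 7))),
                   vals(build_model(smoke_cfg(seed = 7))))
  expect_false(identical(vals(build_model(smoke_cfg(seed = 7))),
                         vals(build_model(smoke_cfg(seed = 8)))))
})

test_that("invalid insertion stages are rejected naming the stage", {
  expect_error(smoke_cfg(msf3m_stages = 5L), "stage 5")
  expect_error(smoke_cfg(msdffm_stages = 0L), "stage 0")
})

test_that("removing MSF3M and MS-DFFM strictly shrinks the model", {
  full <- build_model(smoke_cfg())
  bare <- build_model(smoke_cfg(msdffm_stages = integer(0),
                                msf3m_stages = integer(0)))
  expect_lt(as.integer(param_count(bare)), as.integer(param_count(full)))
})

test_that("an untrained segmentation model returns an empty prediction set", {
  cfg <- model_config("segmentation", nc = 2, input_size = 32,
                      widths = c(4L, 6L, 8L, 10L), seed = 2)
  m <- build_model(cfg)
  set.seed(53)
  img <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  pr <- predict(m, img)
  expect_length(pr, 1)
  expect_equal(nrow(pr[[1]]$detections), 0)
  expect_length(pr[[1]]$polygons, 0)
})

test_that("GFLOPs tracing covers convolution and affine layers", {
  m <- build_model(smoke_cfg())
  tab <- model_gflops(m, 16)
  expect_true(attr(tab, "total") > 0)
  expect_true(any(tab$kh == 21 | tab$kw == 21))  # MSF3M strip convs traced
  expect_true(any(tab$X == 1 & tab$kh == 1))     # classifier affine traced
})

test_that("early stopping runs best + patience epochs on a frozen model", {
  m <- build_model(smoke_cfg())
  r <- train_smoke(m, tiny_ds(), epochs = 10, patience = 3, lr0 = 0,
                   batch_size = 8)
  expect_equal(r$epochs_run, 4)
})

test_that("identical seeds give identical training histories", {
  ds <- tiny_ds()
  r1 <- train_smoke(build_model(smoke_cfg(seed = 3)), ds, epochs = 2,
                    patience = 5, batch_size = 8)
  r2 <- train_smoke(build_model(smoke_cfg(seed = 3)), ds, epochs = 2,
                    patience = 5, batch_size = 8)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_identical(r1$history$val_loss, r2$history$val_loss)
})

test_that("training loss falls over the first five epochs in at least 90% of seeded runs", {
  ds <- generate_cls_data(n_per_class = 80, size = 48, split = 0.8, seed = 5)
  ok <- 0L
  for (s in 1:10) {
    cfg <- model_config("classification", nc = 2, input_size = 48,
                        widths = c(6L, 12L, 24L), seed = s,
                        use_repncspelan4 = FALSE, use_adown = FALSE,
                        use_c2fse = FALSE)
    r <- train_smoke(build_model(cfg), ds, epochs = 5, patience = 10)
    tl <- r$history$train_loss
    if (tl[5] < tl[1]) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("empty datasets are rejected", {
  m <- build_model(smoke_cfg())
  expect_error(train_smoke(m, list(train = list(x = array(0, c(16, 16, 3, 0)),
                                                y = integer(0)),
                                   val = list(x = array(0, c(16, 16, 3, 0)),
                                              y = integer(0)))),
               "empty dataset")
})

test_that("checkpoints round-trip through save/load", {
  m <- build_model(smoke_cfg(seed = 9))
  set.seed(54)
  x <- array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p0 <- predict(m, x)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, x), p0, tolerance = 1e-12)
})
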