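test_that("convolution GFLOPs formula and worked value", {
  expect_identical(conv_gflops(640, 640, 3, 16, 3),
                   640 * 640 * 16 * 28 / 1e9)
  expect_equal(conv_gflops(640, 640, 3, 16, 3), 0.1835008)
  expect_equal(conv_gflops(10, 10, 4, 0, 3), 0)
})

test_that("GFLOPs agree with the multiply-accumulate counting oracle", {
  set.seed(71)
  for (k in c(1, 3, 5)) {
    X <- sample(4:16, 1); Y <- sample(4:16, 1)
    ci <- sample(1:8, 1); co <- sample(1:8, 1)
    expect_equal(conv_gflops(X, Y, ci, co, k), oracle_mac_count(X, Y, ci, co, k))
    g <- sample(c(1, ci), 1)
    expect_equal(conv_gflops(X, Y, ci, co, k, groups = g),
                 oracle_mac_count(X, Y, ci, co, k, groups = g))
  }
})

test_that("precision and recall with explicit undefined-metric errors", {
  pr <- precision_recall(50, 50, 0)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 1)
  pr2 <- precision_recall(8, 2, 2)
  expect_equal(pr2$precision, 0.8)
  expect_equal(pr2$recall, 0.8)
  expect_error(precision_recall(0, 0, 3), "precision undefined")
  expect_error(precision_recall(0, 2, 0), "recall undefined")
})

test_that("FPS follows the mean-duration convention", {
  expect_equal(fps_from_times(0.01), 100)
  expect_equal(fps_from_times(1), 1)
  expect_equal(fps_from_times(c(0.005, 0.015)), 100)
  expect_error(fps_from_times(numeric(0)), "empty")
  expect_error(fps_from_times(c(0.1, 0)), "positive")
})

box_df <- function(image, class, conf, x1, y1, x2, y2) {
  data.frame(image = image, class = class, conf = conf,
             x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

test_that("a perfect detector scores mAP50 = 1 and an empty one 0", {
  truth <- box_df(c(1, 1, 2), c(0, 1, 0), 1,
                  c(0.1, 0.5, 0.2), c(0.1, 0.5, 0.2),
                  c(0.3, 0.7, 0.4), c(0.3, 0.7, 0.4))
  pred <- truth
  pred$conf <- 1
  expect_equal(as.numeric(map50(pred, truth)), 1)

  none <- box_df(integer(0), integer(0), numeric(0), numeric(0),
                 numeric(0), numeric(0), numeric(0))
  expect_equal(as.numeric(map50(none, truth)), 0)
})

test_that("the hit/miss/hit toy set integrates like the exhaustive PR oracle", {
  truth <- box_df(c(1, 1), c(0, 0), 1,
                  c(0.0, 0.5), c(0.0, 0.5), c(0.2, 0.7), c(0.2, 0.7))
  pred <- box_df(c(1, 1, 1), c(0, 0, 0), c(0.9, 0.8, 0.7),
                 c(0.0, 0.8, 0.5), c(0.0, 0.8, 0.5),
                 c(0.2, 0.9, 0.7), c(0.2, 0.9, 0.7))
  got <- as.numeric(map50(pred, truth))
  expect_equal(got, oracle_ap(c(1, 0, 1), 2))
  expect_equal(got, 5 / 6, tolerance = 1e-12)
})

test_that("removing a correct prediction never increases mAP50", {
  truth <- box_df(c(1, 1), c(0, 0), 1,
                  c(0.0, 0.5), c(0.0, 0.5), c(0.2, 0.7), c(0.2, 0.7))
  pred <- box_df(c(1, 1), c(0, 0), c(0.9, 0.7),
                 c(0.0, 0.5), c(0.0, 0.5), c(0.2, 0.7), c(0.2, 0.7))
  full <- as.numeric(map50(pred, truth))
  expect_lte(as.numeric(map50(pred[-1, ], truth)), full)
})

test_that("classes without ground truth are excluded with a warning", {
  truth <- box_df(1, 0, 1, 0.1, 0.1, 0.3, 0.3)
  pred <- box_df(c(1, 1), c(0, 5), c(0.9, 0.9),
                 c(0.1, 0.5), c(0.1, 0.5), c(0.3, 0.7), c(0.3, 0.7))
  expect_warning(m <- map50(pred, truth), "without ground truth")
  expect_equal(as.numeric(m), 1)
})

test_that("polygon IoU matching works through rasterization", {
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  truth <- data.frame(image = 1, class = 0)
  pred <- data.frame(image = 1, class = 0, conf = 0.9)
  m <- map50(pred, truth, pred_shapes = list(sq(0.1, 0.1, 0.4)),
             truth_shapes = list(sq(0.1, 0.1, 0.4)), shape = "polygon")
  expect_equal(as.numeric(m), 1)
  m2 <- map50(pred, truth, pred_shapes = list(sq(0.6, 0.6, 0.3)),
              truth_shapes = list(sq(0.1, 0.1, 0.4)), shape = "polygon")
  expect_equal(as.numeric(m2), 0)
})
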