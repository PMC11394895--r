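test_that("branch preserves shape and is annihilated by zero weights", {
  set.seed(21)
  x <- rand_grid(16, 16, 8, 2)
  br <- msf3m_branch_weights(8)
  expect_equal(dim(multiscale_freq_branch(x, br)), dim(x))

  zero <- msf3m_branch_weights(8, init = "zero")
  expect_true(all(multiscale_freq_branch(x, zero) == 0))
})

test_that("delta-kernel branch is the identity map", {
  set.seed(22)
  x <- rand_grid(12, 10, 4, 1)
  idb <- msf3m_branch_weights(4, init = "identity")
  expect_lt(max(abs(multiscale_freq_branch(x, idb) - x)), 1e-5)
})

test_that("full layer preserves shape, maps zero to zero, and squares under delta kernels", {
  set.seed(23)
  w <- msf3m_weights(8)
  x <- rand_grid(16, 16, 8, 2)
  expect_equal(dim(msf3m_forward(x, w)), dim(x))
  expect_true(all(msf3m_forward(x * 0, w) == 0))

  wid <- msf3m_identity_weights(8)
  expect_lt(max(abs(msf3m_forward(x, wid) - x * x)), 1e-4)
})

test_that("channel mismatch is rejected", {
  x <- rand_grid(8, 8, 3, 1)
  expect_error(msf3m_forward(x, msf3m_weights(5)), "channels")
  expect_error(multiscale_freq_branch(x, msf3m_branch_weights(4)),
               "channels")
})

test_that("output is invariant to batch permutation", {
  set.seed(24)
  w <- msf3m_weights(3)
  x <- rand_grid(8, 8, 3, 4)
  y <- msf3m_forward(x, w)
  perm <- c(3, 1, 4, 2)
  yp <- msf3m_forward(x[, , , perm, drop = FALSE], w)
  expect_equal(yp, y[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(25)
  w <- msf3m_weights(2)
  x <- rand_grid(6, 6, 2, 1)
  loss_of <- function() {
    tape <- peppersort:::ag_tape()
    out <- peppersort:::msf3m_node(tape, peppersort:::ag_node(tape, x), w)
    s <- peppersort:::ag_node(tape, sum(out$value^2), list(out),
                              function(nd) list(2 * nd$parents[[1]]$value *
                                                  nd$grad))
    list(tape = tape, loss = s)
  }
  r <- loss_of()
  params <- peppersort:::collect_params(w)
  peppersort:::ag_zero_grads(params)
  peppersort:::ag_backward(r$tape, r$loss)
  eps <- 1e-5
  set.seed(26)
  for (p in params[sample(length(params), 4)]) {
    k <- sample(length(p$value), 1)
    g_analytic <- p$grad[k]
    old <- p$value[k]
    p$value[k] <- old + eps
    lp <- loss_of()$loss$value
    p$value[k] <- old - eps
    lm <- loss_of()$loss$value
    p$value[k] <- old
    g_fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_analytic - g_fd) / max(abs(g_fd), 1e-3), 1e-3)
  }
})

test_that("non-finite input yields a staged diagnostic", {
  x <- rand_grid(4, 4, 2, 1)
  x[1, 1, 1, 1] <- Inf
  expect_error(msf3m_forward(x, msf3m_weights(2)), "non-finite")
})
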