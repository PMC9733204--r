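test_that("action distribution is the softmax of A %*% h", {
  params <- stack_cell_params(1L, 1L, 1L, init_scale = 0)
  params$A <- matrix(c(0, 0, 0), 3, 1)
  expect_equal(as.numeric(action_distribution(1, params)), rep(1 / 3, 3))
  params$A <- matrix(c(log(2), 0, 0), 3, 1)
  expect_equal(as.numeric(action_distribution(1, params)), c(0.5, 0.25, 0.25))
  set.seed(1)
  params$A <- matrix(rnorm(3), 3, 1)
  expect_equal(sum(action_distribution(rnorm(1), params)), 1)
  expect_error(action_distribution(c(1, 2), params), "length")
})

test_that("soft stack update blends push/pop/noop as specified", {
  prev <- matrix(c(0.2, 0.5, 0.0), 3, 1)
  expect_identical(update_stack(prev, c(0, 0, 1), 0.9), prev)
  expect_equal(as.numeric(update_stack(prev, c(1, 0, 0), 0.9)), c(0.9, 0.2, 0.5))
  expect_equal(as.numeric(update_stack(prev, c(0, 1, 0), 0)), c(0.5, 0.0, 0.0))
  half <- update_stack(prev, c(0.5, 0.5, 0), 1.0)
  expect_equal(half[1, 1], 0.5 * 1.0 + 0.5 * 0.5)
  expect_error(update_stack(prev, c(0.5, 0.2, 0.2), 0), "probability")
})

test_that("hidden update reads the stack top through P", {
  params <- stack_cell_params(2L, 1L, 3L, init_scale = 0)
  h <- update_hidden(numeric(3), numeric(2), matrix(0, 4, 1), params)
  expect_equal(h, c(0.5, 0.5))
  params$P <- matrix(log(3), 2, 1)
  s <- matrix(0, 4, 1); s[1, 1] <- 1
  expect_equal(update_hidden(numeric(3), numeric(2), s, params), c(0.75, 0.75))
  set.seed(2)
  params <- stack_cell_params(5L, 2L, 3L, init_scale = 2)
  h <- update_hidden(rnorm(3), rnorm(5), matrix(runif(8), 4, 2), params)
  expect_true(all(h > 0 & h < 1))
})

test_that("discrete pushdown oracle implements literal stack semantics", {
  init <- matrix(c(0.2, 0.5, 0.0), 3, 1)
  noops <- replicate(5, list(op = "noop"), simplify = FALSE)
  expect_identical(pushdown_oracle(init, noops), init)
  empty <- matrix(0, 3, 1)
  out <- pushdown_oracle(empty, list(list(op = "push", value = 0.3),
                                     list(op = "push", value = 0.7)))
  expect_equal(as.numeric(out), c(0.7, 0.3, 0))
  # push-then-pop is the identity when nothing is lost off the bottom
  out2 <- pushdown_oracle(init, list(list(op = "push", value = 0.9),
                                     list(op = "pop")))
  expect_equal(out2, init)
  expect_error(pushdown_oracle(init, list(list(op = "rotate"))), "unknown")
})

test_that("continuous cell with one-hot actions equals the pushdown oracle", {
  set.seed(42)
  for (i in 1:200) {
    depth <- sample(1:10, 1)
    width <- sample(1:4, 1)
    len <- sample(1:50, 1)
    init <- matrix(round(runif(depth * width), 3), depth, width)
    trace <- random_onehot_trace(len, width)
    expect_identical(apply_onehot_continuous(init, trace),
                     pushdown_oracle(init, trace))
  }
})

test_that("stack entries stay in [0,1] and the update is linear in actions", {
  set.seed(7)
  for (i in 1:50) {
    prev <- matrix(runif(12), 4, 3)
    v <- runif(3)
    a1 <- c(1, 0, 0); a2 <- c(0, 0, 1)
    alpha <- runif(1)
    blend <- alpha * a1 + (1 - alpha) * a2
    s_blend <- update_stack(prev, blend, v)
    s_mix <- alpha * update_stack(prev, a1, v) +
      (1 - alpha) * update_stack(prev, a2, v)
    expect_equal(s_blend, s_mix, tolerance = 1e-12)
    expect_true(all(s_blend >= 0 & s_blend <= 1))
  }
})

test_that("analytic cell-step gradients match numerical differentiation", {
  set.seed(5)
  for (rep in 1:3) {
    m <- sample(3:6, 1); k <- sample(1:3, 1); p <- sample(2:4, 1)
    din <- sample(2:5, 1)
    params <- stack_cell_params(m, k, din, init_scale = 0.5)
    x <- rnorm(din); h0 <- runif(m); s0 <- matrix(runif(p * k), p, k)
    wh <- rnorm(m); ws <- matrix(rnorm(p * k), p, k)
    lossf <- function(pp) {
      out <- stackcvae:::.cell_forward(x, h0, s0, pp)
      sum(out$h * wh) + sum(out$stack * ws)
    }
    cache <- stackcvae:::.cell_forward(x, h0, s0, params)
    g <- stackcvae:::.cell_backward(cache, wh, ws, params,
                                    stackcvae:::.zero_like_cell(params))
    for (nm in c("A", "D", "U", "R", "P")) {
      idx <- sample(seq_along(params[[nm]]), min(5, length(params[[nm]])))
      for (i in idx) {
        e <- 1e-6
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + e; up <- lossf(pp)
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] - e; dn <- lossf(pp)
        gn <- (up - dn) / (2 * e)
        expect_lt(abs(gn - g$acc[[nm]][i]) / (abs(gn) + 1e-6), 1e-4)
      }
    }
  }
})

test_that("a forced PUSH trace fills the stack top-down with pushed values", {
  params <- stack_cell_params(4L, 1L, 2L, init_scale = 0.3)
  s <- matrix(0, 3, 1)
  vals <- c(0.3, 0.6, 0.9)
  for (v in vals) s <- update_stack(s, c(1, 0, 0), v)
  expect_equal(as.numeric(s), rev(vals))
})
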