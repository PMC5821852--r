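test_that("train statistics standardize both splits without leakage", {
  train <- list(x = c(2, 4, 6), Y = matrix(c(2, 4, 6, 1, 1, 1), 3, 2))
  test <- list(x = c(4, 8), Y = matrix(c(4, 8, 1, 1), 2, 2))
  std <- standardize_pair(train, test)
  s <- sqrt(mean((c(2, 4, 6) - 4)^2))
  expect_equal(std$train$x, (c(2, 4, 6) - 4) / s, tolerance = 1e-12)
  expect_equal(std$train$x[1], -1.2247448, tolerance = 1e-6)
  # test transformed with train statistics, not its own
  expect_equal(std$test$x, (c(4, 8) - 4) / s, tolerance = 1e-12)
  # zero-variance voxel flagged and zeroed
  expect_equal(std$flagged, 2L)
  expect_true(all(std$train$Y[, 2] == 0))

  # already-standardized input is unchanged
  x0 <- c(-1, 0, 1) / sqrt(2 / 3)
  Y0 <- matrix(x0, 3, 1)
  std2 <- standardize_pair(list(x = x0, Y = Y0))
  expect_equal(std2$train$x, x0, tolerance = 1e-12)
  expect_equal(std2$train$Y, Y0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("encoding slopes follow the closed-form least-squares solution", {
  x <- c(-1, 0, 1)
  expect_equal(fit_encoding(x, x)$beta, 1)
  expect_equal(fit_encoding(x, c(1, -2, 1))$beta, 0)
  expect_equal(fit_encoding(x, c(-2, 1, 1))$beta, 1.5)
  expect_error(fit_encoding(c(0, 0, 0), x), "zero")
  expect_equal(encode_roi(x, cbind(x, c(-2, 1, 1))), c(1, 1.5))
})

test_that("effective degrees of freedom behave as the ridge trace", {
  d <- c(2, 1, 0.5)
  expect_equal(edf_of_lambda(d, 0), 3)
  expect_equal(edf_of_lambda(1, 1), 0.5)
  expect_lt(edf_of_lambda(d, 1e9), 1e-8)
  lams <- c(0, 0.1, 1, 10, 100)
  vals <- vapply(lams, function(l) edf_of_lambda(d, l), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(edf_of_lambda(d, -1), "non-negative")
})

test_that("the df grid spans 0.1 to min(n, q) - 0.1 in 100 steps", {
  g <- edf_grid(1250, 550)
  expect_length(g, 100)
  expect_equal(g[1], 0.1)
  expect_equal(g[100], 549.9)
  expect_equal(unique(round(diff(g), 12)), round((550 - 0.2) / 99, 12))
  expect_error(edf_grid(0.1, 0.1), "too small")
})

test_that("the Newton solver hits df targets and matches a bisection oracle", {
  expect_equal(solve_lambda(1, 0.5), 1, tolerance = 1e-8)

  d <- c(2, 1)
  l <- solve_lambda(d, 1)
  expect_equal(l, bisect_lambda(d, 1), tolerance = 1e-6)

  set.seed(91)
  for (i in 1:5) {
    d <- sort(runif(8, 0.1, 5), decreasing = TRUE)
    for (t in c(0.5, 2, 5, 7.5)) {
      l <- solve_lambda(d, t)
      expect_lt(abs(edf_of_lambda(d, l) - t), 1e-6)
    }
  }
  expect_error(solve_lambda(c(2, 1), 2.5), "rank")

  # solved penalties decrease strictly along an increasing df grid
  d <- svd(matrix(rnorm(40 * 12), 40, 12))$d
  targets <- edf_grid(40, 12)
  lams <- vapply(targets[targets < 12 - 1e-8], function(t) solve_lambda(d, t),
                 numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("the closed-form LOO shortcut equals explicit refitting", {
  set.seed(92)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  x <- rnorm(12)
  for (lam in c(0.5, 2, 10))
    expect_equal(loo_error(Y, x, lam), naive_loo_error(Y, x, lam),
                 tolerance = 1e-8)

  # shrinkage limit: predictions collapse to zero, error to mean(x^2)
  expect_equal(loo_error(Y, x, 1e12), mean(x^2), tolerance = 1e-3)

  # duplicated trials with consistent targets beat a shuffled-target control
  set.seed(93)
  Yd <- matrix(rnorm(8 * 3), 8, 3)[rep(1:8, 2), ]
  xd <- rnorm(8)[rep(1:8, 2)]
  expect_lt(loo_error(Yd, xd, 1),
            loo_error(Yd, sample(xd), 1))
})

test_that("ridge decoding selects a penalty by LOO and recovers planted models", {
  set.seed(94)
  n <- 60; q <- 10
  Y <- matrix(rnorm(n * q), n, q)
  w <- rnorm(q)
  x <- drop(Y %*% w)
  std <- standardize_pair(list(x = x[1:45], Y = Y[1:45, ]),
                          list(x = x[46:60], Y = Y[46:60, ]))
  dm <- fit_decoding(std$train$Y, std$train$x)
  expect_length(dm$beta, q)
  expect_gte(dm$lambda, 0)
  # beta at the chosen penalty equals the direct normal-equations solution
  direct <- solve(crossprod(std$train$Y) + dm$lambda * diag(q),
                  crossprod(std$train$Y, std$train$x))
  expect_equal(dm$beta, drop(direct), tolerance = 1e-6)
  # noise-free planted model: near-perfect test correlation
  ev <- evaluate(dm, std$test$x, std$test$Y)
  expect_gt(ev$r, 0.99)
  expect_error(fit_decoding(matrix(0, 5, 2), rnorm(5)), "degenerate")

  # q = 1 decoding agrees with the encoding fit's prediction direction
  set.seed(95)
  x1 <- rnorm(30); y1 <- 0.7 * x1 + rnorm(30, 0, 0.3)
  x1 <- (x1 - mean(x1)) / pop_sd_test(x1)
  y1 <- (y1 - mean(y1)) / pop_sd_test(y1)
  dm1 <- fit_decoding(matrix(y1, ncol = 1), x1)
  em1 <- fit_encoding(x1, y1)
  expect_equal(sign(dm1$beta), sign(em1$beta))
  expect_equal(abs(cor(y1 * dm1$beta, y1 * em1$beta)), 1, tolerance = 1e-10)
})

test_that("validation reports the Pearson correlation of truth and prediction", {
  set.seed(96)
  Y <- matrix(rnorm(20), 10, 2)
  m <- structure(list(beta = c(1, 0), lambda = 0), class = "decoding_model")
  truths <- Y[, 1]
  expect_equal(evaluate(m, truths, Y)$r, 1)
  expect_equal(evaluate(m, -truths, Y)$r, -1)

  em <- structure(list(beta = 2), class = "encoding_model")
  tr <- c(1, 2, 3, 4); pr_in <- c(1.1, 1.9, 3.2, 3.8)
  got <- evaluate(em, tr, pr_in)
  expect_equal(got$r, naive_pearson(tr, 2 * pr_in), tolerance = 1e-12)

  flat <- structure(list(beta = c(0, 0)), class = "decoding_model")
  ev0 <- evaluate(flat, truths, Y)
  expect_equal(ev0$r, 0)
  expect_true(ev0$flagged)
})

test_that("decoding accuracy degrades monotonically with response noise", {
  set.seed(97)
  n <- 80; q <- 20
  x <- rnorm(n)
  x <- (x - mean(x)) / pop_sd_test(x)
  slopes <- runif(q, 0.4, 0.6) * sample(c(-1, 1), q, replace = TRUE)
  snr_noise <- c(0, 0.125, 0.5, 2)     # |slope| 0.5 => SNR inf, 4, 1, 0.25
  rs <- numeric(length(snr_noise))
  for (i in seq_along(snr_noise)) {
    Y <- outer(x, slopes) + matrix(rnorm(n * q, 0, snr_noise[i]), n, q)
    std <- standardize_pair(list(x = x[1:60], Y = Y[1:60, ]),
                            list(x = x[61:80], Y = Y[61:80, ]))
    dm <- fit_decoding(std$train$Y, std$train$x)
    rs[i] <- evaluate(dm, std$test$x, std$test$Y)$r
  }
  expect_true(all(diff(rs) <= 0.005))
  expect_gt(rs[1], 0.999)
})
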