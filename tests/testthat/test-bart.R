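sim_step <- function(n, seed, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  list(X = X, y = as.numeric(X[, 1] > 0) + rnorm(n, 0, noise))
}

test_that("continuous fit tracks a step function near the noise floor", {
  d <- sim_step(500, 1)
  fit <- bart(d$X, d$y, type = "continuous", n_trees = 20, n_burn = 100,
              n_draws = 200)
  te <- sim_step(800, 2, noise = 0)
  rmse <- sqrt(mean((predict(fit, te$X, type = "mean") - te$y)^2))
  expect_lt(rmse, 0.15)  # Bayes predictor would achieve 0.1
  # constant outcome degenerates gracefully
  expect_message(cfit <- bart(d$X, rep(3.5, 500), type = "continuous"),
                 "constant")
  expect_true(all(abs(predict(cfit, te$X, type = "mean") - 3.5) < 1e-6))
})

test_that("probit fit separates a threshold rule inside (0,1)", {
  set.seed(3)
  n <- 1000
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- as.numeric(X[, 1] > 0)
  fit <- bart(X, y, type = "probit", n_trees = 20, n_burn = 100,
              n_draws = 200)
  Xt <- matrix(rnorm(600 * 3), 600, 3, dimnames = dimnames(X))
  p <- predict(fit, Xt, type = "mean")
  expect_gt(mean(p[Xt[, 1] > 0.5]), 0.8)
  expect_lt(mean(p[Xt[, 1] < -0.5]), 0.2)
  draws <- predict(fit, Xt, type = "draws")
  expect_true(all(draws > 0 & draws < 1))
  expect_error(bart(X, rep(1, n), type = "probit"), "single class")
})

test_that("probit marginal calibration holds on pure-noise features", {
  set.seed(4)
  n <- 1000
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- rbinom(n, 1, 0.3)
  fit <- bart(X, y, type = "probit", n_trees = 50, n_burn = 200,
              n_draws = 400)
  Xt <- matrix(rnorm(500 * 3), 500, 3, dimnames = dimnames(X))
  p <- predict(fit, Xt, type = "mean")
  # the standardized (averaged) probability is calibrated to the truth;
  # single points wobble around it under the tree prior
  expect_lt(abs(mean(p) - 0.3), 0.05)
  expect_true(all(p > 0 & p < 1))
})

test_that("prediction matrix shape, duplicates, and schema checks", {
  d <- sim_step(200, 5)
  fit <- bart(d$X, d$y, n_trees = 10, n_burn = 50, n_draws = 60)
  P <- predict(fit, d$X, type = "draws")
  expect_equal(dim(P), c(60, 200))
  dup <- d$X[c(1, 1, 2), , drop = FALSE]
  Pd <- predict(fit, dup, type = "draws")
  expect_identical(Pd[, 1], Pd[, 2])
  bad <- d$X[, c(1, 2), drop = FALSE]
  expect_error(predict(fit, bad), "x3")
  mislabeled <- d$X
  colnames(mislabeled) <- c("x1", "x2", "zz")
  expect_error(predict(mislabeled, object = fit), "zz")
})

test_that("serialized posterior predicts bit-for-bit like the original", {
  d <- sim_step(150, 6)
  fit <- bart(d$X, d$y, n_trees = 10, n_burn = 50, n_draws = 40)
  path <- tempfile(fileext = ".json")
  bart_write_json(fit, path)
  fit2 <- bart_read_json(path)
  expect_identical(predict(fit, d$X, type = "draws"),
                   predict(fit2, d$X, type = "draws"))
  unlink(path)
})

test_that("fits are seed-deterministic and stable under row permutation", {
  d <- sim_step(300, 7)
  set.seed(11)
  f1 <- bart(d$X, d$y, n_trees = 15, n_burn = 80, n_draws = 150)
  set.seed(11)
  f2 <- bart(d$X, d$y, n_trees = 15, n_burn = 80, n_draws = 150)
  expect_identical(f1$forest, f2$forest)
  perm <- sample(seq_len(300))
  set.seed(11)
  f3 <- bart(d$X[perm, ], d$y[perm], n_trees = 15, n_burn = 80,
             n_draws = 150)
  te <- sim_step(200, 8)
  expect_lt(max(abs(predict(f1, te$X, type = "mean") -
                      predict(f3, te$X, type = "mean"))), 0.02)
})

test_that("posterior-predictive intervals cover a well-specified truth", {
  set.seed(9)
  n <- 500
  X <- matrix(runif(n * 2, -1, 1), n, 2,
              dimnames = list(NULL, c("x1", "x2")))
  f <- function(X) sin(2 * X[, 1]) + X[, 2]^2
  y <- f(X) + rnorm(n, 0, 0.3)
  fit <- bart(X, y, n_trees = 30, n_burn = 150, n_draws = 300)
  ppd <- predict(fit, X, type = "ppd")
  lo <- apply(ppd, 2, quantile, 0.025)
  hi <- apply(ppd, 2, quantile, 0.975)
  ynew <- f(X) + rnorm(n, 0, 0.3)
  cov <- mean(ynew >= lo & ynew <= hi)
  expect_gte(cov, 0.85)
  expect_lte(cov, 0.99)
})

test_that("error-SD trace passes a stationarity screen", {
  set.seed(10)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- X[, 1] + rnorm(n, 0, 0.5)
  fit <- bart(X, y, n_trees = 20, n_burn = 150, n_draws = 400)
  tr <- bart_trace(fit, "sigma")
  expect_length(tr, 400)
  h1 <- mean(tr[1:200]); h2 <- mean(tr[201:400])
  expect_lt(abs(h1 - h2) / mean(tr), 0.1)  # no drift between halves
  # arbitrary scalar summaries are traceable too
  mtr <- bart_trace(fit, fn = mean)
  expect_length(mtr, 400)
  expect_true(stats::sd(mtr) > 0)
})
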