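# Elastic-net objective and its subgradient (KKT) conditions.
enet_kkt_gap <- function(X, y, b0, beta, alpha, lambda) {
  n <- nrow(X)
  r <- y - b0 - drop(X %*% beta)
  grad <- drop(crossprod(X, r)) / n - lambda * (1 - alpha) * beta
  active <- beta != 0
  gap <- abs(mean(r))  # intercept stationarity
  if (any(active)) {
    gap <- max(gap, abs(grad[active] - lambda * alpha * sign(beta[active])))
  }
  if (any(!active)) {
    gap <- max(gap, max(0, abs(grad[!active]) - lambda * alpha))
  }
  gap
}

test_that("the solver reduces to OLS when the penalty vanishes", {
  set.seed(1)
  X <- matrix(rnorm(400), 80, 5)
  y <- drop(X %*% c(1, -1, 0, 0.5, 0)) + rnorm(80)
  fit <- enr_solve(X, y, alpha = 0.5, lambda = 0)
  expect_equal(unname(c(fit$b0, fit$beta)), unname(coef(lm(y ~ X))),
               tolerance = 1e-6)
})

test_that("the lasso solution matches the univariate soft-threshold closed form", {
  set.seed(2)
  n <- 150
  x <- matrix(scale(rnorm(n)), ncol = 1)
  y <- rnorm(n, 0.4 * x)
  for (lam in c(0.01, 0.1, 0.5)) {
    fit <- enr_solve(x, y, alpha = 1, lambda = lam)
    v <- mean(x^2)
    z <- mean(x * (y - mean(y)))
    expect_equal(unname(fit$beta), sign(z) * max(abs(z) - lam, 0) / v,
                 tolerance = 1e-8)
  }
})

test_that("the ridge solution matches the closed form", {
  set.seed(3)
  X <- matrix(rnorm(500), 100, 5)
  y <- drop(X %*% c(1, 0, -1, 0.5, 0)) + rnorm(100)
  lam <- 0.3
  fit <- enr_solve(X, y, alpha = 0, lambda = lam)
  Xc <- scale(X, scale = FALSE)
  closed <- solve(crossprod(Xc) / 100 + lam * diag(5),
                  crossprod(Xc, y - mean(y)) / 100)
  expect_equal(unname(fit$beta), drop(closed), tolerance = 1e-6)
})

test_that("the lasso path agrees with glmnet", {
  set.seed(4)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(100)
  lam <- c(0.5, 0.2, 0.05)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, standardize = FALSE,
                      thresh = 1e-14)
  mine <- enr_solve(X, y, alpha = 1, lambda = lam)
  expect_equal(unname(as.matrix(g$beta)), unname(mine$beta), tolerance = 1e-5)
  expect_equal(unname(g$a0), unname(mine$b0), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("solutions satisfy the KKT conditions on random instances", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(40:120, 1); p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, X %*% rnorm(p, 0, 0.5))
    alpha <- runif(1); lam <- runif(1, 0.01, 0.5)
    fit <- enr_solve(X, y, alpha, lam)
    expect_lt(enet_kkt_gap(X, y, fit$b0, fit$beta, alpha, lam), 1e-5)
  }
})

test_that("increasing lambda never increases the active set", {
  set.seed(6)
  X <- matrix(rnorm(90 * 20), 90, 20)
  y <- rnorm(90, X %*% c(rep(1, 3), rep(0, 17)))
  lam <- exp(seq(log(1), log(1e-3), length.out = 30))
  fit <- enr_solve(X, y, alpha = 1, lambda = lam)
  nnz <- colSums(fit$beta != 0)
  expect_true(all(diff(nnz) >= 0))  # path is descending in lambda
  expect_error(enr_solve(X, c(y[-1], NA), 1, 0.1), "non-finite")
})

test_that("tuning selects sensible penalties", {
  set.seed(7)
  X <- matrix(rnorm(100 * 10), 100, 10)
  # one-point grid returns that point
  y <- rnorm(100)
  one <- enr_tune(X, y, alphas = 0.5, lambdas = 0.2, seed = 1)
  expect_equal(one$alpha, 0.5)
  expect_equal(one$lambda, 0.2)
  # under the null the selected lambda shrinks toward the null model
  hits <- 0L
  for (i in 1:10) {
    y0 <- rnorm(100)
    tu <- enr_tune(X, y0, alphas = c(0.5, 1), n_lambda = 30, seed = i)
    med <- median(lambda_grid_of(tu))
    if (tu$lambda >= med) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
  # noiseless sparse signal: small lambda, support recovered
  ys <- drop(X %*% c(2, -1.5, rep(0, 8)))
  tus <- enr_tune(X, ys, alphas = 1, n_lambda = 30, seed = 3, rule = "min")
  expect_lt(tus$lambda, median(lambda_grid_of(tus)))
  fit <- enr_solve(X, ys, 1, tus$lambda)
  expect_true(all(which(abs(fit$beta) > 0.05) %in% 1:2) &&
                all(1:2 %in% which(fit$beta != 0)))
  expect_error(enr_tune(X[1:5, ], rnorm(5), alphas = 1, folds = 2,
                        train_fraction = 0.9, seed = 1), "test samples")
})

test_that("stability selection retains a strong predictor and drops noise", {
  set.seed(8)
  n <- 113
  X <- matrix(rnorm(n * 21), n, 21)
  colnames(X) <- paste0("x", 1:21)
  y <- 2 * X[, 1] + rnorm(n)
  tu <- enr_tune(X, y, alphas = c(0.5, 1), n_lambda = 30, seed = 2)
  sm <- stability_select(X, y, tu$alpha, tu$lambda, seed = 2)
  expect_true("x1" %in% sm$retained$predictor)
  row <- sm$retained[sm$retained$predictor == "x1", ]
  expect_equal(row$count, 10)
  expect_lt(abs(row$coefficient - 2) / 2, 0.25)  # shrinkage expected
  expect_gt(sm$pearson_r, 0.7)
  # retain_min = 0 keeps every ever-selected predictor
  all_sel <- stability_select(X, y, tu$alpha, tu$lambda, seed = 2,
                              retain_min = 0)
  expect_setequal(all_sel$retained$predictor,
                  names(which(all_sel$selection_counts > 0)))
})

test_that("selection is invariant to predictor column order", {
  set.seed(9)
  X <- matrix(rnorm(100 * 12), 100, 12)
  colnames(X) <- paste0("x", 1:12)
  y <- X[, 3] - 0.8 * X[, 7] + rnorm(100, 0, 0.5)
  sm1 <- stability_select(X, y, alpha = 1, lambda = 0.08, seed = 4)
  perm <- sample(12)
  sm2 <- stability_select(X[, perm], y, alpha = 1, lambda = 0.08, seed = 4)
  expect_equal(sm1$selection_counts[colnames(X)[perm]], sm2$selection_counts)
  expect_equal(sort(sm1$retained$predictor), sort(sm2$retained$predictor))
})

test_that("pure-noise outcomes usually yield an empty model", {
  set.seed(10)
  X <- matrix(rnorm(113 * 20), 113, 20)
  empty <- logical(8)
  for (i in seq_along(empty)) {
    y <- rnorm(113)
    tu <- enr_tune(X, y, seed = 20 + i)
    sm <- stability_select(X, y, tu$alpha, tu$lambda, seed = 20 + i)
    empty[i] <- sm$empty
  }
  expect_gte(sum(empty), 6L)
  # the empty model is valid and flagged
  sm0 <- stability_select(X, rnorm(113), alpha = 1, lambda = 10, seed = 1)
  expect_true(sm0$empty)
  expect_equal(nrow(sm0$retained), 0L)
  # intercept-only predictions: the correlation is undefined or meaningless
  expect_true(is.na(sm0$pearson_r) || abs(sm0$pearson_r) < 0.5)
})

test_that("the confirmatory regression recovers generating marker effects", {
  # zero-noise outcome: exact recovery
  set.seed(11)
  n <- 113
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("CE[18:0]", "TG[12:0]")))
  cv <- make_trial_covariates(n, seed = 12)
  y0 <- 0.2 * X[, 1] + 0.15 * X[, 2] + 0.01 * cv$age + 0.05 * cv$bmi
  r0 <- suppressWarnings(
    confirmatory_lm(y0, X, cv$age, cv$sex, cv$bmi, rnorm(n, 2.8, 0.8), cv$arm)
  )
  expect_equal(r0$beta, c(0.2, 0.15), tolerance = 1e-10)

  # coverage: generating effects of 0.20 and 0.15 marker units per SD fall
  # inside their 95% CI in about 95% of replicates, and a null predictor's
  # CI covers zero at the same rate
  hits <- matrix(NA, 150, 3)
  for (i in 1:150) {
    set.seed(1000 + i)
    Xi <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("CE[18:0]", "TG[12:0]", "LPC[15:0]")))
    yi <- 0.20 * Xi[, 1] + 0.15 * Xi[, 2] + 0.005 * cv$age + rnorm(n, 0, 0.35)
    ri <- confirmatory_lm(yi, Xi, cv$age, cv$sex, cv$bmi,
                          rnorm(n, 2.8, 0.8), cv$arm)
    hits[i, ] <- ri$ci_low <= c(0.20, 0.15, 0) & c(0.20, 0.15, 0) <= ri$ci_high
  }
  expect_true(all(colMeans(hits) >= 0.90))
  expect_true(all(colMeans(hits) <= 0.995))
  expect_error(confirmatory_lm(y0, X[, 0], cv$age, cv$sex, cv$bmi,
                               rnorm(n), cv$arm), "empty")
})
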