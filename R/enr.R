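# Elastic-net regression with cross-validated tuning and stability
# selection, linking within-class fatty-acid changes to changes in
# cardiometabolic risk markers.

#' Solve one elastic-net problem
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 +
#' (1-alpha)/2 ||b||^2)` by cyclic coordinate descent with
#' soft-thresholding; the intercept is unpenalized. At `lambda = 0` the
#' solution coincides with ordinary least squares; with a single
#' standardized predictor and `alpha = 1` it equals the soft-threshold
#' closed form.
#'
#' @param X Numeric predictor matrix (columns typically z-normalized
#'   deltas).
#' @param y Numeric response vector.
#' @param alpha Mixing parameter in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda Penalty, a scalar or descending vector (a path is solved
#'   with warm starts).
#' @param tol Convergence tolerance on the maximum coefficient change;
#'   default 1e-7.
#' @param max_iter Sweep limit per lambda; default 100000.
#' @return For scalar `lambda`, a list with `b0`, `beta`, `iterations`;
#'   for a path, `beta` is a p x length(lambda) matrix and `b0` a vector.
#' @export
enr_solve <- function(X, y, alpha, lambda, tol = 1e-7, max_iter = 1e5) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  stopifnot(length(y) == nrow(X), alpha >= 0, alpha <= 1, all(lambda >= 0))
  fit <- enet_cd_path(X, as.numeric(y), alpha, as.numeric(lambda),
                      tol, as.integer(max_iter))
  if (!all(fit$converged)) {
    stop("coordinate descent did not converge within ", max_iter,
         " sweeps at lambda = ",
         paste(signif(lambda[!fit$converged], 4), collapse = ", "))
  }
  rownames(fit$beta) <- colnames(X)
  if (length(lambda) == 1L) {
    list(b0 = fit$b0[1L], beta = fit$beta[, 1L], iterations = fit$iterations[1L])
  } else {
    list(b0 = fit$b0, beta = fit$beta, iterations = fit$iterations)
  }
}

# Smallest lambda that zeroes every coefficient at the given alpha, and a
# descending log-spaced grid below it.
lambda_grid <- function(X, y, alpha, n_lambda = 50, decades = 4) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  a <- max(alpha, 1e-3)
  lmax <- max(abs(crossprod(Xc, yc))) / (nrow(X) * a)
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

# Seeded random train/test splits: a list of index vectors (training rows).
make_splits <- function(n, folds, train_fraction, seed) {
  stopifnot(folds >= 1L, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  if (n - n_train < 2L) stop("fewer than 2 test samples per split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(folds), function(i) sort(sample.int(n, n_train)))
}

#' Tune elastic-net hyperparameters by repeated train/test splits
#'
#' For each (alpha, lambda) pair on the grid, averages the test-set
#' mean-squared error over `folds` seeded random splits
#' (`train_fraction` training / rest test). With `rule = "min"` the
#' minimizing pair is returned, ties broken toward larger lambda, then
#' larger alpha (the sparser model). The default `rule = "1se"` is the
#' standard parsimony rule that optimizes model complexity while
#' minimizing the error: among all pairs whose mean MSE lies within one
#' standard error of the minimum, the largest lambda (then largest alpha)
#' is chosen.
#'
#' @inheritParams enr_solve
#' @param alphas Numeric vector of mixing parameters; default 0.1 to 1 by
#'   0.1.
#' @param lambdas Optional penalty grid; by default 50 log-spaced values
#'   from the per-alpha lambda-max down 4 decades.
#' @param folds Number of random splits; default 10.
#' @param train_fraction Training share per split; default 0.8.
#' @param seed Integer master seed for the splits.
#' @param n_lambda Path length per alpha when `lambdas` is `NULL`.
#' @param tol Solver tolerance during tuning (looser than the final-fit
#'   default; the selected pair is refit exactly downstream).
#' @return A list with `alpha`, `lambda`, the mean `mse` achieved, and the
#'   full `cv_table`.
#' @export
enr_tune <- function(X, y, alphas = seq(0.1, 1, by = 0.1), lambdas = NULL,
                     folds = 10, train_fraction = 0.8, seed = 1,
                     n_lambda = 50, tol = 1e-5, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  stopifnot(length(alphas) >= 1L)
  splits <- make_splits(nrow(X), folds, train_fraction, seed)
  rows <- list()
  for (a in alphas) {
    lam <- if (is.null(lambdas)) lambda_grid(X, y, a, n_lambda = n_lambda) else
      sort(lambdas, decreasing = TRUE)
    mse <- matrix(NA_real_, length(lam), length(splits))
    for (s in seq_along(splits)) {
      tr <- splits[[s]]
      fit <- enr_solve(X[tr, , drop = FALSE], y[tr], a, lam, tol = tol)
      beta <- if (length(lam) == 1L) cbind(fit$beta) else fit$beta
      pred <- sweep(X[-tr, , drop = FALSE] %*% beta, 2L, -fit$b0)
      mse[, s] <- colMeans((y[-tr] - pred)^2)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      alpha = a, lambda = lam, mse = rowMeans(mse),
      mse_se = apply(mse, 1L, stats::sd) / sqrt(ncol(mse))
    )
  }
  cv <- do.call(rbind, rows)
  # minimum MSE; ties toward larger lambda then larger alpha
  ord <- order(cv$mse, -cv$lambda, -cv$alpha)
  best <- cv[ord[1L], ]
  if (rule == "1se") {
    ok <- cv$mse <= best$mse + best$mse_se
    cand <- cv[ok, , drop = FALSE]
    best <- cand[order(-cand$lambda, -cand$alpha)[1L], ]
  }
  list(alpha = best$alpha, lambda = best$lambda, mse = best$mse,
       rule = rule, cv_table = cv)
}

#' Stability selection over repeated train/test splits
#'
#' Fits the elastic net at a fixed (alpha, lambda) on `folds` seeded
#' random training sets; a predictor is selected in an iteration iff its
#' coefficient is nonzero. Predictors selected in at least `retain_min`
#' iterations are retained, with a final coefficient averaged over the
#' iterations where they were nonzero. Each iteration's held-out
#' predictions are collated and the overall Pearson correlation between
#' predicted and measured values is reported as the performance proxy.
#'
#' @inheritParams enr_tune
#' @param alpha,lambda The tuned elastic-net parameters.
#' @param retain_min Minimum number of selecting iterations; default 9.
#' @param marker Optional outcome label carried into the result.
#' @return An object of class `stability_model`: `retained` (data.frame of
#'   predictor, averaged coefficient, selection count), `pearson_r`
#'   (`NA` with `empty = TRUE` when nothing is retained), `alpha`,
#'   `lambda`, `folds`, `retain_min`, `seed`, `selection_counts`.
#' @export
stability_select <- function(X, y, alpha, lambda, seed = 1, folds = 10,
                             train_fraction = 0.8, retain_min = 9,
                             marker = NULL) {
  X <- as.matrix(X)
  stopifnot(retain_min <= folds)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  splits <- make_splits(nrow(X), folds, train_fraction, seed + 1L)
  coefs <- matrix(0, ncol(X), folds, dimnames = list(colnames(X), NULL))
  pred <- obs <- numeric(0)
  for (s in seq_along(splits)) {
    tr <- splits[[s]]
    fit <- enr_solve(X[tr, , drop = FALSE], y[tr], alpha, lambda)
    coefs[, s] <- fit$beta
    pred <- c(pred, drop(X[-tr, , drop = FALSE] %*% fit$beta) + fit$b0)
    obs <- c(obs, y[-tr])
  }
  selected <- coefs != 0
  counts <- rowSums(selected)
  keep <- counts >= retain_min & counts > 0
  retained <- data.frame(
    predictor = colnames(X)[keep],
    coefficient = vapply(which(keep), function(j) {
      mean(coefs[j, selected[j, ]])
    }, 0.0),
    count = unname(counts[keep]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  r <- if (stats::sd(pred) > 0) stats::cor(pred, obs) else NA_real_
  structure(
    list(
      marker = marker, retained = retained, pearson_r = r,
      empty = !any(keep), alpha = alpha, lambda = lambda,
      folds = folds, retain_min = retain_min, seed = seed,
      selection_counts = counts, n = nrow(X)
    ),
    class = "stability_model"
  )
}

#' @export
print.stability_model <- function(x, ...) {
  cat("Elastic-net stability selection",
      if (!is.null(x$marker)) paste0(" for '", x$marker, "'"), "\n", sep = "")
  cat(sprintf("  alpha = %.3g, lambda = %.4g, %d/%d selection threshold\n",
              x$alpha, x$lambda, x$retain_min, x$folds))
  if (x$empty) {
    cat("  no predictor retained\n")
  } else {
    print(x$retained, row.names = FALSE)
  }
  cat(sprintf("  collated out-of-fold Pearson r = %s\n",
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' @export
coef.stability_model <- function(object, ...) {
  stats::setNames(object$retained$coefficient, object$retained$predictor)
}

#' Fully adjusted confirmatory regression for retained predictors
#'
#' Ordinary least squares of a risk-marker change on all retained
#' within-class fatty-acid deltas simultaneously, adjusted for age, sex,
#' BMI, the baseline marker value, and dietary arm. Coefficients are
#' expressed per SD of predictor change when the deltas are z-normalized.
#'
#' @param marker_delta Numeric outcome vector (change from baseline, marker
#'   units).
#' @param predictors Numeric matrix of retained predictors' deltas
#'   (typically z-normalized), with column names.
#' @param age,bmi Numeric covariates.
#' @param sex Factor or character covariate.
#' @param baseline_marker Numeric baseline marker value.
#' @param arm Factor with the reference arm first.
#' @return An object of class `confirmatory_lm`: a data.frame with one row
#'   per predictor (`beta`, `ci_low`, `ci_high`, `p`, `n`) carrying the
#'   underlying `lm` fit as attribute `"fit"`.
#' @export
confirmatory_lm <- function(marker_delta, predictors, age, sex, bmi,
                            baseline_marker, arm) {
  predictors <- as.matrix(predictors)
  if (ncol(predictors) == 0L) stop("retained predictor set is empty")
  df <- data.frame(
    .y = marker_delta, predictors, age = age, sex = factor(sex),
    bmi = bmi, base = baseline_marker, arm = factor(arm),
    check.names = FALSE
  )
  miss <- !stats::complete.cases(df)
  if (any(miss)) {
    stop("missing covariates for samples: ",
         paste(rownames(df)[miss], collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  nm <- paste0("`", colnames(predictors), "`")
  nm[!nm %in% rownames(cf)] <- colnames(predictors)[!nm %in% rownames(cf)]
  out <- data.frame(
    predictor = colnames(predictors),
    beta = cf[nm, "Estimate"],
    ci_low = ci[nm, 1L],
    ci_high = ci[nm, 2L],
    p = cf[nm, "Pr(>|t|)"],
    n = nrow(df),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(out, fit = fit, class = c("confirmatory_lm", "data.frame"))
}
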