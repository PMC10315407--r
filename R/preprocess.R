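# Preprocessing of samples x species concentration matrices: missingness
# exclusion, left-censored imputation, transform conventions.

#' Exclude species with a high fraction of missing values
#'
#' Species (columns) whose missing fraction is greater than or equal to
#' `threshold` are removed before imputation; everything else is retained
#' unchanged. Missingness is assessed across all supplied samples jointly.
#'
#' @param m Numeric matrix, samples x species, `NA` marking values below the
#'   detection limit. Row names are sample IDs, column names species.
#' @param threshold Missing fraction at or above which a species is
#'   excluded; default 0.75.
#' @return A list with `matrix` (retained columns) and `report`, a
#'   data.frame of excluded species and their missing fractions.
#' @export
filter_missing <- function(m, threshold = 0.75) {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L) {
    stop("'m' must be a non-empty samples x species matrix")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]")
  }
  frac <- colMeans(is.na(m))
  drop <- frac >= threshold
  report <- data.frame(
    species = colnames(m)[drop],
    missing_fraction = unname(frac[drop]),
    stringsAsFactors = FALSE
  )
  list(matrix = m[, !drop, drop = FALSE], report = report)
}

# Estimate (mu, sigma) of a left-censored normal sample by least-squares
# regression of the observed order statistics on standard-normal quantiles
# at plotting positions shifted for the censored fraction. 'x' is on the
# log scale; 'n_total' the full sample size including censored cells.
censored_normal_fit <- function(x, n_total) {
  k <- length(x)
  stopifnot(k >= 2L, n_total >= k)
  n_missing <- n_total - k
  xs <- sort(x)
  # Blom plotting positions over the full (censored + observed) sample;
  # the observed values occupy ranks n_missing + 1 ... n_total.
  p <- (n_missing + seq_len(k) - 0.375) / (n_total + 0.25)
  q <- stats::qnorm(p)
  fit <- stats::lsfit(q, xs)
  c(mu = unname(fit$coefficients[1L]), sigma = unname(fit$coefficients[2L]))
}

# One draw per missing cell from Normal(mu, sd) truncated above at 'upper'.
rtruncnorm_upper <- function(n, mu, sd, upper) {
  pu <- stats::pnorm(upper, mean = mu, sd = sd)
  pu <- max(pu, 1e-12)
  u <- stats::runif(n, min = 0, max = pu)
  stats::qnorm(u, mean = mu, sd = sd)
}

#' Left-censored imputation by quantile regression of order statistics
#'
#' Implements quantile-regression imputation for left-censored (below
#' detection limit) concentrations. Per species, on the natural-log scale:
#' the mean and SD of the uncensored distribution are estimated by
#' least-squares regression of the observed order statistics against
#' standard-normal quantiles evaluated at plotting positions shifted for
#' the censored fraction; missing cells are then drawn from
#' `Normal(mu, tune_sigma * sigma)` truncated above at the species' minimum
#' observed log-concentration, and exponentiated back. Observed cells are
#' never altered, and every imputed value lies at or below the species'
#' observed minimum. Deterministic given `seed`.
#'
#' Species with fewer than 3 observed values cannot support the regression
#' and are imputed with half the global minimum observed concentration,
#' flagged in the report.
#'
#' @param m Numeric matrix, samples x species, `NA` marking censored cells;
#'   observed values must be strictly positive.
#' @param seed Integer seed governing the truncated-normal draws.
#' @param tune_sigma Multiplier on the estimated SD of the censored tail;
#'   default 1.
#' @return A list with `matrix` (complete) and `report`, a list holding
#'   `imputed_cell_count`, the per-species `censor_threshold` (minimum
#'   observed concentration), the estimated per-species `mu` and `sigma`
#'   (log scale), `fallback_species`, and `seed`.
#' @export
impute_qrilc <- function(m, seed, tune_sigma = 1.0) {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L) {
    stop("'m' must be a non-empty samples x species matrix")
  }
  if (any(m[!is.na(m)] <= 0)) stop("observed concentrations must be > 0")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  out <- m
  n <- nrow(m)
  mu <- sigma <- thr <- rep(NA_real_, ncol(m))
  names(mu) <- names(sigma) <- names(thr) <- colnames(m)
  fallback <- character(0)
  imputed <- 0L
  global_min <- suppressWarnings(min(m, na.rm = TRUE))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) {
      obs <- log(m[, j])
      est <- censored_normal_fit(obs, n)
      mu[j] <- est["mu"]; sigma[j] <- est["sigma"]
      thr[j] <- min(m[, j])
      next
    }
    k <- sum(!miss)
    if (k < 3L) {
      out[miss, j] <- global_min / 2
      fallback <- c(fallback, colnames(m)[j])
      imputed <- imputed + sum(miss)
      thr[j] <- if (k > 0L) min(m[!miss, j]) else NA_real_
      next
    }
    obs <- log(m[!miss, j])
    est <- censored_normal_fit(obs, n)
    mu[j] <- est["mu"]; sigma[j] <- est["sigma"]
    thr[j] <- min(m[!miss, j])
    # per-species substream derived from the master seed and the observed
    # column, so identical observed columns always impute identically
    col_seed <- (as.integer(seed) + 131L * sum(which(miss)) +
                   as.integer(round(1e4 * mean(obs)) %% 1e6)) %%
      .Machine$integer.max
    set.seed(col_seed)
    draws <- rtruncnorm_upper(
      sum(miss), est["mu"], tune_sigma * abs(est["sigma"]), log(thr[j])
    )
    out[miss, j] <- exp(draws)
    imputed <- imputed + sum(miss)
  }
  list(
    matrix = out,
    report = list(
      imputed_cell_count = imputed,
      censor_threshold = thr,
      mu = mu,
      sigma = sigma,
      fallback_species = fallback,
      seed = as.integer(seed)
    )
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Log-transform and z-normalize a concentration vector
#'
#' `(log(v) - mean(log v)) / sd(log v)` with the sample (n-1) SD, so the
#' result has mean 0 and SD 1. Used to put within-class fatty-acid
#' concentrations on a comparable SD scale across targets.
#'
#' @param v Strictly positive numeric vector, length >= 2, non-constant.
#' @return Numeric z-score vector.
#' @export
#' @examples
#' log_z(c(1, exp(1), exp(2)))  # -1 0 1
log_z <- function(v) {
  nm <- deparse(substitute(v))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("non-positive or non-finite values in ", nm)
  }
  if (length(v) < 2L) stop("need >= 2 values in ", nm)
  lv <- log(v)
  s <- stats::sd(lv)
  if (!is.finite(s) || s == 0) stop("zero variance in ", nm)
  (lv - mean(lv)) / s
}

#' Change from baseline
#'
#' Element-wise week-16 minus week-0 values, aligned by sample ID (names or
#' row names). No log transform is applied, because changes can be
#' negative; an optional z-normalization (mean 0, SD 1) is available for
#' within-class fatty-acid deltas.
#'
#' @param week16,week0 Numeric vectors (or single-column matrices) with
#'   sample IDs as names.
#' @param z If `TRUE`, z-normalize the deltas.
#' @return Numeric delta vector named by sample ID.
#' @export
change_from_baseline <- function(week16, week0, z = FALSE) {
  week16 <- drop(week16); week0 <- drop(week0)
  if (is.null(names(week16)) || is.null(names(week0))) {
    stop("both vectors must carry sample IDs as names")
  }
  unmatched <- c(setdiff(names(week16), names(week0)),
                 setdiff(names(week0), names(week16)))
  if (length(unmatched)) {
    stop("sample IDs not present at both visits: ",
         paste(unique(unmatched), collapse = ", "))
  }
  d <- week16 - week0[names(week16)]
  if (z) {
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) stop("zero variance in deltas")
    d <- (d - mean(d)) / s
  }
  d
}
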