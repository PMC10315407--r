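# Dietary-arm effects on post-intervention within-class fatty-acid
# z-scores: covariate-adjusted linear models with Bonferroni control.

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p_raw)` with the significance threshold `0.05 / m`.
#' The family size `m` is a configuration value: it may exceed the number
#' of p-values supplied (e.g. when a figure's caption fixes the
#' denominator).
#'
#' @param p_raw Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size, at least `length(p_raw)`.
#' @param level Familywise level; default 0.05.
#' @return A list with `p_adj` and `threshold` (`level / m`).
#' @export
#' @examples
#' bonferroni(c(1e-5, 0.01), m = 282)$threshold  # 0.05/282 = 0.00018
bonferroni <- function(p_raw, m, level = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("'m' must be >= 1")
  if (m < length(p_raw)) stop("'m' must be at least length(p_raw)")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  list(p_adj = pmin(1, m * p_raw), threshold = level / m)
}

# Assemble the adjustment design shared by fit_diet_effect and the
# vectorized driver. Covariate concentrations enter on the log scale.
diet_design <- function(base_fa, base_total, post_total, age, sex, bmi, arm) {
  arm <- factor(arm)
  if (nlevels(arm) != 3L) stop("'arm' must have exactly 3 levels")
  if (!"SFA" %in% levels(arm)) stop("'arm' must contain the SFA reference level")
  arm <- stats::relevel(arm, ref = "SFA")
  df <- data.frame(
    base_fa = log(base_fa), base_total = log(base_total),
    post_total = log(post_total), age = age, sex = factor(sex),
    bmi = bmi, arm = arm
  )
  miss <- !stats::complete.cases(df)
  if (any(miss)) {
    stop("missing covariates for samples: ",
         paste(which(miss), collapse = ", "))
  }
  # constant concentration adjustors carry no information (and would be
  # collinear with the intercept): adjustment is inert, so drop them
  conc <- c("base_fa", "base_total", "post_total")
  keep <- conc[vapply(df[conc], function(v) stats::sd(v) > 0, NA)]
  form <- stats::reformulate(c(keep, "age", "sex", "bmi", "arm"))
  X <- stats::model.matrix(form, df)
  list(X = X, arm_cols = grep("^arm", colnames(X), value = TRUE))
}

# OLS on a prebuilt design; returns coefficients, SEs and t-test p-values.
ols_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rdf <- length(y) - ncol(X)
  if (rdf < 1L) stop("too few samples for the number of parameters")
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * diag(XtXinv))
  names(se) <- colnames(X)
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE)
  list(coef = fit$coefficients, se = se, p = p, rdf = rdf,
       residuals = fit$residuals, fitted = fit$fitted.values)
}

#' Arm effects for one within-class fatty acid
#'
#' Ordinary least squares of the log-transformed, z-normalized
#' post-intervention within-class fatty-acid concentration on the two
#' UFA-rich arm dummies (SFA-rich arm as reference), adjusted for age,
#' sex, BMI, the baseline within-class fatty-acid concentration and the
#' baseline and post-intervention total concentrations of the lipid class
#' (all concentrations on the log scale). The arm coefficients are
#' interpreted as z-score (SD) shifts versus the SFA-rich diet, with
#' two-sided t-test p-values.
#'
#' @param post_fa Post-intervention within-class fatty-acid concentrations
#'   (raw, > 0); the outcome is `log_z(post_fa)`.
#' @param base_fa Baseline within-class fatty-acid concentrations.
#' @param base_total,post_total Baseline / post-intervention class totals.
#' @param age,bmi Numeric covariates.
#' @param sex Factor or character.
#' @param arm Factor with levels SFA, MUFA, MUFA_PUFA (SFA taken as
#'   reference).
#' @param target Optional label for the within-class fatty acid.
#' @return A data.frame with one row per UFA arm: `target`, `arm`,
#'   `z_score`, `se`, `p_raw`, `n`.
#' @export
fit_diet_effect <- function(post_fa, base_fa, base_total, post_total,
                            age, sex, bmi, arm, target = NA_character_) {
  y <- log_z(post_fa)
  des <- diet_design(base_fa, base_total, post_total, age, sex, bmi, arm)
  fit <- ols_fit(des$X, y)
  cols <- des$arm_cols
  data.frame(
    target = target,
    arm = sub("^arm", "", cols),
    z_score = unname(fit$coef[cols]),
    se = unname(fit$se[cols]),
    p_raw = unname(fit$p[cols]),
    n = length(y),
    stringsAsFactors = FALSE
  )
}

#' Arm effects across all within-class fatty acids
#'
#' Fits [fit_diet_effect()] for every within-class fatty-acid column,
#' pairing each target with the totals of its lipid class, then applies
#' the Bonferroni correction over the family of tests.
#'
#' @param wcfa0,wcfa16 Baseline / post-intervention within-class
#'   fatty-acid matrices (samples x `CLASS[C:D]` columns) on the raw
#'   concentration scale.
#' @param totals0,totals16 Baseline / post-intervention class-total
#'   matrices (samples x class codes).
#' @param meta Data.frame with columns `age`, `sex`, `bmi`, `arm`, rows
#'   aligned with the matrices.
#' @param m_bonf Bonferroni family size; defaults to the number of models
#'   fitted.
#' @param diagnostics If `TRUE`, per-model residual diagnostics are logged
#'   (Shapiro-Wilk normality p, Breusch-Pagan homoscedasticity p);
#'   reported, never a gate.
#' @return An object of class `diet_effects`: a data.frame with columns
#'   `target`, `arm`, `z_score`, `se`, `p_raw`, `p_adj`, `significant`,
#'   `n` (and `shapiro_p` with `diagnostics = TRUE`), with the threshold
#'   and family size as attributes.
#' @export
fit_diet_effects <- function(wcfa0, wcfa16, totals0, totals16, meta,
                             m_bonf = NULL, diagnostics = FALSE) {
  stopifnot(
    identical(colnames(wcfa0), colnames(wcfa16)),
    identical(rownames(wcfa0), rownames(wcfa16)),
    nrow(meta) == nrow(wcfa0)
  )
  targets <- colnames(wcfa0)
  cls <- sub("\\[.*$", "", targets)
  rows <- vector("list", length(targets))
  shap <- bp <- rep(NA_real_, length(targets))
  n_fitted <- 0L
  for (i in seq_along(targets)) {
    tot <- cls[i]
    if (!tot %in% colnames(totals0)) {
      stop("no class total available for ", targets[i])
    }
    y <- log_z(wcfa16[, i])
    des <- diet_design(
      wcfa0[, i], totals0[, tot], totals16[, tot],
      meta$age, meta$sex, meta$bmi, meta$arm
    )
    fit <- ols_fit(des$X, y)
    n_fitted <- n_fitted + 1L
    if (diagnostics) {
      shap[i] <- stats::shapiro.test(fit$residuals)$p.value
      bp[i] <- breusch_pagan(des$X, fit$residuals)
    }
    rows[[i]] <- data.frame(
      target = targets[i],
      arm = sub("^arm", "", des$arm_cols),
      z_score = unname(fit$coef[des$arm_cols]),
      se = unname(fit$se[des$arm_cols]),
      p_raw = unname(fit$p[des$arm_cols]),
      n = nrow(wcfa0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  m <- if (is.null(m_bonf)) n_fitted else m_bonf
  adj <- bonferroni(out$p_raw, m = max(m, length(out$p_raw)))
  out$p_adj <- adj$p_adj
  out$significant <- out$p_raw < adj$threshold
  if (diagnostics) {
    out$shapiro_p <- rep(shap, each = 2L)
    out$breusch_pagan_p <- rep(bp, each = 2L)
  }
  structure(out,
    threshold = adj$threshold, m_bonf = max(m, length(out$p_raw)),
    class = c("diet_effects", "data.frame")
  )
}

# Breusch-Pagan LM statistic: n R^2 from regressing squared residuals on
# the design; chi-square with (rank - 1) df.
breusch_pagan <- function(X, residuals) {
  u <- residuals^2
  fit <- stats::lm.fit(X, u)
  r2 <- 1 - sum(fit$residuals^2) / sum((u - mean(u))^2)
  stat <- length(u) * r2
  stats::pchisq(stat, df = ncol(X) - 1L, lower.tail = FALSE)
}

#' @export
print.diet_effects <- function(x, ...) {
  cat(sprintf(
    "Dietary-arm effects: %d tests, Bonferroni threshold %.3g (m = %d)\n",
    nrow(x), attr(x, "threshold"), attr(x, "m_bonf")
  ))
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("%d significant after correction\n", nrow(sig)))
  print.data.frame(utils::head(x[order(x$p_raw), ], 10L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.diet_effects <- function(object, ...) {
  by_arm <- split(object, object$arm)
  data.frame(
    arm = names(by_arm),
    tests = vapply(by_arm, nrow, 0L),
    significant = vapply(by_arm, function(d) sum(d$significant), 0L),
    min_p = vapply(by_arm, function(d) min(d$p_raw), 0.0),
    row.names = NULL
  )
}
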