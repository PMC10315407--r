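# Prentice-weighted Cox proportional-hazards models for nested
# case-cohort data with age as the timescale (left truncation at entry).

# Validate the case-cohort record invariants shared by the reader, the
# generator and the fitter.
validate_casecohort <- function(data) {
  need <- c("id", "in_subcohort", "is_case", "entry_age", "exit_age", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing case-cohort columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$id)) stop("duplicated ids")
  if (any(data$entry_age >= data$exit_age)) {
    stop("entry_age must be < exit_age for ids: ",
         paste(data$id[data$entry_age >= data$exit_age], collapse = ", "))
  }
  if (any(data$is_case & !data$event)) stop("is_case records must have event = 1")
  if (any(!data$in_subcohort & !data$is_case)) {
    stop("non-subcohort non-cases cannot enter a case-cohort sample")
  }
  invisible(data)
}

#' Prentice risk set at a failure age
#'
#' Under the Prentice weighting for nested case-cohort data, the risk set
#' at failure age `t` consists of (a) all subcohort members under
#' observation (`entry_age < t <= exit_age`) and (b) any case failing
#' exactly at `t`, whether or not it belongs to the subcohort;
#' non-subcohort cases contribute to no other risk sets. With everyone in
#' the subcohort this reduces to the standard Cox risk set.
#'
#' @param data Case-cohort data.frame (columns `id`, `in_subcohort`,
#'   `is_case`, `entry_age`, `exit_age`, `event`).
#' @param t Failure age.
#' @return Character/whatever vector of `id`s at risk at `t` (possibly
#'   empty).
#' @export
prentice_riskset <- function(data, t) {
  validate_casecohort(data)
  at_risk <- (data$in_subcohort & data$entry_age < t & t <= data$exit_age) |
    (data$event & data$exit_age == t)
  data$id[at_risk]
}

# Newton-Raphson on the Prentice pseudo-partial-likelihood with Breslow
# tie handling. X is the n x p covariate matrix.
prentice_cox_engine <- function(entry, exit, event, sub, X,
                                tol_score = 1e-8, tol_ll = 1e-10,
                                max_iter = 30) {
  n <- nrow(X); p <- ncol(X)
  event <- as.integer(event) == 1L
  times <- sort(unique(exit[event]))
  K <- length(times)
  risksets <- vector("list", K)
  eventsets <- vector("list", K)
  for (k in seq_len(K)) {
    t <- times[k]
    risksets[[k]] <- which((sub & entry < t & t <= exit) | (event & exit == t))
    eventsets[[k]] <- which(event & exit == t)
  }
  beta <- rep(0, p)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- rep(0, p)
    I <- matrix(0, p, p)
    for (k in seq_len(K)) {
      idx <- risksets[[k]]; ev <- eventsets[[k]]; d <- length(ev)
      Xr <- X[idx, , drop = FALSE]; wr <- w[idx]
      S0 <- sum(wr)
      S1 <- colSums(Xr * wr)
      S2 <- crossprod(Xr, Xr * wr)
      xbar <- S1 / S0
      ll <- ll + sum(eta[ev]) - d * log(S0)
      U <- U + colSums(X[ev, , drop = FALSE]) - d * xbar
      I <- I + d * (S2 / S0 - tcrossprod(xbar))
    }
    trace <- c(trace, ll)
    if (max(abs(beta)) > 15) {
      stop("separation (monotone likelihood): |log HR| diverging; ",
           "consider penalization or collapsing the offending covariate")
    }
    conv_score <- max(abs(U)) < tol_score
    conv_ll <- is.finite(ll_old) && abs(ll - ll_old) < tol_ll * (abs(ll) + 1)
    if (conv_score || conv_ll) {
      return(list(beta = beta, loglik = ll, score = U, info = I,
                  iterations = iter, times = times,
                  risksets = risksets, eventsets = eventsets,
                  trace = trace))
    }
    step <- tryCatch(solve(I, U), error = function(e) {
      stop("singular information matrix; check for collinear covariates")
    })
    beta <- beta + step
    ll_old <- ll
  }
  stop("Newton-Raphson did not converge in ", max_iter,
       " iterations; log-likelihood trace: ",
       paste(signif(trace, 8), collapse = ", "))
}

# Per-record score residuals and per-event Schoenfeld residuals at the
# solution; robust (sandwich, grouped by id = record) variance.
prentice_cox_resid <- function(engine, X, event, exit) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% engine$beta); w <- exp(eta)
  A <- rep(0, n)              # sum over risk sets of d_k / S0_k
  B <- matrix(0, n, p)        # sum of (d_k / S0_k) * xbar_k
  xbar_at <- matrix(0, length(engine$times), p)
  for (k in seq_along(engine$times)) {
    idx <- engine$risksets[[k]]; d <- length(engine$eventsets[[k]])
    wr <- w[idx]
    S0 <- sum(wr)
    xbar <- colSums(X[idx, , drop = FALSE] * wr) / S0
    xbar_at[k, ] <- xbar
    A[idx] <- A[idx] + d / S0
    B[idx, ] <- B[idx, ] + matrix(xbar * (d / S0), length(idx), p, byrow = TRUE)
  }
  resid <- matrix(0, n, p)
  kmatch <- match(exit, engine$times)
  for (i in seq_len(n)) {
    term <- w[i] * (X[i, ] * A[i] - B[i, ])
    if (event[i]) {
      resid[i, ] <- (X[i, ] - xbar_at[kmatch[i], ]) - term
    } else {
      resid[i, ] <- -term
    }
  }
  Iinv <- solve(engine$info)
  D <- resid %*% Iinv
  robust <- crossprod(D)
  # Schoenfeld residuals, one row per event subject
  ev_rows <- which(event == 1)
  ev_rows <- ev_rows[order(exit[ev_rows])]
  sch <- X[ev_rows, , drop = FALSE] - xbar_at[match(exit[ev_rows], engine$times), , drop = FALSE]
  list(score_resid = resid, dfbeta = D, var_robust = robust,
       var_model = Iinv, schoenfeld = sch, schoenfeld_time = exit[ev_rows])
}

#' Fit a Prentice-weighted Cox model to case-cohort data
#'
#' Maximizes the Prentice pseudo-partial-likelihood (non-subcohort cases
#' enter the risk set only at their own failure age) with Breslow tie
#' handling by Newton-Raphson, on the age timescale with left truncation
#' at `entry_age`. Reports the log hazard ratio per unit of each
#' covariate, a robust (sandwich, grouped by record) standard error, Wald
#' 95% CI and p-value. With every record flagged `in_subcohort` the fit is
#' identical to a standard Cox model.
#'
#' @param data Case-cohort data.frame; see [prentice_riskset()] for the
#'   required design columns.
#' @param exposure Name of the exposure column (typically a
#'   log-transformed, z-normalized within-class fatty-acid concentration).
#' @param covariates Character vector of adjustment-covariate column names
#'   (factors are expanded via `model.matrix`); typically includes the log
#'   class-total concentration.
#' @return An object of class `prentice_cox` with elements `coef` (log
#'   HRs), `var` (robust), `var_model`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `loglik`, `iterations`, `n`, `n_events`, `exposure`, residual
#'   matrices for diagnostics.
#' @export
fit_prentice_cox <- function(data, exposure, covariates = character(0)) {
  validate_casecohort(data)
  if (sum(data$event) < 1L) stop("no events in the data")
  vars <- c(exposure, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  mf <- data[, vars, drop = FALSE]
  if (any(!stats::complete.cases(mf))) {
    stop("missing covariate values for ids: ",
         paste(data$id[!stats::complete.cases(mf)], collapse = ", "))
  }
  mf[] <- lapply(mf, function(v) if (is.character(v)) factor(v) else v)
  # intercept-full expansion then drop: treatment contrasts for factors
  # (a Cox model has no intercept; full dummy blocks would be constant)
  X <- stats::model.matrix(
    stats::reformulate(sprintf("`%s`", vars)), mf
  )[, -1L, drop = FALSE]
  engine <- prentice_cox_engine(
    data$entry_age, data$exit_age, as.integer(data$event),
    as.logical(data$in_subcohort), X
  )
  res <- prentice_cox_resid(engine, X, as.integer(data$event), data$exit_age)
  se <- sqrt(diag(res$var_robust))
  beta <- stats::setNames(engine$beta, colnames(X))
  z <- beta / se
  structure(
    list(
      coef = beta, se = stats::setNames(se, colnames(X)),
      var = res$var_robust, var_model = res$var_model,
      hr = exp(beta),
      ci_low = exp(beta - 1.959964 * se),
      ci_high = exp(beta + 1.959964 * se),
      p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      loglik = engine$loglik, iterations = engine$iterations,
      n = nrow(data), n_events = sum(data$event),
      n_subcohort = sum(data$in_subcohort),
      exposure = exposure,
      schoenfeld = res$schoenfeld, schoenfeld_time = res$schoenfeld_time,
      score_resid = res$score_resid
    ),
    class = "prentice_cox"
  )
}

#' @export
print.prentice_cox <- function(x, ...) {
  cat(sprintf(
    "Prentice-weighted Cox model: n = %d (%d subcohort), %d events, %d iterations\n",
    x$n, x$n_subcohort, x$n_events, x$iterations
  ))
  tab <- data.frame(
    `log HR` = x$coef, `robust SE` = x$se, HR = x$hr,
    `95% low` = x$ci_low, `95% high` = x$ci_high, p = x$p,
    check.names = FALSE
  )
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.prentice_cox <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.prentice_cox <- function(object, ...) object$coef

#' @export
vcov.prentice_cox <- function(object, ...) object$var

#' @export
confint.prentice_cox <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coef - q * object$se, object$coef + q * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.prentice_cox <- function(object, type = c("schoenfeld", "score"), ...) {
  type <- match.arg(type)
  if (type == "schoenfeld") object$schoenfeld else object$score_resid
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity; a thin,
#' order-preserving wrapper around `p.adjust(method = "BH")`. Every
#' adjusted p-value is at least its raw value.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03))  # all 0.03
fdr_bh <- function(p_raw) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Proportional-hazards diagnostics from scaled Schoenfeld residuals
#'
#' Correlates each covariate's scaled Schoenfeld residuals with event age
#' and reports the Pearson correlation and its p-value per covariate.
#' Reported as a diagnostic, never a gate.
#'
#' @param fit A [fit_prentice_cox()] result.
#' @return A data.frame with `covariate`, `correlation`, `p`, or `NULL`
#'   (with a message) when there are fewer than 2 events.
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "prentice_cox"))
  if (nrow(fit$schoenfeld) < 2L) {
    message("fewer than 2 events; Schoenfeld diagnostic skipped")
    return(NULL)
  }
  d <- nrow(fit$schoenfeld)
  scaled <- fit$schoenfeld %*% (fit$var_model * d)
  scaled <- sweep(scaled, 2L, fit$coef, `+`)
  out <- lapply(seq_along(fit$coef), function(j) {
    ct <- suppressWarnings(stats::cor.test(scaled[, j], fit$schoenfeld_time))
    data.frame(
      covariate = names(fit$coef)[j],
      correlation = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Case-cohort associations across a panel of exposures
#'
#' Fits one Prentice-weighted Cox model per exposure column, each adjusted
#' for the shared covariates (plus, per exposure, an optional class-total
#' column), then applies Benjamini-Hochberg and Bonferroni corrections
#' side by side.
#'
#' @param data Case-cohort data.frame containing all exposure and
#'   covariate columns.
#' @param exposures Character vector of exposure column names.
#' @param covariates Shared adjustment covariate names.
#' @param class_total_of Optional named character vector mapping an
#'   exposure to its class-total column.
#' @param outcome Label (e.g. `"T2D"`, `"CVD"`) carried into the table.
#' @param m_bonf Bonferroni family size; defaults to the number of
#'   exposures tested.
#' @return A data.frame with one row per exposure: `target`, `outcome`,
#'   `log_hr`, `hr`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`, `p_bonf`,
#'   `n`, `n_cases`.
#' @export
cch_associations <- function(data, exposures, covariates = character(0),
                             class_total_of = NULL, outcome = "T2D",
                             m_bonf = NULL) {
  rows <- lapply(exposures, function(ex) {
    covs <- covariates
    if (!is.null(class_total_of) && ex %in% names(class_total_of)) {
      covs <- c(covs, class_total_of[[ex]])
    }
    fit <- fit_prentice_cox(data, ex, covs)
    j <- grep(ex, names(fit$coef), fixed = TRUE)[1L]
    data.frame(
      target = ex, outcome = outcome,
      log_hr = unname(fit$coef[j]), hr = unname(fit$hr[j]),
      ci_low = unname(fit$ci_low[j]), ci_high = unname(fit$ci_high[j]),
      p_raw = unname(fit$p[j]), n = fit$n, n_cases = fit$n_events,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  m <- if (is.null(m_bonf)) length(exposures) else m_bonf
  out$p_fdr <- fdr_bh(out$p_raw)
  out$p_bonf <- bonferroni(out$p_raw, m = max(m, nrow(out)))$p_adj
  out
}
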