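test_that("Bonferroni control uses the configured family size", {
  b282 <- bonferroni(c(1e-5, 0.01), m = 282)
  expect_equal(signif(b282$threshold, 2), 0.00018)
  expect_equal(b282$p_adj, c(min(1, 282e-5), 1))
  b41 <- bonferroni(0.5, m = 41)
  expect_equal(signif(b41$threshold, 2), 0.0012)
  expect_equal(bonferroni(0, m = 7)$p_adj, 0)
  # adjusted values are monotone in the raw values and capped at 1
  p <- sort(runif(20))
  adj <- bonferroni(p, m = 25)$p_adj
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(bonferroni(0.5, m = 0), ">= 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "length")
})

test_that("a zero-noise linear outcome is interpolated exactly", {
  cv <- make_trial_covariates(seed = 4)
  lin <- with(cv, 0.3 * log(base_fa) + 0.1 * log(base_total) + 0.02 * age -
                0.01 * bmi + 0.2 * (sex == "M") - 0.9 * (arm == "MUFA") +
                0.4 * (arm == "MUFA_PUFA"))
  post_fa <- exp(lin)  # outcome becomes (lin - mean)/sd(lin)
  res <- fit_diet_effect(post_fa, cv$base_fa, cv$base_total, cv$post_total,
                         cv$age, cv$sex, cv$bmi, cv$arm)
  s <- sd(lin)
  expect_equal(res$z_score[res$arm == "MUFA"], -0.9 / s, tolerance = 1e-8)
  expect_equal(res$z_score[res$arm == "MUFA_PUFA"], 0.4 / s, tolerance = 1e-8)
})

test_that("arm coefficients are invariant to rescaling the outcome", {
  cv <- make_trial_covariates(seed = 5)
  set.seed(6)
  post_fa <- exp(rnorm(113, 1, 0.4) - 0.5 * (cv$arm == "MUFA"))
  r1 <- fit_diet_effect(post_fa, cv$base_fa, cv$base_total, cv$post_total,
                        cv$age, cv$sex, cv$bmi, cv$arm)
  # multiplying concentrations shifts logs by a constant; z-scores and
  # hence arm coefficients are unchanged
  r2 <- fit_diet_effect(post_fa * 7, cv$base_fa, cv$base_total, cv$post_total,
                        cv$age, cv$sex, cv$bmi, cv$arm)
  expect_equal(r1$z_score, r2$z_score, tolerance = 1e-10)
  expect_equal(r1$se, r2$se, tolerance = 1e-10)
})

test_that("constant class totals leave the fit unchanged (inert adjustment)", {
  cv <- make_trial_covariates(seed = 7)
  set.seed(8)
  post_fa <- exp(rnorm(113, 1, 0.4))
  const <- rep(5, 113)
  r_const <- fit_diet_effect(post_fa, cv$base_fa, const, const,
                             cv$age, cv$sex, cv$bmi, cv$arm)
  # reference fit without the total adjustors at all
  y <- log_z(post_fa)
  ref <- lm(y ~ log(cv$base_fa) + cv$age + factor(cv$sex) + cv$bmi + cv$arm)
  cf <- summary(ref)$coefficients
  expect_equal(r_const$z_score,
               unname(cf[grep("arm", rownames(cf)), "Estimate"]),
               tolerance = 1e-10)
})

test_that("model validation rejects degenerate designs", {
  cv <- make_trial_covariates(seed = 9)
  post_fa <- exp(rnorm(113, 1, 0.4))
  expect_error(
    fit_diet_effect(post_fa, cv$base_fa, cv$base_total, cv$post_total,
                    cv$age, cv$sex, cv$bmi, factor(rep("SFA", 113))),
    "3 levels"
  )
  base_na <- cv$base_fa; base_na[3] <- NA
  expect_error(
    fit_diet_effect(post_fa, base_na, cv$base_total, cv$post_total,
                    cv$age, cv$sex, cv$bmi, cv$arm),
    "missing covariates.*3"
  )
  # collinear covariates are named
  expect_error(
    fit_diet_effect(post_fa, cv$base_fa, cv$base_total, cv$base_total * 2,
                    cv$age, cv$sex, cv$bmi, cv$arm),
    "collinear.*post_total"
  )
})

test_that("a configured -1.08 SD arm shift is recovered within 2 SE", {
  tr <- gen_trial(seed = 7)
  keep <- colnames(filter_missing(rbind(tr$week0, tr$week16))$matrix)
  i0 <- impute_qrilc(tr$week0[, keep], seed = 1)
  i16 <- impute_qrilc(tr$week16[, keep], seed = 2)
  de <- fit_diet_effects(
    within_class_fa(i0$matrix), within_class_fa(i16$matrix),
    class_totals(i0$matrix), class_totals(i16$matrix), tr$meta
  )
  row <- de[de$target == "DAG[20:0]" & de$arm == "MUFA", ]
  expect_lt(abs(row$z_score - (-1.08)), 2 * row$se)
  expect_lt(row$se, 0.25)
  expect_true(row$significant)
  # the adjusted p respects the configured family size
  expect_true(all(de$p_adj >= de$p_raw))
  expect_true(all(de$p_adj <= 1))
})

test_that("residual diagnostics are logged per model, never gate results", {
  pn <- default_panel(); pn$detect_q <- 0
  tr <- gen_trial(panel = pn, seed = 2)
  w0 <- within_class_fa(tr$week0)
  w16 <- within_class_fa(tr$week16)
  de <- fit_diet_effects(w0, w16, class_totals(tr$week0),
                         class_totals(tr$week16), tr$meta,
                         diagnostics = TRUE)
  expect_true(all(de$shapiro_p >= 0 & de$shapiro_p <= 1))
  expect_true(all(de$breusch_pagan_p >= 0 & de$breusch_pagan_p <= 1))
  # cross-check the Breusch-Pagan statistic against an independent
  # implementation on one model
  y <- log_z(w16[, 1])
  df <- data.frame(
    y = y, bf = log(w0[, 1]), bt = log(class_totals(tr$week0)[, "CE"]),
    pt = log(class_totals(tr$week16)[, "CE"]), age = tr$meta$age,
    sex = factor(tr$meta$sex), bmi = tr$meta$bmi,
    arm = relevel(factor(tr$meta$arm), "SFA")
  )
  ref <- lmtest::bptest(lm(y ~ bf + bt + pt + age + sex + bmi + arm, df))
  X <- model.matrix(~ bf + bt + pt + age + sex + bmi + arm, df)
  mine <- lipidfa:::breusch_pagan(X, residuals(lm(y ~ bf + bt + pt + age + sex + bmi + arm, df)))
  expect_equal(mine, unname(ref$p.value), tolerance = 1e-8)
})
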