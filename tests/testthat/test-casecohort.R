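toy_records <- function() {
  data.frame(
    id = c("a", "b", "c"),
    in_subcohort = c(FALSE, TRUE, TRUE),
    is_case = c(TRUE, FALSE, TRUE),
    entry_age = c(50, 50, 50),
    exit_age = c(60, 70, 65),
    event = c(1, 0, 1),
    stringsAsFactors = FALSE
  )
}

test_that("Prentice risk sets admit outside cases only at their failure age", {
  rec <- toy_records()
  # non-subcohort case only at its own failure age
  expect_setequal(prentice_riskset(rec, 60), c("a", "b", "c"))
  expect_setequal(prentice_riskset(rec, 59), c("b", "c"))
  expect_setequal(prentice_riskset(rec, 61), c("b", "c"))
  # subcohort non-case at risk over its whole observation window
  expect_true("b" %in% prentice_riskset(rec, 70))
  expect_false("b" %in% prentice_riskset(rec, 70.5))
  expect_false("b" %in% prentice_riskset(rec, 50))
  # outside all windows: empty, not an error
  expect_length(prentice_riskset(rec, 90), 0L)
})

test_that("record invariants are enforced", {
  rec <- toy_records()
  bad1 <- rec; bad1$exit_age[1] <- 49
  expect_error(validate_cc(bad1), "entry_age")
  bad2 <- rec; bad2$event[3] <- 0
  expect_error(validate_cc(bad2), "event = 1")
  bad3 <- rec; bad3$is_case[1] <- FALSE
  expect_error(validate_cc(bad3), "non-subcohort")
  bad4 <- rec; bad4$id[2] <- "a"
  expect_error(validate_cc(bad4), "duplicated")
})

test_that("the full-cohort fit equals an independent standard Cox fit", {
  sp <- cohort_spec(n_cohort = 600, n_subcohort = 600, log_hr = log(1.8),
                    target_cases = 120)
  cc <- gen_casecohort(sp, seed = 2)
  expect_true(all(cc$in_subcohort))
  fit <- fit_prentice_cox(cc, "exposure", c("sex", "waist", "smoking"))
  oracle <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ exposure + sex + waist + smoking,
    data = cc, ties = "breslow"
  )
  expect_equal(unname(fit$coef), unname(coef(oracle)), tolerance = 1e-6)
})

test_that("the case-cohort fit matches the epsilon-entry Cox construction", {
  cc <- gen_casecohort(seed = 1)
  fit <- fit_prentice_cox(cc, "exposure",
                          c("sex", "waist", "smoking", "class_total"))
  eps <- cc
  eps$entry_age[!eps$in_subcohort] <- eps$exit_age[!eps$in_subcohort] - 1e-7
  oracle <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ exposure + sex + waist +
      smoking + class_total,
    data = eps, ties = "breslow", robust = TRUE, id = id,
    control = survival::coxph.control(timefix = FALSE)
  )
  expect_equal(unname(fit$coef), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-4)
})

test_that("monotone likelihoods are reported as separation", {
  rec <- data.frame(
    id = 1:2, in_subcohort = TRUE, is_case = c(TRUE, FALSE),
    entry_age = c(50, 50), exit_age = c(60, 70), event = c(1, 0),
    x = c(1, 0)
  )
  expect_error(fit_prentice_cox(rec, "x"), "separation")
  expect_error(
    fit_prentice_cox(transform(rec, event = 0, is_case = FALSE), "x"),
    "no events"
  )
})

test_that("log hazard ratios are equivariant under exposure rescaling", {
  cc <- gen_casecohort(cohort_spec(log_hr = log(1.6)), seed = 3)
  f1 <- fit_prentice_cox(cc, "exposure", "sex")
  cc2 <- transform(cc, exposure = 2 * exposure)
  f2 <- fit_prentice_cox(cc2, "exposure", "sex")
  expect_equal(unname(f2$coef["exposure"]), unname(f1$coef["exposure"]) / 2,
               tolerance = 1e-6)
  expect_equal(unname(f2$se["exposure"]), unname(f1$se["exposure"]) / 2,
               tolerance = 1e-6)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(0.07), 0.07)
  p <- c(0.001, 0.5, 0.02, 0.9)
  expect_true(all(fdr_bh(p) >= p))
  expect_equal(order(fdr_bh(p)), order(p))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Schoenfeld diagnostics behave under and against proportional hazards", {
  # proportional hazards: few small p-values across replicates
  small_p <- 0L
  n_tests <- 0L
  for (i in 1:15) {
    cc <- gen_casecohort(
      cohort_spec(n_cohort = 800, n_subcohort = 800, log_hr = log(1.5),
                  target_cases = 120), seed = 100 + i)
    f <- fit_prentice_cox(cc, "exposure", "sex")
    d <- schoenfeld_check(f)
    small_p <- small_p + sum(d$p < 0.05)
    n_tests <- n_tests + nrow(d)
  }
  expect_lt(small_p / n_tests, 0.2)

  # strong time-increasing effect: mostly detected
  detect <- 0L
  for (i in 1:8) {
    set.seed(200 + i)
    n <- 800
    x <- runif(n, -1, 1)
    # hazard lambda0 * t^(b0 x) gives a log-time-varying coefficient
    b0 <- 1.2
    u <- rexp(n)
    tt <- (u * (b0 * x + 1.5) / 0.05)^(1 / (b0 * x + 1.5))
    cens <- runif(n, 2, 12)
    rec <- data.frame(
      id = seq_len(n), in_subcohort = TRUE, event = as.integer(tt <= cens),
      entry_age = 0.001, exit_age = pmin(tt, cens), x = x
    )
    rec$is_case <- rec$event == 1
    rec <- rec[rec$exit_age > rec$entry_age, ]
    f <- fit_prentice_cox(rec, "x")
    d <- schoenfeld_check(f)
    if (d$p[d$covariate == "x"] < 0.05) detect <- detect + 1L
  }
  expect_gte(detect, 5L)
})

test_that("association tables carry both corrections and the design counts", {
  cc <- gen_casecohort(cohort_spec(n_cohort = 2000, n_subcohort = 250,
                                   log_hr = log(2), target_cases = 120),
                       seed = 9)
  cc$exposure2 <- rnorm(nrow(cc))
  tab <- cch_associations(
    cc, exposures = c("exposure", "exposure2"),
    covariates = c("sex", "waist"),
    class_total_of = c(exposure = "class_total"),
    outcome = "T2D", m_bonf = 41
  )
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$hr, exp(tab$log_hr))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-12))
  expect_equal(tab$p_bonf, pmin(1, 41 * tab$p_raw))
  expect_equal(unique(tab$n_cases), sum(cc$event))
})
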