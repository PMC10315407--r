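# Shared toy covariates for the regression-model tests.
make_trial_covariates <- function(n = 113, seed = 1) {
  set.seed(seed)
  list(
    age = rnorm(n, 44, 10),
    sex = sample(c("F", "M"), n, TRUE),
    bmi = rnorm(n, 27, 4),
    arm = factor(rep(c("SFA", "MUFA", "MUFA_PUFA"), length.out = n),
                 levels = c("SFA", "MUFA", "MUFA_PUFA")),
    base_fa = exp(rnorm(n, 1, 0.5)),
    base_total = exp(rnorm(n, 3, 0.4)),
    post_total = exp(rnorm(n, 3, 0.4))
  )
}

# lambda values explored for the winning alpha of a tuning run
lambda_grid_of <- function(tu) {
  tu$cv_table$lambda[tu$cv_table$alpha == tu$alpha]
}

validate_cc <- lipidfa:::validate_casecohort
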