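# Synthetic-data generators: a three-arm high-fat dietary trial with a
# miniature lipid panel, and a nested case-cohort with Cox-generated event
# ages. These emulate the statistical structure every pipeline stage
# assumes (log-normal species with within-class correlation, detection
# limit left-censoring, arm shifts on the within-class fatty-acid log
# scale, linear marker responses, Prentice-compatible sampling), not the
# mass-spectrometry physics.

#' Default miniature lipid panel
#'
#' A fixed ~65-species panel spanning all 16 lipid classes and 12 fatty
#' acids, with per-species log-mean and log-SD concentrations (log
#' umol/L), a within-class exchangeable correlation, and per-species
#' detection-limit quantiles. Most species are fully observed; a subset
#' carries moderate censoring and one species (`DCER(18:0)`) a 0.8
#' detection quantile so the >= 75% missingness exclusion is exercised.
#'
#' @param rho Within-class exchangeable correlation of log concentrations;
#'   default 0.4.
#' @return A data.frame with columns `species`, `log_mean`, `log_sd`,
#'   `detect_q`, plus attribute `rho`.
#' @export
default_panel <- function(rho = 0.4) {
  species <- c(
    "CE(12:0)", "CE(16:0)", "CE(18:0)", "CE(18:1)", "CE(18:2)", "CE(22:1)",
    "MAG(12:0)", "MAG(14:1)", "MAG(16:0)", "MAG(18:1)",
    "LPC(15:0)", "LPC(16:0)", "LPC(17:0)", "LPC(18:0)",
    "LPE(18:0)", "LPE(18:1)",
    "SM(14:0)", "SM(16:0)", "SM(18:0)", "SM(24:1)",
    "CER(16:0)", "CER(18:0)", "CER(24:1)",
    "DCER(16:0)", "DCER(18:0)", "DCER(24:1)",
    "HCER(14:0)", "HCER(16:0)", "HCER(18:1)",
    "LCER(16:0)", "LCER(24:1)",
    "DAG(16:0/16:0)", "DAG(16:0/14:0)", "DAG(16:0/18:1)", "DAG(18:0/18:1)",
    "DAG(20:0/16:0)", "DAG(20:0/18:0)", "DAG(18:1/18:2)", "DAG(18:2/18:2)",
    "TG(12:0/16:0/18:1)", "TG(16:0/16:0/18:1)", "TG(16:0/18:1/18:2)",
    "TG(14:0/16:0/16:0)", "TG(17:0/18:1/18:1)", "TG(18:0/18:1/18:2)",
    "TG(20:0/16:0/18:1)", "TG(22:1/18:1/18:1)", "TG(16:0/16:0/16:0)",
    "TG(18:1/18:1/18:1)",
    "PC(16:0/18:1)", "PC(16:0/18:2)", "PC(18:0/18:1)", "PC(18:0/18:2)",
    "PC(16:0/16:0)", "PC(14:1/18:1)",
    "PE(16:0/18:1)", "PE(18:0/18:2)", "PE(16:0/18:2)", "PE(18:0/18:1)",
    "PEO(16:0/18:1)", "PEO(18:0/18:2)",
    "PEP(18:0/18:1)", "PEP(16:0/18:2)",
    "PI(16:0/18:1)", "PI(18:0/18:2)", "PI(18:0/18:1)"
  )
  cls <- sub("\\(.*$", "", species)
  base <- c(
    TG = 3.5, CE = 3.2, PC = 3.0, SM = 2.2, LPC = 1.8, DAG = 1.2,
    PE = 1.0, PI = 0.8, PEO = 0.3, PEP = 0.3, CER = 0.0, MAG = -0.5,
    LPE = -0.5, HCER = -1.0, DCER = -1.5, LCER = -1.5
  )
  # deterministic within-class spread so species are not identical
  idx <- stats::ave(seq_along(species), cls, FUN = seq_along)
  log_mean <- unname(base[cls]) + 0.3 * (idx - mean(idx))
  detect_q <- rep(0, length(species))
  detect_q[seq_along(species) %% 6 == 0] <- 0.2
  detect_q[species == "DCER(18:0)"] <- 0.8
  out <- data.frame(
    species = species, log_mean = log_mean, log_sd = 0.5,
    detect_q = detect_q, stringsAsFactors = FALSE
  )
  attr(out, "rho") <- rho
  out
}

#' Default dietary-trial specification
#'
#' Three isoenergetic high-fat arms (SFA-rich reference, MUFA-rich,
#' MUFA/PUFA-rich) with per-arm sizes 38/39/36, intervention shifts on
#' the within-class fatty-acid log scale (in SD units), and linear marker
#' response models. Default shift magnitudes and marker coefficients
#' follow the effect sizes the pipeline is designed to detect: e.g. a
#' -1.08 SD shift of DAG[20:0] under the MUFA-rich arm, and an LDL change
#' of 0.20 per SD change of CE[18:0] plus 0.15 per SD change of TG[12:0].
#'
#' @return A list with `n_arm`, `arm_effects` (data.frame `target`, `arm`,
#'   `z`), `marker_models` (named list with `betas`, `noise_sd`,
#'   `baseline_mean`, `baseline_sd`), `tracking` (week-0/week-16 latent
#'   correlation) and covariate distributions.
#' @export
trial_spec <- function() {
  list(
    n_arm = c(SFA = 38, MUFA = 39, MUFA_PUFA = 36),
    arm_effects = data.frame(
      target = c("DAG[20:0]", "HCER[14:0]", "SM[24:1]", "TG[22:1]",
                 "DAG[18:2]", "TG[18:2]"),
      arm = c("MUFA", "MUFA", "MUFA", "MUFA", "MUFA_PUFA", "MUFA_PUFA"),
      z = c(-1.08, -1.08, 0.55, 0.53, 0.29, 0.30),
      stringsAsFactors = FALSE
    ),
    marker_models = list(
      ldl = list(betas = c("CE[18:0]" = 0.20, "TG[12:0]" = 0.15),
                 noise_sd = 0.35, baseline_mean = 2.8, baseline_sd = 0.8),
      total_cholesterol = list(betas = c("CE[18:0]" = 0.26),
                 noise_sd = 0.45, baseline_mean = 5.2, baseline_sd = 0.9),
      arterial_stiffness = list(betas = c("LPC[15:0]" = 0.34),
                 noise_sd = 1.0, baseline_mean = 7.0, baseline_sd = 1.5),
      p_selectin = list(betas = c("CE[12:0]" = 2.41),
                 noise_sd = 8.0, baseline_mean = 45, baseline_sd = 12),
      pulse_pressure = list(betas = c("MAG[12:0]" = 1.92),
                 noise_sd = 5.0, baseline_mean = 45, baseline_sd = 8)
    ),
    tracking = 0.3,
    age = c(mean = 43.8, sd = 10.2),
    bmi = c(mean = 26.8, sd = 4.3),
    p_female = 0.602
  )
}

#' Generate a synthetic dietary-fat trial
#'
#' Baseline species concentrations are multivariate log-normal with
#' within-class exchangeable correlation; week-16 concentrations track
#' baseline with latent correlation `tracking` and apply the configured
#' arm shifts. A configured z-shift for a within-class fatty acid is
#' applied as a common log-scale shift (`z * sd(log aggregate)`) to every
#' species containing that fatty acid, which moves the aggregated
#' within-class fatty-acid concentration by exactly the configured amount
#' in the sample's arm. Detection-limit censoring then replaces values
#' below each species' configured quantile with `NA`. Risk markers are
#' generated as baseline plus a linear combination of z-scored
#' within-class fatty-acid changes plus Gaussian noise.
#'
#' @param spec A [trial_spec()] list.
#' @param panel A [default_panel()] data.frame.
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return A list with `week0`, `week16` (samples x species matrices with
#'   `NA` below the detection limit), `markers0`, `markers16`
#'   (data.frames), `meta` (sample_id, arm, age, sex, bmi) and `truth`
#'   (uncensored matrices, applied shifts, thresholds, marker models,
#'   seed).
#' @export
gen_trial <- function(spec = trial_spec(), panel = default_panel(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- sum(spec$n_arm)
  arm <- factor(rep(names(spec$n_arm), spec$n_arm),
                levels = names(spec$n_arm))
  ids <- sprintf("S%03d", seq_len(n))
  rho <- attr(panel, "rho")
  if (is.null(rho)) rho <- 0.4
  cls <- sub("\\(.*$", "", panel$species)
  classes <- unique(cls)
  p <- nrow(panel)
  r <- spec$tracking

  latent <- function(Zc_prev = NULL, Ec_prev = NULL) {
    Zc <- matrix(stats::rnorm(n * length(classes)), n, length(classes),
                 dimnames = list(ids, classes))
    Ec <- matrix(stats::rnorm(n * p), n, p)
    if (!is.null(Zc_prev)) {
      Zc <- r * Zc_prev + sqrt(1 - r^2) * Zc
      Ec <- r * Ec_prev + sqrt(1 - r^2) * Ec
    }
    list(Zc = Zc, Ec = Ec)
  }
  compose <- function(lat) {
    Z <- sqrt(rho) * lat$Zc[, cls, drop = FALSE] + sqrt(1 - rho) * lat$Ec
    sweep(sweep(Z, 2L, panel$log_sd, `*`), 2L, panel$log_mean, `+`)
  }
  lat0 <- latent()
  log0 <- compose(lat0)
  lat16 <- latent(lat0$Zc, lat0$Ec)
  log16 <- compose(lat16)
  colnames(log0) <- colnames(log16) <- panel$species

  # Arm shifts on the within-class FA log scale. Every species containing
  # the target FA is scaled by exp(delta), which moves the aggregated
  # within-class FA by exactly delta on the log scale; the remaining
  # species of the class are rescaled so the class total is preserved,
  # keeping the total-adjustment covariates unconfounded with the arm.
  conc0 <- exp(log0)
  conc16 <- exp(log16)
  rownames(conc0) <- rownames(conc16) <- ids
  agg0 <- within_class_fa(conc0)
  shifts <- spec$arm_effects
  if (nrow(shifts)) {
    miss <- setdiff(shifts$target, colnames(agg0))
    if (length(miss)) {
      stop("arm effect references absent within-class fatty acid: ",
           paste(miss, collapse = ", "))
    }
    parsed <- parse_species_all(panel$species)
    shifts$sd_log <- shifts$delta_log <- NA_real_
    for (i in seq_len(nrow(shifts))) {
      key <- shifts$target[i]
      tcls <- sub("\\[.*$", "", key)
      tfa <- sub("^.*\\[(.*)\\]$", "\\1", key)
      contrib <- vapply(parsed, function(sp) {
        sp$lipid_class == tcls && tfa %in% sp$chains
      }, NA)
      others <- cls == tcls & !contrib
      sd_log <- stats::sd(log(agg0[, key]))
      in_arm <- arm == shifts$arm[i]
      # the configured shift is expressed on the z scale of the analyzed
      # outcome, whose SD includes the shift-induced between-arm variance:
      # inflate the log shift so the z-scored effect equals the target
      p_arm <- mean(in_arm)
      denom <- 1 - shifts$z[i]^2 * p_arm * (1 - p_arm)
      if (denom <= 0.1) stop("configured z-shift too large for ", key)
      delta <- shifts$z[i] * sd_log / sqrt(denom)
      fc <- exp(delta)
      A <- rowSums(conc16[in_arm, contrib, drop = FALSE])
      conc16[in_arm, contrib] <- conc16[in_arm, contrib] * fc
      if (any(others)) {
        O <- rowSums(conc16[in_arm, others, drop = FALSE])
        g <- (A + O - A * fc) / O
        if (any(g <= 0)) {
          stop("shift for ", key, " too large to preserve the class total")
        }
        conc16[in_arm, others] <- conc16[in_arm, others] * g
      }
      shifts$sd_log[i] <- sd_log
      shifts$delta_log[i] <- delta
    }
  }

  # covariates and markers
  age <- stats::rnorm(n, spec$age["mean"], spec$age["sd"])
  bmi <- stats::rnorm(n, spec$bmi["mean"], spec$bmi["sd"])
  sex <- ifelse(stats::runif(n) < spec$p_female, "F", "M")
  agg16 <- within_class_fa(conc16)
  agg0 <- within_class_fa(conc0)
  markers0 <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  markers16 <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (mk in names(spec$marker_models)) {
    mm <- spec$marker_models[[mk]]
    missfa <- setdiff(names(mm$betas), colnames(agg0))
    if (length(missfa)) {
      stop("marker model '", mk, "' references absent within-class fatty acid: ",
           paste(missfa, collapse = ", "))
    }
    base <- stats::rnorm(n, mm$baseline_mean, mm$baseline_sd)
    dz <- scale(agg16[, names(mm$betas), drop = FALSE] -
                  agg0[, names(mm$betas), drop = FALSE])
    post <- base + drop(dz %*% mm$betas) + stats::rnorm(n, 0, mm$noise_sd)
    markers0[[mk]] <- base
    markers16[[mk]] <- post
  }

  # detection-limit left-censoring on the pooled visits
  thresholds <- rep(NA_real_, p)
  names(thresholds) <- panel$species
  week0 <- conc0
  week16 <- conc16
  for (j in seq_len(p)) {
    q <- panel$detect_q[j]
    if (q <= 0) next
    thr <- stats::quantile(c(conc0[, j], conc16[, j]), probs = q,
                           names = FALSE)
    thresholds[j] <- thr
    week0[week0[, j] < thr, j] <- NA
    week16[week16[, j] < thr, j] <- NA
  }

  list(
    week0 = week0, week16 = week16,
    markers0 = markers0, markers16 = markers16,
    meta = data.frame(
      sample_id = ids, arm = arm, age = age, sex = sex, bmi = bmi,
      stringsAsFactors = FALSE
    ),
    truth = list(
      conc0 = conc0, conc16 = conc16, shifts = shifts,
      thresholds = thresholds, marker_models = spec$marker_models,
      panel = panel, seed = as.integer(seed)
    )
  )
}

#' Default nested case-cohort specification
#'
#' A scaled-down nested case-cohort: a cohort of 5000 with a random
#' subcohort of 300 and a baseline hazard calibrated so that roughly 180
#' incident cases occur over 6-10 years of follow-up after entry between
#' ages 35 and 65. The exposure is a z-scored (log) within-class
#' fatty-acid concentration with configurable true log hazard ratio;
#' a reduced confounder set (sex, one continuous, one binary covariate)
#' and a correlated log class-total complete the model.
#'
#' @param n_cohort,n_subcohort Cohort / random-subcohort sizes.
#' @param log_hr True log hazard ratio per SD of the exposure.
#' @param target_cases Approximate expected number of incident cases.
#' @return A specification list consumed by [gen_casecohort()].
#' @export
cohort_spec <- function(n_cohort = 5000, n_subcohort = 300,
                        log_hr = log(2.84), target_cases = 180) {
  list(
    n_cohort = n_cohort, n_subcohort = n_subcohort, log_hr = log_hr,
    target_cases = target_cases,
    covariate_effects = c(sex_male = 0.3, waist = 0.02, smoking = 0.4),
    class_total_effect = 0.2,
    exposure_total_cor = 0.5,
    entry_range = c(35, 65), followup_range = c(6, 10),
    p_male = 0.4, p_smoking = 0.25,
    waist = c(mean = 90, sd = 12)
  )
}

#' Generate a synthetic nested case-cohort
#'
#' Simulates full-cohort event ages from a proportional-hazards model with
#' constant baseline hazard on the age timescale (entry age uniform on the
#' configured range, exponential residual event time, administrative
#' censoring at the end of follow-up), draws the random subcohort, and
#' emits subcohort members plus all incident cases. Each record's exit age
#' is the minimum of the event age and the censoring age, and non-
#' subcohort non-cases never enter the sample. True parameters are
#' attached for recovery tests.
#'
#' @param spec A [cohort_spec()] list.
#' @param seed Integer seed.
#' @return A data.frame of case-cohort records (`id`, `in_subcohort`,
#'   `is_case`, `entry_age`, `exit_age`, `event`, `exposure`,
#'   `class_total`, `sex`, `waist`, `smoking`) with attribute `truth`.
#' @export
gen_casecohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(spec$n_subcohort <= spec$n_cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  N <- spec$n_cohort
  exposure <- stats::rnorm(N)
  rho <- spec$exposure_total_cor
  class_total <- rho * exposure + sqrt(1 - rho^2) * stats::rnorm(N)
  sex <- ifelse(stats::runif(N) < spec$p_male, "M", "F")
  waist <- stats::rnorm(N, spec$waist["mean"], spec$waist["sd"])
  smoking <- as.integer(stats::runif(N) < spec$p_smoking)
  eta <- spec$log_hr * exposure +
    spec$covariate_effects["sex_male"] * (sex == "M") +
    spec$covariate_effects["waist"] * (waist - spec$waist["mean"]) +
    spec$covariate_effects["smoking"] * smoking +
    spec$class_total_effect * class_total
  eta <- unname(eta)
  mean_fu <- mean(spec$followup_range)
  lambda0 <- (spec$target_cases / N) / (mean_fu * mean(exp(eta)))
  entry <- stats::runif(N, spec$entry_range[1], spec$entry_range[2])
  t_event <- stats::rexp(N, rate = lambda0 * exp(eta))
  t_cens <- stats::runif(N, spec$followup_range[1], spec$followup_range[2])
  event <- as.integer(t_event <= t_cens)
  exit <- entry + pmin(t_event, t_cens)
  if (sum(event) == 0L) {
    stop("no cases generated; increase the baseline hazard or cohort size")
  }
  sub <- rep(FALSE, N)
  sub[sample.int(N, spec$n_subcohort)] <- TRUE
  keep <- sub | event == 1L
  out <- data.frame(
    id = sprintf("P%05d", seq_len(N))[keep],
    in_subcohort = sub[keep],
    is_case = event[keep] == 1L,
    entry_age = entry[keep],
    exit_age = exit[keep],
    event = event[keep],
    exposure = exposure[keep],
    class_total = class_total[keep],
    sex = sex[keep],
    waist = waist[keep],
    smoking = smoking[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(
    log_hr = spec$log_hr, lambda0 = lambda0,
    covariate_effects = spec$covariate_effects,
    class_total_effect = spec$class_total_effect,
    n_cases = sum(event), spec = spec, seed = as.integer(seed)
  )
  validate_casecohort(out)
}

#' Materialize the default synthetic fixture bundle
#'
#' Writes the trial matrices (wide, tab-delimited, empty fields for
#' censored cells), marker and metadata tables, the case-cohort table,
#' and a JSON manifest of the true generating parameters.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial <- gen_trial(seed = seed)
  cc <- gen_casecohort(seed = seed + 1L)
  wm <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  paths <- c(
    week0 = file.path(dir, "species_week0.tsv"),
    week16 = file.path(dir, "species_week16.tsv"),
    markers0 = file.path(dir, "markers_week0.tsv"),
    markers16 = file.path(dir, "markers_week16.tsv"),
    meta = file.path(dir, "samples.tsv"),
    casecohort = file.path(dir, "casecohort.tsv"),
    truth = file.path(dir, "truth.json")
  )
  wm(trial$week0, paths["week0"])
  wm(trial$week16, paths["week16"])
  utils::write.table(trial$markers0, paths["markers0"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(trial$markers16, paths["markers16"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(trial$meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cc, paths["casecohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    trial_shifts = trial$truth$shifts,
    thresholds = as.list(trial$truth$thresholds[!is.na(trial$truth$thresholds)]),
    casecohort = attr(cc, "truth")[c("log_hr", "lambda0", "n_cases")],
    seed = seed
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
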