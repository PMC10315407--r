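# Pipeline driver: config validation, stage orchestration, audit manifest.

#' Read a concentration table
#'
#' Wide layout: one `sample_id` column plus one column per species (names
#' parse as lipid shorthand). Long layout: columns `sample_id`, `species`,
#' `value`. Empty fields (or `na_string`) mark values below the detection
#' limit.
#'
#' @param path Delimited text file (tab by default).
#' @param layout `"wide"` or `"long"`.
#' @param sep Field separator.
#' @param na_string Missing-value sentinel in addition to empty fields.
#' @return Numeric samples x species matrix with `NA` for missing cells.
#' @export
read_concentrations <- function(path, layout = c("wide", "long"),
                                sep = "\t", na_string = "NA") {
  layout <- match.arg(layout)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", na_string),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (names(tab)[1L] != "sample_id") stop("wide layout needs a leading sample_id column")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab$sample_id
  } else {
    need <- c("sample_id", "species", "value")
    if (!all(need %in% names(tab))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(tab[, c("sample_id", "species")])) {
      stop("duplicated (sample, species) cells")
    }
    m <- stats::xtabs(value ~ sample_id + species, data = tab,
                      addNA = FALSE, sparse = FALSE)
    obs <- stats::xtabs(~ sample_id + species, data = tab) > 0
    m[!obs] <- NA
    m <- unclass(m)
    names(dimnames(m)) <- NULL
  }
  storage.mode(m) <- "double"
  invisible(parse_species_all(colnames(m)))  # fail fast on bad names
  m
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file path) with input paths,
#' stage toggles, thresholds and a master seed. Defaults: missingness
#' threshold 0.75, `retain_min` 9 of 10 iterations, FDR q 0.05,
#' Bonferroni family size = number of models fitted.
#'
#' @param config Named list or YAML path.
#' @return The validated, default-filled config list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    missingness_threshold = 0.75,
    tune_sigma = 1.0,
    retain_min = 9,
    folds = 10,
    train_fraction = 0.8,
    alphas = seq(0.1, 1, by = 0.1),
    fdr_q = 0.05,
    m_bonf = NULL,
    seed = 1,
    stages = list(diet_effects = TRUE, enr = FALSE, casecohort = FALSE),
    markers = NULL,
    cox_covariates = c("sex", "waist", "smoking"),
    output_dir = NULL,
    inputs = list()
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  with(config, {
    if (missingness_threshold <= 0 || missingness_threshold > 1) {
      stop("missingness_threshold must lie in (0, 1]")
    }
    if (retain_min > folds) stop("retain_min must be <= folds")
    if (train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must lie in (0, 1)")
    }
    if (fdr_q <= 0 || fdr_q > 1) stop("fdr_q must lie in (0, 1]")
  })
  config$seed <- as.integer(config$seed)
  config
}

#' Run the analysis pipeline
#'
#' Executes preprocess (missingness exclusion + left-censored imputation,
#' per visit) and aggregation, then the toggled analysis stages
#' (dietary-arm effects; elastic-net stability selection per marker;
#' case-cohort Cox associations), writing every intermediate table plus a
#' JSON manifest of parameters, seeds and input/output checksums.
#' Identical config and inputs yield byte-identical outputs. Input files
#' are never modified.
#'
#' @param config A [run_config()] list (or YAML path) whose `inputs` name
#'   the fixture files (`week0`, `week16`, `meta`, and per stage
#'   `markers0`/`markers16`, `casecohort`) and whose `output_dir` exists
#'   or can be created.
#' @return The run manifest (invisibly also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$output_dir)) stop("config needs an output_dir")
  inp <- cfg$inputs
  for (need in c("week0", "week16", "meta")) {
    if (is.null(inp[[need]]) || !file.exists(inp[[need]])) {
      stop("missing input file for '", need, "'")
    }
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(cfg$output_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  w0 <- read_concentrations(inp$week0)
  w16 <- read_concentrations(inp$week16)
  meta <- utils::read.delim(inp$meta, stringsAsFactors = FALSE)
  stopifnot(identical(rownames(w0), rownames(w16)),
            identical(meta$sample_id, rownames(w0)))

  # missingness assessed jointly across visits, single exclusion pass
  joint <- rbind(w0, w16)
  filt <- filter_missing(joint, cfg$missingness_threshold)
  keep <- colnames(filt$matrix)
  emit(
    if (nrow(filt$report)) filt$report else
      data.frame(species = character(0), missing_fraction = numeric(0)),
    "excluded_species.tsv"
  )

  # imputation per visit stratum
  imp0 <- impute_qrilc(w0[, keep, drop = FALSE], seed = cfg$seed,
                       tune_sigma = cfg$tune_sigma)
  imp16 <- impute_qrilc(w16[, keep, drop = FALSE], seed = cfg$seed + 1L,
                        tune_sigma = cfg$tune_sigma)
  audit <- data.frame(
    species = keep,
    censor_threshold_w0 = unname(imp0$report$censor_threshold),
    censor_threshold_w16 = unname(imp16$report$censor_threshold),
    mu_w0 = unname(imp0$report$mu), sigma_w0 = unname(imp0$report$sigma),
    mu_w16 = unname(imp16$report$mu), sigma_w16 = unname(imp16$report$sigma)
  )
  emit(audit, "imputation_audit.tsv")

  wcfa0 <- within_class_fa(imp0$matrix)
  wcfa16 <- within_class_fa(imp16$matrix)
  tot0 <- class_totals(imp0$matrix)
  tot16 <- class_totals(imp16$matrix)
  write_wcfa_table(wcfa0, tot0, file.path(cfg$output_dir, "wcfa_week0.tsv"))
  write_wcfa_table(wcfa16, tot16, file.path(cfg$output_dir, "wcfa_week16.tsv"))
  outputs <- c(outputs, file.path(cfg$output_dir, c("wcfa_week0.tsv", "wcfa_week16.tsv")))

  results <- list()
  if (isTRUE(cfg$stages$diet_effects)) {
    de <- fit_diet_effects(wcfa0, wcfa16, tot0, tot16, meta,
                           m_bonf = cfg$m_bonf)
    emit(as.data.frame(de), "diet_effects.tsv")
    results$diet_effects <- de
  }
  if (isTRUE(cfg$stages$enr)) {
    mk0 <- utils::read.delim(inp$markers0, stringsAsFactors = FALSE)
    mk16 <- utils::read.delim(inp$markers16, stringsAsFactors = FALSE)
    stopifnot(identical(mk0$sample_id, meta$sample_id))
    dfa <- scale(wcfa16 - wcfa0)
    markers <- cfg$markers
    if (is.null(markers)) markers <- setdiff(names(mk0), "sample_id")
    enr_rows <- list()
    for (mk in markers) {
      dy <- mk16[[mk]] - mk0[[mk]]
      tuned <- enr_tune(dfa, dy, alphas = cfg$alphas, folds = cfg$folds,
                        train_fraction = cfg$train_fraction,
                        seed = cfg$seed)
      sm <- stability_select(dfa, dy, tuned$alpha, tuned$lambda,
                             seed = cfg$seed, folds = cfg$folds,
                             train_fraction = cfg$train_fraction,
                             retain_min = cfg$retain_min, marker = mk)
      tab <- if (nrow(sm$retained)) {
        cbind(marker = mk, sm$retained, pearson_r = sm$pearson_r,
              alpha = sm$alpha, lambda = sm$lambda)
      } else {
        data.frame(marker = mk, predictor = NA, coefficient = NA,
                   count = NA, pearson_r = sm$pearson_r,
                   alpha = sm$alpha, lambda = sm$lambda)
      }
      enr_rows[[mk]] <- tab
      results$enr[[mk]] <- sm
    }
    emit(do.call(rbind, enr_rows), "enr_stability.tsv")
  }
  if (isTRUE(cfg$stages$casecohort)) {
    cc <- utils::read.delim(inp$casecohort, stringsAsFactors = FALSE)
    validate_casecohort(cc)
    assoc <- cch_associations(
      cc, exposures = "exposure",
      covariates = cfg$cox_covariates,
      class_total_of = c(exposure = "class_total"),
      outcome = cfg$outcome %||% "T2D",
      m_bonf = cfg$m_bonf
    )
    emit(assoc, "casecohort_associations.tsv")
    results$casecohort <- assoc
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidfa")),
    seed = cfg$seed,
    thresholds = cfg[c("missingness_threshold", "retain_min", "folds",
                       "train_fraction", "fdr_q")],
    inputs = as.list(tools::md5sum(unlist(inp))),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
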