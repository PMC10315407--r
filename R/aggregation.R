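# Multiplicity-weighted aggregation of molecular species into within-class
# fatty-acid concentrations and unweighted class totals.

# Build the species x (class, fa) multiplicity weight matrix from parsed
# column names.
wcfa_weights <- function(species_names) {
  parsed <- parse_species_all(species_names)
  keys <- lapply(parsed, function(sp) {
    fas <- unique(sp$chains)
    data.frame(
      lipid_class = sp$lipid_class, fa = fas,
      mult = vapply(fas, function(f) sum(sp$chains == f), 0L),
      stringsAsFactors = FALSE
    )
  })
  all_keys <- unique(do.call(rbind, keys)[, c("lipid_class", "fa")])
  # order: class code then carbons then double bonds
  fa_tab <- parse_fa(all_keys$fa)
  ord <- order(all_keys$lipid_class, fa_tab$carbons, fa_tab$double_bonds)
  all_keys <- all_keys[ord, , drop = FALSE]
  labels <- paste0(all_keys$lipid_class, "[", all_keys$fa, "]")
  W <- matrix(0, nrow = length(species_names), ncol = nrow(all_keys),
              dimnames = list(species_names, labels))
  for (i in seq_along(parsed)) {
    k <- keys[[i]]
    idx <- match(paste0(k$lipid_class, "[", k$fa, "]"), labels)
    W[i, idx] <- k$mult
  }
  attr(W, "classes") <- vapply(parsed, `[[`, "", "lipid_class")
  attr(W, "key") <- all_keys
  W
}

#' Within-class fatty-acid concentrations
#'
#' For every (lipid class, fatty acid) pair with at least one contributing
#' molecular species, sums the species concentrations of that class
#' weighted by the number of chains of the fatty acid each molecule
#' carries. For 1-chain classes the within-class fatty-acid concentration
#' equals the species concentration. Pairs without contributing species
#' are not materialized.
#'
#' @param m Complete (imputed) numeric matrix, samples x species, with
#'   parseable species shorthand as column names.
#' @return Numeric matrix, samples x within-class fatty acids, columns
#'   named `CLASS[C:D]`.
#' @export
#' @examples
#' m <- matrix(c(1, 2), 1, 2,
#'   dimnames = list("s1", c("DAG(16:0/16:0)", "DAG(16:0/14:0)")))
#' within_class_fa(m)  # DAG[14:0] = 2, DAG[16:0] = 4
within_class_fa <- function(m) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (anyNA(m)) stop("'m' must be imputed (no missing cells)")
  W <- wcfa_weights(colnames(m))
  out <- m %*% W
  out
}

#' Total lipid-class concentrations
#'
#' The plain, unweighted per-sample sum of all molecular-species
#' concentrations belonging to each lipid class present in the panel.
#'
#' @inheritParams within_class_fa
#' @return Numeric matrix, samples x classes, columns named by class code.
#' @export
class_totals <- function(m) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (anyNA(m)) stop("'m' must be imputed (no missing cells)")
  cls <- vapply(parse_species_all(colnames(m)), `[[`, "", "lipid_class")
  present <- sort(unique(cls))
  G <- outer(cls, present, `==`) * 1
  out <- m %*% G
  colnames(out) <- present
  out
}

#' Write the within-class fatty-acid interchange table
#'
#' Writes a wide tab-delimited table with a `sample_id` column, the
#' `CLASS[C:D]` within-class fatty-acid block and a `CLASS[total]` block;
#' this is the format consumed by the downstream analysis stages.
#'
#' @param wcfa Matrix from [within_class_fa()].
#' @param totals Matrix from [class_totals()].
#' @param path Output file path.
#' @export
write_wcfa_table <- function(wcfa, totals, path) {
  stopifnot(identical(rownames(wcfa), rownames(totals)))
  colnames(totals) <- paste0(colnames(totals), "[total]")
  tab <- data.frame(
    sample_id = rownames(wcfa), wcfa, totals,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
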