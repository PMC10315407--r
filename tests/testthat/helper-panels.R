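# Random toy panels and a brute-force aggregation oracle used by the
# property-style tests.

fa_alphabet <- c("12:0", "14:0", "14:1", "15:0", "16:0", "17:0", "18:0",
                 "18:1", "18:2", "20:0", "22:1", "24:1")

# A random species panel (names only) spanning random classes.
random_species <- function(n_species, seed) {
  set.seed(seed)
  tab <- lipid_classes()
  out <- character(0)
  while (length(out) < n_species) {
    row <- tab[sample.int(nrow(tab), 1L), ]
    chains <- sample(fa_alphabet, row$chains_per_molecule, replace = TRUE)
    out <- unique(c(out, paste0(row$code, "(", paste(chains, collapse = "/"), ")")))
  }
  out[seq_len(n_species)]
}

# A random complete concentration matrix over a random panel.
random_matrix <- function(n_samples, n_species, seed) {
  species <- random_species(n_species, seed)
  set.seed(seed + 1L)
  m <- matrix(exp(stats::rnorm(n_samples * length(species), 1, 0.8)),
              n_samples, length(species),
              dimnames = list(sprintf("s%02d", seq_len(n_samples)), species))
  m
}

# Brute-force oracle: expand every molecule into its chain multiset and
# accumulate concentrations chain by chain.
brute_force_wcfa <- function(m) {
  acc <- list()
  for (j in seq_len(ncol(m))) {
    sp <- parse_species(colnames(m)[j])
    for (chain in sp$chains) {
      key <- paste0(sp$lipid_class, "[", chain, "]")
      acc[[key]] <- if (is.null(acc[[key]])) m[, j] else acc[[key]] + m[, j]
    }
  }
  out <- do.call(cbind, acc)
  out[, sort(colnames(out)), drop = FALSE]
}

brute_force_totals <- function(m) {
  cls <- sub("\\(.*$", "", colnames(m))
  sapply(sort(unique(cls)), function(cl) {
    rowSums(m[, cls == cl, drop = FALSE])
  })
}
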