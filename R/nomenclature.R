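# Lipid shorthand nomenclature: class taxonomy, species parsing,
# fatty-acid chain multiplicity.

.lipidfa_env <- new.env(parent = emptyenv())

# vendor / prose aliases mapped onto the supported class codes
.class_aliases <- c(
  SPE    = "LPE",
  TAG    = "TG",
  DG     = "DAG",
  MG     = "MAG",
  LYSOPC = "LPC",
  LYSOPE = "LPE"
)

#' Lipid class taxonomy
#'
#' Returns the 16-class taxonomy used throughout the package: the class
#' code, its category (neutral lipid, sphingolipid, phospholipid) and the
#' number of fatty-acyl chains per molecule (1, 2 or 3). The table ships as
#' a plain-text file under `inst/extdata/lipid_classes.tsv` so it can be
#' audited or extended.
#'
#' @return A data.frame with columns `code`, `category`,
#'   `chains_per_molecule` and `name`.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  if (is.null(.lipidfa_env$classes)) {
    path <- system.file("extdata", "lipid_classes.tsv", package = "lipidfa")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(tab$chains_per_molecule %in% 1:3))
    .lipidfa_env$classes <- tab
  }
  .lipidfa_env$classes
}

#' Number of acyl chains per molecule for a lipid class
#'
#' @param code Character vector of class codes (e.g. `"TG"`).
#' @return Integer vector of chain counts (1, 2 or 3).
#' @export
chains_per_molecule <- function(code) {
  tab <- lipid_classes()
  idx <- match(toupper(code), tab$code)
  if (anyNA(idx)) {
    stop("unsupported lipid class: ", paste(code[is.na(idx)], collapse = ", "))
  }
  tab$chains_per_molecule[idx]
}

#' Parse a fatty-acid shorthand token
#'
#' A fatty acid is written `"C:D"` with `C` the carbon count (>= 2) and `D`
#' the number of double bonds (>= 0). Double-bond position and geometry are
#' not part of the identity: two chains are equal iff both counts match.
#'
#' @param token Character vector of `"C:D"` tokens.
#' @return A data.frame with columns `carbons`, `double_bonds`, `shorthand`.
#' @export
#' @examples
#' parse_fa("16:0")
parse_fa <- function(token) {
  token <- trimws(token)
  m <- regexec("^([0-9]+):([0-9]+)$", token)
  parts <- regmatches(token, m)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed fatty-acid token: ", paste(token[bad], collapse = ", "))
  }
  carbons <- as.integer(vapply(parts, `[[`, "", 2L))
  dbl <- as.integer(vapply(parts, `[[`, "", 3L))
  if (any(carbons < 2L)) {
    stop("fatty acid must have >= 2 carbons: ", paste(token[carbons < 2L], collapse = ", "))
  }
  data.frame(
    carbons = carbons, double_bonds = dbl,
    shorthand = paste0(carbons, ":", dbl),
    stringsAsFactors = FALSE
  )
}

#' Parse a lipid molecular-species shorthand name
#'
#' Accepts the machine dialect `CLASS(C:D/...)` as well as the prose form
#' `CLASS (C:D)` and square-bracket variants `CLASS[C:D]`; the class code is
#' case-insensitive and a small alias table maps vendor variants (e.g.
#' `TAG` -> `TG`, `SPE` -> `LPE`). The number of chains must equal the
#' class's chains-per-molecule.
#'
#' @param name A single species name.
#' @return An object of class `lipid_species`: a list with elements
#'   `lipid_class` (code), `category`, `chains` (character vector of
#'   canonical `"C:D"` tokens, order as written) and `raw_name`.
#' @export
#' @examples
#' parse_species("DAG(16:0/18:1)")
#' parse_species("ce (18:0)")
parse_species <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regexec("^\\s*([A-Za-z]+)\\s*[(\\[]([^)\\]]*)[)\\]]\\s*$", name,
               perl = TRUE)
  parts <- regmatches(name, m)[[1L]]
  if (length(parts) != 3L) {
    stop("cannot parse species name: '", name, "'")
  }
  code <- toupper(parts[2L])
  if (code %in% names(.class_aliases)) code <- .class_aliases[[code]]
  tab <- lipid_classes()
  row <- match(code, tab$code)
  if (is.na(row)) {
    stop("unsupported lipid class: ", parts[2L])
  }
  tokens <- strsplit(parts[3L], "/", fixed = TRUE)[[1L]]
  fa <- parse_fa(tokens)
  k <- tab$chains_per_molecule[row]
  if (nrow(fa) != k) {
    stop(
      "arity mismatch for ", code, ": expected ", k, " chain(s), got ",
      nrow(fa), " in '", name, "'"
    )
  }
  structure(
    list(
      lipid_class = code,
      category = tab$category[row],
      chains = fa$shorthand,
      raw_name = name
    ),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(
    format_species(x), " [", x$category, ", ",
    length(x$chains), " chain(s)]\n",
    sep = ""
  )
  invisible(x)
}

#' Canonical shorthand for a parsed species
#'
#' @param species A `lipid_species` object.
#' @return The canonical `CLASS(C:D/...)` string; `parse_species()` on the
#'   result recovers the same class and chains.
#' @export
format_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  paste0(species$lipid_class, "(", paste(species$chains, collapse = "/"), ")")
}

#' Chain multiplicity of a fatty acid within a molecular species
#'
#' The number of acyl chains of `species` identical to `fa`, used to weight
#' the species' contribution to the within-class fatty-acid concentration.
#' A diacylglycerol carrying two palmitic acids, `DAG(16:0/16:0)`,
#' contributes twice to DAG\[16:0\]; `DAG(16:0/14:0)` contributes once each
#' to DAG\[16:0\] and DAG\[14:0\].
#'
#' @param species A `lipid_species` object.
#' @param fa A fatty acid as a `"C:D"` string (or one-row result of
#'   [parse_fa()]).
#' @return Integer count in `0:chains_per_molecule`.
#' @export
#' @examples
#' fa_multiplicity(parse_species("DAG(16:0/16:0)"), "16:0")  # 2
fa_multiplicity <- function(species, fa) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.data.frame(fa)) fa <- fa$shorthand
  fa <- parse_fa(fa)$shorthand
  stopifnot(length(fa) == 1L)
  sum(species$chains == fa)
}

# Parse a vector of species names, memoized; errors identify the name.
parse_species_all <- function(names) {
  if (is.null(.lipidfa_env$species_cache)) {
    .lipidfa_env$species_cache <- new.env(parent = emptyenv())
  }
  cache <- .lipidfa_env$species_cache
  lapply(names, function(nm) {
    sp <- cache[[nm]]
    if (is.null(sp)) {
      sp <- parse_species(nm)
      cache[[nm]] <- sp
    }
    sp
  })
}
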