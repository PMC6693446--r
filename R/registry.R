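# Registry of the six iturinic lipopeptides and parent-mass arithmetic.

.registry_env <- new.env(parent = emptyenv())

#' Registry of the six iturinic lipopeptides
#'
#' One row per compound: the cyclic heptapeptide (positions aa1-aa7, with the
#' conserved Asn-Tyr-Asn head at aa1-aa3), the proline position (4 for
#' bacillomycin D, 5 for the iturin/mycosubtilin-like compounds, `NA` for
#' bacillomycin L, the only member without a proline) and the producer
#' species reported for each compound.
#'
#' @param path Optional path to an alternative tab-separated registry;
#'   defaults to the table shipped with the package.
#' @return `data.frame` with columns `name`, `aa1`..`aa7`,
#'   `proline_position` (integer, `NA` when absent), `producer_species`.
#' @examples
#' compound_registry()$name
#' @export
compound_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.registry_env$registry)) {
    return(.registry_env$registry)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "compound_registry.tsv",
      package = "iturityper", mustWork = TRUE
    )
  }
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  reg$proline_position <- suppressWarnings(as.integer(reg$proline_position))
  .validate_registry(reg)
  if (default) .registry_env$registry <- reg
  reg
}

.validate_registry <- function(reg) {
  aa_cols <- paste0("aa", 1:7)
  stopifnot(all(c("name", aa_cols, "proline_position") %in% names(reg)))
  if (nrow(reg) != 6L) {
    stop("registry must have exactly 6 compounds, got ", nrow(reg))
  }
  head_ok <- reg$aa1 == "Asn" & reg$aa2 == "Tyr" & reg$aa3 == "Asn"
  if (!all(head_ok)) {
    stop("every iturinic heptapeptide must begin Asn-Tyr-Asn")
  }
  no_pro <- is.na(reg$proline_position)
  if (sum(no_pro) != 1L) {
    stop("exactly one registry compound (bacillomycin L) lacks a proline")
  }
  for (i in which(!no_pro)) {
    pos <- reg$proline_position[i]
    if (!pos %in% c(4L, 5L) || reg[[paste0("aa", pos)]][i] != "Pro") {
      stop("proline_position inconsistent for ", reg$name[i])
    }
  }
  invisible(reg)
}

#' Look up one compound definition
#'
#' @param name Compound name as in [compound_registry()] (case-insensitive).
#' @param registry Registry data frame; defaults to the shipped registry.
#' @return List of class `compound_definition` with `name`, `heptapeptide`
#'   (character vector of 7 three-letter codes), `proline_position`
#'   (integer or `NA`) and `producer_species` (character vector).
#' @examples
#' compound_definition("iturin A")$heptapeptide
#' @export
compound_definition <- function(name, registry = compound_registry()) {
  i <- match(tolower(name), tolower(registry$name))
  if (is.na(i)) {
    stop("unknown compound '", name, "'; registry has: ",
      paste(registry$name, collapse = ", "))
  }
  structure(
    list(
      name = registry$name[i],
      heptapeptide = unname(unlist(registry[i, paste0("aa", 1:7)])),
      proline_position = registry$proline_position[i],
      producer_species = strsplit(registry$producer_species[i], ";")[[1]]
    ),
    class = "compound_definition"
  )
}

#' @export
print.compound_definition <- function(x, ...) {
  pro <- if (is.na(x$proline_position)) "none" else x$proline_position
  cat(x$name, ": cyclo(", paste(x$heptapeptide, collapse = "-"),
    ")-beta-AA, proline position ", pro, "\n", sep = "")
  invisible(x)
}

.as_compound <- function(compound) {
  if (inherits(compound, "compound_definition")) compound
  else compound_definition(compound)
}

.as_chain <- function(chain) {
  if (inherits(chain, "beta_acyl")) chain else beta_acyl(chain)
}

#' Neutral monoisotopic mass of a cyclic lipopeptide
#'
#' Sum of the seven residue masses plus the beta-amino fatty-acyl residue
#' mass. No water is added: the macrocycle is closed by an amide bond, so
#' the molecule is a pure residue ring.
#'
#' @param compound A `compound_definition` or compound name.
#' @param chain A `beta_acyl` or integer chain length (13-18).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' cyclic_parent_mass("iturin A", 14) # 1042.5447
#' protonated_mz(cyclic_parent_mass("iturin A", 14)) # 1043.5520
#' @export
cyclic_parent_mass <- function(compound, chain) {
  compound <- .as_compound(compound)
  chain <- .as_chain(chain)
  sum(.residue_mass_of(compound$heptapeptide)) + chain$mass
}
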