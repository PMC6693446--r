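# Monoisotopic mass arithmetic for the iturinic lipopeptide family.

# IUPAC/CODATA monoisotopic atomic masses (Da), >= 5 decimals.
.ATOMIC_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.ELECTRON_MASS <- 0.00054857990

#' Mass constants used throughout the package
#'
#' Proton, water, carbon monoxide, ketene (the 42.01 Da neutral loss that
#' reveals the beta-amino fatty acid chain length) and methylene (the
#' 14.02 Da unit behind the chain-length/Ser-vs-Thr ambiguity), all
#' monoisotopic, in Da.
#'
#' @return Named numeric vector with elements `proton`, `water`,
#'   `carbon_monoxide`, `ketene`, `methylene` and `electron`.
#' @examples
#' mass_constants()[["ketene"]]
#' @export
mass_constants <- function() {
  c(
    proton = .ATOMIC_MASS[["H"]] - .ELECTRON_MASS,
    water = 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]],
    carbon_monoxide = .ATOMIC_MASS[["C"]] + .ATOMIC_MASS[["O"]],
    ketene = 2 * .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["H"]] +
      .ATOMIC_MASS[["O"]],
    methylene = .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["H"]],
    electron = .ELECTRON_MASS
  )
}

#' Parse an elemental formula string
#'
#' Accepts compact formulas such as `"C4H6N2O2"`. Element symbols must be
#' among C, H, N, O, S; counts default to 1.
#'
#' @param formula Character scalar, e.g. `"C2H2O"`. The empty string is the
#'   empty formula.
#' @return Named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  sym <- sub("[0-9]+$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  tapply(cnt, factor(sym, levels = unique(sym)), sum)[unique(sym)]
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Character formula (e.g. `"C14H27NO"`) or a named numeric
#'   vector of element counts as returned by [parse_formula()].
#' @return Monoisotopic mass in Da; `0` for the empty formula.
#' @examples
#' residue_mass("C2H2O") # the 42.01 Da ketene loss
#' @export
residue_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) {
    return(0)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named")
  }
  if (any(counts < 0)) {
    stop("element counts must be non-negative")
  }
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

#' Amino-acid residue table
#'
#' The residues occurring in the iturinic heptapeptides (Asn, Tyr, Gln, Pro,
#' Ser, Thr, Glu, plus Gly as a non-family sentinel), with elemental formulas
#' and monoisotopic residue masses computed from atomic masses.
#'
#' @param path Optional path to an alternative tab-separated residue table
#'   with columns `three_letter`, `one_letter`, `formula`; defaults to the
#'   table shipped with the package.
#' @return `data.frame` with columns `three_letter`, `one_letter`, `formula`,
#'   `mass`.
#' @examples
#' residue_table()[residue_table()$three_letter == "Tyr", ]
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_masses.tsv",
      package = "iturityper", mustWork = TRUE
    )
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$mass <- vapply(tab$formula, residue_mass, numeric(1))
  tab
}

# Cached residue lookup (three-letter code -> mass).
.residue_env <- new.env(parent = emptyenv())

.residue_masses <- function() {
  if (is.null(.residue_env$masses)) {
    tab <- residue_table()
    .residue_env$masses <- stats::setNames(tab$mass, tab$three_letter)
    .residue_env$formulas <- stats::setNames(tab$formula, tab$three_letter)
  }
  .residue_env$masses
}

.residue_mass_of <- function(code3) {
  masses <- .residue_masses()
  bad <- setdiff(code3, names(masses))
  if (length(bad)) {
    stop("residue(s) not in table: ", paste(unique(bad), collapse = ", "))
  }
  unname(masses[code3])
}

#' Beta-amino fatty-acyl residue
#'
#' The lipid residue closing the iturinic macrocycle, CnH(2n-1)NO as
#' incorporated. Chain lengths C13-C18 cover the family's alkyl variants.
#'
#' @param n_carbons Integer chain length, 13 to 18.
#' @return List of class `beta_acyl` with `n_carbons`, `formula`, `mass`.
#' @examples
#' beta_acyl(14)$mass # 225.2093
#' @export
beta_acyl <- function(n_carbons) {
  n_carbons <- as.integer(n_carbons)
  stopifnot(length(n_carbons) == 1L, !is.na(n_carbons))
  if (n_carbons < 13L || n_carbons > 18L) {
    stop("beta-amino acid chain length must be in 13..18, got ", n_carbons)
  }
  formula <- sprintf("C%dH%dNO", n_carbons, 2L * n_carbons - 1L)
  structure(
    list(n_carbons = n_carbons, formula = formula,
         mass = residue_mass(formula)),
    class = "beta_acyl"
  )
}

#' m/z of a protonated species
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @return `(neutral_mass + charge * proton) / charge`.
#' @examples
#' protonated_mz(1042.5447, 1)
#' @export
protonated_mz <- function(neutral_mass, charge = 1L) {
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge < 1L) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * mass_constants()[["proton"]]) / charge
}

#' Immonium-type ion m/z of a residue
#'
#' The low-mass ion produced by double backbone fragmentation of one residue:
#' residue mass minus CO, as a singly protonated cation (electron mass
#' accounted through the proton mass). For Tyr this is the 136.076 ion seen
#' in every iturinic lipopeptide spectrum.
#'
#' @param residue Three-letter residue code present in [residue_table()].
#' @return m/z of the singly charged immonium-type ion.
#' @examples
#' immonium_mz("Tyr") # 136.076
#' @export
immonium_mz <- function(residue) {
  k <- mass_constants()
  .residue_mass_of(residue) - k[["carbon_monoxide"]] + k[["proton"]]
}
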