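# Theoretical fragment ions of cyclic lipopeptides.
#
# Iturinic lipopeptides fragment through two dominant pathways that differ in
# where the macrocycle opens before backbone fragmentation: between the
# beta-amino fatty acid tail and the conserved Asn at AA#1 ("tail" opening),
# or at the amide bond N-terminal to the proline ("proline" opening, absent
# for bacillomycin L). Each opening linearizes the ring; b/y series of the
# linear species are then enumerated.

.CYCLE_SIZE <- 8L # 7 amino-acid residues + 1 beta-acyl unit

.cycle_units <- function(compound, chain) {
  compound <- .as_compound(compound)
  chain <- .as_chain(chain)
  data.frame(
    position = 1:8,
    label = c(compound$heptapeptide, sprintf("C%d", chain$n_carbons)),
    mass = c(.residue_mass_of(compound$heptapeptide), chain$mass),
    stringsAsFactors = FALSE
  )
}

#' Open the macrocycle at one amide bond
#'
#' The ring has 8 amide bonds: bond `s` follows unit `s` in the cyclic order
#' AA#1..AA#7, beta-acyl. Opening bond `s` yields a linear species starting
#' at unit `s + 1` (so site 8, the bond between the lipid tail and AA#1,
#' gives the canonical AA#1..AA#7-tail linearization; site
#' `proline_position - 1` starts the linear peptide at the proline).
#'
#' @param compound A `compound_definition` or compound name.
#' @param chain A `beta_acyl` or integer chain length.
#' @param site Bond index in 1..8.
#' @return List of class `ring_opening` with `site` and `units`, a
#'   data frame (8 rows, linear order) of `position` (cyclic position, 8 =
#'   beta-acyl), `label` and `mass`.
#' @examples
#' open_ring("iturin A", 14, 8)$units$label
#' @export
open_ring <- function(compound, chain, site) {
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L || site > .CYCLE_SIZE) {
    stop("ring-opening site must be in 1..8, got ", site)
  }
  units <- .cycle_units(compound, chain)
  ord <- ((site + seq_len(.CYCLE_SIZE) - 1L) %% .CYCLE_SIZE) + 1L
  structure(
    list(site = site, units = units[ord, , drop = FALSE]),
    class = "ring_opening"
  )
}

.empty_ions <- function() {
  data.frame(
    mz = numeric(0), series = character(0), k = integer(0),
    opening = character(0), composition = character(0),
    charge = integer(0), stringsAsFactors = FALSE
  )
}

.ion_row <- function(mz, series, k, opening, labels, positions) {
  data.frame(
    mz = mz, series = series, k = k, opening = opening,
    composition = paste(labels, collapse = "-"), charge = 1L,
    positions = I(list(as.integer(positions))),
    stringsAsFactors = FALSE
  )
}

#' b and y fragment series of a ring-opened lipopeptide
#'
#' b_k is the sum of the first k unit masses plus a proton; y_k the sum of
#' the last k unit masses plus water plus a proton; k runs 1..7 (the
#' full-length k = 8 ion is the opened precursor and is excluded). Only
#' singly charged fragments are generated.
#'
#' @param opening A `ring_opening`.
#' @param opening_label Label stored in the `opening` column of the result
#'   (e.g. `"tail"` or `"proline"`).
#' @return Data frame of fragment ions: `mz`, `series`, `k`, `opening`,
#'   `composition`, `charge`, `positions` (list of covered cyclic
#'   positions, 8 = beta-acyl).
#' @examples
#' ions <- b_y_series(open_ring("iturin A", 14, 8))
#' round(ions$mz[ions$series == "b" & ions$k == 2], 2) # 278.11
#' @export
b_y_series <- function(opening, opening_label = c("tail", "proline")[
                         1L + (opening$site != .CYCLE_SIZE)]) {
  stopifnot(inherits(opening, "ring_opening"))
  k <- mass_constants()
  u <- opening$units
  n <- nrow(u)
  out <- lapply(seq_len(n - 1L), function(i) {
    rbind(
      .ion_row(
        sum(u$mass[seq_len(i)]) + k[["proton"]],
        "b", i, opening_label, u$label[seq_len(i)], u$position[seq_len(i)]
      ),
      .ion_row(
        sum(u$mass[(n - i + 1L):n]) + k[["water"]] + k[["proton"]],
        "y", i, opening_label, u$label[(n - i + 1L):n],
        u$position[(n - i + 1L):n]
      )
    )
  })
  do.call(rbind, out)
}

#' Chain-length diagnostic ion of the beta-amino fatty acid
#'
#' The protonated beta-acyl residue after loss of ketene (42.01 Da): the ion
#' that reveals the chain length (C14 gives 184.21, C15 gives 198.22, one
#' methylene apart), and thereby resolves whether a 14.02 Da parent-mass
#' step is a chain-length change or a Ser-to-Thr substitution.
#'
#' @param chain A `beta_acyl` or integer chain length.
#' @return One-row fragment-ion data frame (series `"beta_diagnostic"`).
#' @examples
#' round(beta_diagnostic_ion(14)$mz, 2)
#' @export
beta_diagnostic_ion <- function(chain) {
  chain <- .as_chain(chain)
  k <- mass_constants()
  .ion_row(
    chain$mass + k[["proton"]] - k[["ketene"]],
    "beta_diagnostic", NA_integer_, NA_character_,
    sprintf("C%d-ketene", chain$n_carbons), 8L
  )
}

#' Diagnostic fragment table for a (compound, chain) candidate
#'
#' Union of (a) the invariant trio -- the tail-opening b2 (Asn-Tyr, 278.11)
#' and b3 (Asn-Tyr-Asn, 392.16) ions and the Tyr immonium-type ion
#' (136.076), which contain no lipid tail and are identical across all six
#' compounds and chain lengths; (b) the chain-length beta-diagnostic ion;
#' (c) the full b/y series from the tail opening; and (d) the b/y series
#' from the proline opening when the compound has a proline (bacillomycin L
#' does not, hence its more uniform fragmentation pattern). Ions are
#' deduplicated at 1e-4 Da and sorted by m/z; the protonated precursor is
#' appended as a reference row.
#'
#' @param compound A `compound_definition` or compound name.
#' @param chain A `beta_acyl` or integer chain length.
#' @param neutral_losses If `TRUE`, add -NH3 (17.0265) and -H2O (18.0106)
#'   satellites of every b/y ion. Off by default: the diagnostic ions used
#'   for assignment are the plain series.
#' @return Data frame of class `fragment_table` with columns `mz`, `series`,
#'   `k`, `opening`, `composition`, `charge`, `positions`, `is_invariant`
#'   (the trio), `is_variable` (b/y ions covering any of the variable
#'   positions AA#4-AA#7); attributes `compound`, `chain_n`, `precursor_mz`.
#' @examples
#' tab <- diagnostic_table("iturin A", 14)
#' round(sort(tab$mz[tab$is_invariant]), 2)
#' @export
diagnostic_table <- function(compound, chain, neutral_losses = FALSE) {
  # Tables over the registry x chain domain are pure; cache them (only for
  # name lookups, which resolve through the packaged registry).
  cache_key <- if (is.character(compound) && !inherits(chain, "beta_acyl")) {
    paste(compound, chain, neutral_losses, sep = "|")
  } else {
    NULL
  }
  if (!is.null(cache_key) && !is.null(.table_cache[[cache_key]])) {
    return(.table_cache[[cache_key]])
  }
  compound <- .as_compound(compound)
  chain <- .as_chain(chain)
  k <- mass_constants()

  tail_open <- open_ring(compound, chain, .CYCLE_SIZE)
  ions <- b_y_series(tail_open, "tail")
  if (!is.na(compound$proline_position)) {
    pro_open <- open_ring(compound, chain, compound$proline_position - 1L)
    ions <- rbind(ions, b_y_series(pro_open, "proline"))
  }
  ions <- rbind(ions, beta_diagnostic_ion(chain))
  ions <- rbind(ions, .ion_row(
    immonium_mz("Tyr"), "immonium", NA_integer_, NA_character_, "Tyr", 2L
  ))
  if (neutral_losses) {
    by <- ions[ions$series %in% c("b", "y"), , drop = FALSE]
    nh3 <- 3 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["N"]]
    for (loss in c(nh3, k[["water"]])) {
      sat <- by
      sat$mz <- sat$mz - loss
      sat$series <- paste0(sat$series, "_loss")
      ions <- rbind(ions, sat)
    }
  }

  prec <- protonated_mz(cyclic_parent_mass(compound, chain), 1L)
  ions$is_invariant <- (ions$series == "immonium" & ions$composition == "Tyr") |
    (ions$series == "b" & !is.na(ions$opening) & ions$opening == "tail" &
       ions$k %in% c(2L, 3L))
  ions$is_variable <- ions$series %in% c("b", "y") &
    vapply(ions$positions, function(p) any(p %in% 4:7), logical(1)) &
    !ions$is_invariant

  # Deduplicate at 1e-4 Da, keeping diagnostic roles on the merged ion.
  ions <- ions[order(ions$mz, ions$series, ions$k), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(ions$mz) > 1e-4))
  keep <- !duplicated(grp)
  merged <- ions[keep, , drop = FALSE]
  merged$is_invariant <- as.logical(tapply(ions$is_invariant, grp, any))
  merged$is_variable <- as.logical(tapply(ions$is_variable, grp, any))

  merged <- rbind(merged, cbind(
    .ion_row(prec, "precursor", NA_integer_, NA_character_,
      paste0("[M+H]+ ", compound$name), 1:8),
    is_invariant = FALSE, is_variable = FALSE
  ))
  rownames(merged) <- NULL
  out <- structure(merged,
    class = c("fragment_table", "data.frame"),
    compound = compound$name, chain_n = chain$n_carbons, precursor_mz = prec
  )
  if (!is.null(cache_key)) .table_cache[[cache_key]] <- out
  out
}

.table_cache <- new.env(parent = emptyenv())

#' Write / read a fragment table as TSV
#'
#' The `positions` list column is serialized as a comma-joined string; the
#' reader restores it, the class and the table attributes.
#'
#' @param table A `fragment_table`.
#' @param path File path.
#' @return `write_fragment_table` returns `path` invisibly;
#'   `read_fragment_table` returns the `fragment_table`.
#' @export
write_fragment_table <- function(table, path) {
  stopifnot(inherits(table, "fragment_table"))
  out <- as.data.frame(table)
  out$positions <- vapply(out$positions, paste, character(1), collapse = ",")
  out$compound <- attr(table, "compound")
  out$chain_n <- attr(table, "chain_n")
  out$precursor_ref <- attr(table, "precursor_mz")
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- raw[, c("mz", "series", "k", "opening", "composition", "charge",
                 "positions", "is_invariant", "is_variable")]
  tab$positions <- I(lapply(strsplit(as.character(tab$positions), ","),
                            as.integer))
  structure(tab,
    class = c("fragment_table", "data.frame"),
    compound = raw$compound[1], chain_n = raw$chain_n[1],
    precursor_mz = raw$precursor_ref[1]
  )
}
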