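# Assignment of compound and acyl-chain length to observed MS/MS spectra.
#
# This mechanizes the manual interpretation of iturinic lipopeptide spectra:
# candidates are all registry compounds x chain lengths whose protonated
# parent matches the precursor, and a call requires the invariant ion trio
# (278.11, 392.16, 136.076), the chain-length beta-diagnostic ion, and
# enough ions from the variable region AA#4-AA#7 to pin the compound.

#' Matching configuration
#'
#' @param fragment_tol_ppm Fragment tolerance in ppm (default 10, Orbitrap
#'   scale).
#' @param fragment_tol_floor_da Absolute floor on the fragment tolerance in
#'   Da (default 0.01), so low-mass ions are not matched at sub-millidalton
#'   windows.
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @param min_variable_ions Minimum matched b/y ions covering the variable
#'   region AA#4-AA#7 required for a call (default 2).
#' @param ambiguity_margin Score margin under which runner-up candidates are
#'   reported as ambiguous (default 0.05).
#' @param chain_range Candidate beta-amino acid chain lengths (default
#'   13:18).
#' @return List of class `match_config`.
#' @export
match_config <- function(fragment_tol_ppm = 10,
                         fragment_tol_floor_da = 0.01,
                         precursor_tol_ppm = 10,
                         min_variable_ions = 2L,
                         ambiguity_margin = 0.05,
                         chain_range = 13:18) {
  stopifnot(
    fragment_tol_ppm > 0, fragment_tol_floor_da >= 0,
    precursor_tol_ppm > 0, min_variable_ions >= 0, ambiguity_margin >= 0
  )
  structure(
    list(
      fragment_tol_ppm = fragment_tol_ppm,
      fragment_tol_floor_da = fragment_tol_floor_da,
      precursor_tol_ppm = precursor_tol_ppm,
      min_variable_ions = as.integer(min_variable_ions),
      ambiguity_margin = ambiguity_margin,
      chain_range = as.integer(chain_range)
    ),
    class = "match_config"
  )
}

.fragment_tol_da <- function(mz, cfg) {
  pmax(mz * cfg$fragment_tol_ppm * 1e-6, cfg$fragment_tol_floor_da)
}

#' Candidate (compound, chain) pairs for a precursor mass
#'
#' All registry compounds crossed with the configured chain lengths whose
#' protonated parent m/z matches the observed precursor within tolerance.
#' Isobars are expected and legitimate: iturin A and mycosubtilin are exact
#' sequence isomers, and a chain-length step (+CH2) is isobaric with a
#' Ser-to-Thr substitution (the 14.02 Da ambiguity), so e.g. iturin A C15
#' and bacillomycin F C14 share a precursor.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param charge Precursor charge (default 1).
#' @param cfg A [match_config()].
#' @param registry Compound registry.
#' @return Data frame with columns `compound`, `chain_n`, `theoretical_mz`,
#'   `delta_ppm`; zero rows when nothing matches (a valid outcome).
#' @examples
#' candidate_set(1043.55, 1)[, c("compound", "chain_n")]
#' @export
candidate_set <- function(precursor_mz, charge = 1L, cfg = match_config(),
                          registry = compound_registry()) {
  stopifnot(precursor_mz > 0)
  grid <- expand.grid(
    compound = registry$name, chain_n = cfg$chain_range,
    stringsAsFactors = FALSE
  )
  grid$theoretical_mz <- mapply(
    function(cp, n) protonated_mz(cyclic_parent_mass(cp, n), charge),
    grid$compound, grid$chain_n
  )
  grid$delta_ppm <- (precursor_mz - grid$theoretical_mz) /
    grid$theoretical_mz * 1e6
  hit <- abs(grid$delta_ppm) <= cfg$precursor_tol_ppm
  out <- grid[hit, , drop = FALSE]
  out <- out[order(abs(out$delta_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a spectrum against one theoretical fragment table
#'
#' Greedy nearest-peak matching: theoretical ions are visited in m/z order
#' and each takes the nearest still-unused observed peak within tolerance.
#' The score is the fraction of the table's fragment ions (precursor row
#' excluded) that found a peak; intensity is carried through for reporting
#' but never scored, since assignment rests on presence or absence of
#' diagnostic ions.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param table A `fragment_table`.
#' @param cfg A [match_config()].
#' @return List of class `table_match`: `compound`, `chain_n`, `score`,
#'   `n_matched`, `n_expected`, flags `invariant_ok` / `beta_ok` /
#'   `n_variable_matched`, and `matched_ions` (data frame pairing each
#'   matched theoretical ion with its observed peak).
#' @export
match_peaks <- function(spectrum, table, cfg = match_config()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"),
            inherits(table, "fragment_table"))
  ions <- as.data.frame(table)
  ions <- ions[ions$series != "precursor", , drop = FALSE]
  obs <- spectrum$peaks
  used <- rep(FALSE, nrow(obs))
  hit_idx <- rep(NA_integer_, nrow(ions))
  for (i in order(ions$mz)) {
    tol <- .fragment_tol_da(ions$mz[i], cfg)
    d <- abs(obs$mz - ions$mz[i])
    d[used] <- Inf
    if (nrow(obs) && min(d) <= tol) {
      j <- which.min(d)
      hit_idx[i] <- j
      used[j] <- TRUE
    }
  }
  matched <- !is.na(hit_idx)
  matched_ions <- cbind(
    ions[matched, c("mz", "series", "k", "opening", "composition",
                    "is_invariant", "is_variable"), drop = FALSE],
    observed_mz = obs$mz[hit_idx[matched]],
    observed_intensity = obs$intensity[hit_idx[matched]]
  )
  rownames(matched_ions) <- NULL
  structure(
    list(
      compound = attr(table, "compound"),
      chain_n = attr(table, "chain_n"),
      score = if (nrow(ions)) sum(matched) / nrow(ions) else 0,
      n_matched = sum(matched),
      n_expected = nrow(ions),
      invariant_ok = all(matched[ions$is_invariant]) &&
        sum(ions$is_invariant) == 3L,
      beta_ok = any(matched & ions$series == "beta_diagnostic"),
      n_variable_matched = sum(matched & ions$is_variable),
      matched_ions = matched_ions
    ),
    class = "table_match"
  )
}

#' Assign compound and chain length to an MS/MS spectrum
#'
#' Scores every candidate from [candidate_set()] with [match_peaks()]. A
#' call is made only when the best candidate has (a) all three invariant
#' ions, (b) the beta-diagnostic ion, and (c) at least `min_variable_ions`
#' matched b/y ions from the variable region AA#4-AA#7; otherwise the
#' spectrum is `"unassigned"`. Runner-up candidates whose score is within
#' `ambiguity_margin` of the best are reported in `ambiguous_with` rather
#' than silently dropped; at an exact score tie the candidate matching more
#' variable-region ions (then the alphabetically first) is reported on top,
#' with the tie visible in `ambiguous_with`.
#'
#' @param spectrum An `ms2_spectrum` with a precursor.
#' @param cfg A [match_config()].
#' @param registry Compound registry.
#' @return List of class `chemotype_assignment`: `spectrum_id`, `compound`
#'   (name or `"unassigned"`), `chain_n` (integer or `NA`), `score`,
#'   `matched_ions`, `ambiguous_with` (data frame of runner-ups), `reason`.
#' @examples
#' sp <- gen_spectrum("iturin A", 14, generator_config(seed = 1))
#' assign_chemotype(sp)$compound
#' @export
assign_chemotype <- function(spectrum, cfg = match_config(),
                             registry = compound_registry()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  if (is.na(spectrum$precursor_mz)) {
    stop("spectrum '", spectrum$id, "' has no precursor m/z")
  }
  unassigned <- function(reason) {
    structure(
      list(
        spectrum_id = spectrum$id, compound = "unassigned",
        chain_n = NA_integer_, score = 0,
        matched_ions = NULL,
        ambiguous_with = .empty_ambiguity(), reason = reason
      ),
      class = "chemotype_assignment"
    )
  }
  cands <- candidate_set(spectrum$precursor_mz, spectrum$precursor_charge,
    cfg, registry)
  if (!nrow(cands)) {
    return(unassigned("no registry parent mass within precursor tolerance"))
  }
  matches <- lapply(seq_len(nrow(cands)), function(i) {
    match_peaks(
      spectrum,
      diagnostic_table(cands$compound[i], cands$chain_n[i]),
      cfg
    )
  })
  scores <- vapply(matches, `[[`, numeric(1), "score")
  nvar <- vapply(matches, `[[`, numeric(1), "n_variable_matched")
  comp <- vapply(matches, `[[`, character(1), "compound")
  ord <- order(-scores, -nvar, comp)
  best <- matches[[ord[1]]]

  if (!best$invariant_ok) {
    return(unassigned("invariant ion trio (278.11/392.16/136.076) not matched"))
  }
  if (!best$beta_ok) {
    return(unassigned("beta-amino acid chain-length diagnostic ion not matched"))
  }
  if (best$n_variable_matched < cfg$min_variable_ions) {
    return(unassigned(sprintf(
      "only %d variable-region ions matched (need %d)",
      best$n_variable_matched, cfg$min_variable_ions)))
  }

  runners <- ord[-1]
  close_ones <- runners[scores[ord[1]] - scores[runners] < cfg$ambiguity_margin]
  ambiguous_with <- if (length(close_ones)) {
    data.frame(
      compound = comp[close_ones],
      chain_n = vapply(matches[close_ones], `[[`, integer(1), "chain_n"),
      score = scores[close_ones]
    )
  } else {
    .empty_ambiguity()
  }
  structure(
    list(
      spectrum_id = spectrum$id,
      compound = best$compound,
      chain_n = best$chain_n,
      score = best$score,
      matched_ions = best$matched_ions,
      ambiguous_with = ambiguous_with,
      reason = "called"
    ),
    class = "chemotype_assignment"
  )
}

.empty_ambiguity <- function() {
  data.frame(compound = character(0), chain_n = integer(0),
             score = numeric(0))
}

#' @export
print.chemotype_assignment <- function(x, ...) {
  if (x$compound == "unassigned") {
    cat("unassigned (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("%s, C%d chain (score %.3f, %d ions matched)\n",
      x$compound, x$chain_n, x$score, nrow(x$matched_ions)))
    if (nrow(x$ambiguous_with)) {
      cat("  ambiguous with:",
        paste(sprintf("%s C%d (%.3f)", x$ambiguous_with$compound,
          x$ambiguous_with$chain_n, x$ambiguous_with$score),
          collapse = ", "), "\n")
    }
  }
  invisible(x)
}
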