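# File-in / report-out pipelines tying the stages together. These are the
# programmatic equivalents of shell subcommands; inst/scripts/itupipe.R
# wraps them for command-line use.

.read_fasta_or_stop <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("input file not found: ", path)
  reader <- if (alphabet == "dna") Biostrings::readDNAStringSet
            else Biostrings::readAAStringSet
  seqs <- tryCatch(reader(path), error = function(e) {
    stop("malformed FASTA '", path, "': ", conditionMessage(e))
  })
  stats::setNames(as.character(seqs), names(seqs))
}

.write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Type iturinic clusters from a FASTA file
#'
#' For every record: call the seven modules, map the heptapeptide to a
#' chemotype, then group the records within species labels. Optionally
#' check each record's proteome for the sfp gene.
#'
#' @param fasta_in Path to a nucleotide FASTA of candidate cluster
#'   sequences. Record descriptions may carry a species label as
#'   `species=...`; records without one are labelled `"unknown species"`.
#' @param report_out Optional path for the TSV report.
#' @param refs Module reference panel (see [module_refs()]).
#' @param identity_threshold,coverage_threshold Grouping thresholds, see
#'   [group_clusters()].
#' @param proteome_fasta Optional protein FASTA; if given together with
#'   `reference_sfp`, an `sfp_present` column is added (one flag for the
#'   whole proteome).
#' @param reference_sfp Optional reference sfp protein sequence.
#' @return Data frame (invisibly written to `report_out` when given): one
#'   row per record with `id`, `species`, `chemotype`, `group`, per-module
#'   calls `aa1`..`aa7` and identities `id1`..`id7`, and `sfp` when
#'   checked.
#' @export
type_clusters <- function(fasta_in, report_out = NULL,
                          refs = module_refs(),
                          identity_threshold = 0.94,
                          coverage_threshold = 0.95,
                          proteome_fasta = NULL,
                          reference_sfp = NULL) {
  seqs <- .read_fasta_or_stop(fasta_in, "dna")
  if (length(seqs) == 0L) {
    warning("empty FASTA: ", fasta_in)
    report <- data.frame(id = character(0), species = character(0),
      chemotype = character(0), group = integer(0))
    if (!is.null(report_out)) .write_report(report, report_out)
    return(invisible(report))
  }
  species <- ifelse(
    grepl("species=", names(seqs)),
    sub(".*species=([^ ]+).*", "\\1", names(seqs)),
    "unknown species"
  )
  ids <- sub("\\s.*$", "", names(seqs))
  records <- lapply(seq_along(seqs), function(i) {
    structure(
      list(id = ids[i], species_label = species[i],
        sequence = unname(seqs[i]), chemotype = NA_character_),
      class = "cluster_record"
    )
  })
  calls <- lapply(records, call_modules, refs = refs)
  chemotypes <- vapply(calls, function(cc) {
    as.character(heptapeptide_to_compound(cc))
  }, character(1))
  groups <- group_clusters(records, identity_threshold, coverage_threshold)
  report <- data.frame(
    id = ids, species = species, chemotype = chemotypes,
    group = groups$group
  )
  for (m in 1:7) {
    report[[paste0("aa", m)]] <- vapply(calls, function(cc) cc$call[m],
      character(1))
    report[[paste0("id", m)]] <- round(vapply(calls,
      function(cc) cc$identity[m], numeric(1)), 4)
  }
  if (!is.null(proteome_fasta) && !is.null(reference_sfp)) {
    proteome <- .read_fasta_or_stop(proteome_fasta, "protein")
    report$sfp <- sfp_present(proteome, reference_sfp)$present
  }
  if (!is.null(report_out)) .write_report(report, report_out)
  invisible(report)
}

#' Assign chemotypes to all spectra of an MGF file
#'
#' One report row per spectrum. A spectrum without a precursor cannot be
#' assigned; its row is flagged (`call = "error"`) and the run continues.
#'
#' @param mgf_in Path to an MGF peak list file.
#' @param report_out Optional path for the TSV report.
#' @param cfg A [match_config()].
#' @return Data frame (written to `report_out` when given) with columns
#'   `id`, `call`, `chain_n`, `score`, `n_matched`, `ambiguous_with`,
#'   `note`.
#' @export
assign_spectra <- function(mgf_in, report_out = NULL, cfg = match_config()) {
  if (!file.exists(mgf_in)) stop("input file not found: ", mgf_in)
  spectra <- read_mgf(mgf_in)
  rows <- lapply(spectra, function(sp) {
    if (is.na(sp$precursor_mz)) {
      return(data.frame(id = sp$id, call = "error", chain_n = NA_integer_,
        score = NA_real_, n_matched = NA_integer_, ambiguous_with = "",
        note = "no precursor m/z"))
    }
    a <- assign_chemotype(sp, cfg)
    data.frame(
      id = a$spectrum_id, call = a$compound, chain_n = a$chain_n,
      score = round(a$score, 4),
      n_matched = if (is.null(a$matched_ions)) 0L else nrow(a$matched_ions),
      ambiguous_with = paste(
        sprintf("%s:C%d", a$ambiguous_with$compound,
          a$ambiguous_with$chain_n),
        collapse = ";"
      ),
      note = a$reason
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(report_out)) .write_report(report, report_out)
  invisible(report)
}

#' Run the ituB PCR assay over a FASTA of templates
#'
#' @param fasta_in Path to a nucleotide FASTA of candidate ituB templates.
#' @param report_out Optional path for the TSV report.
#' @param psets Primer sets.
#' @param max_mismatch Mismatches tolerated per primer.
#' @param band_tolerance Relative band-size tolerance.
#' @return Data frame (written to `report_out` when given) with columns
#'   `id`, `call`, `products` (semicolon-joined `set:length` pairs).
#' @export
pcr_type <- function(fasta_in, report_out = NULL, psets = primer_sets(),
                     max_mismatch = 0L, band_tolerance = 0.10) {
  seqs <- .read_fasta_or_stop(fasta_in, "dna")
  rows <- lapply(seq_along(seqs), function(i) {
    call <- classify_by_band(seqs[[i]], psets, max_mismatch, band_tolerance)
    data.frame(
      id = sub("\\s.*$", "", names(seqs)[i]),
      call = call$classified_compound,
      products = if (nrow(call$products)) {
        paste(sprintf("%s:%d", call$products$set, call$products$length),
          collapse = ";")
      } else {
        ""
      }
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(report_out)) .write_report(report, report_out)
  invisible(report)
}
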