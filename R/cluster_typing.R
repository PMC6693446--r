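# Chemotype calling from nucleotide cluster sequences: locate the 7 NRPS
# modules, call the residue each encodes, map the heptapeptide to a
# compound, group clusters within species, and check for the sfp gene.

#' Call the seven NRPS modules of a cluster sequence
#'
#' Scans the cluster with every reference module sequence (one per
#' (position, residue) pair, see [module_refs()]); for each module position
#' the reference with the highest identity over its footprint determines
#' the amino-acid call. A position with no reference above `floor_identity`
#' is called `"unknown"`. Reverse-strand input is detected via the
#' conserved module-1 reference and normalized to the plus strand first.
#'
#' @param cluster A `cluster_record` or a nucleotide string.
#' @param refs Reference panel data frame (`module_index`, `amino_acid`,
#'   `sequence`).
#' @param floor_identity Minimum identity for a call (default 0.5).
#' @param check_strand Try the reverse complement and use whichever strand
#'   anchors the conserved module-1 reference better (default `TRUE`).
#' @return Data frame with one row per module position: `position`,
#'   `call`, `identity`, `start`, `end` (1-based footprint on the
#'   normalized strand), plus attribute `strand` (`"+"` or `"-"`).
#' @examples
#' cl <- gen_cluster("iturin A", generator_config(seed = 1,
#'   mutation_rate = 0))
#' call_modules(cl)$call
#' @export
call_modules <- function(cluster, refs = module_refs(),
                         floor_identity = 0.5, check_strand = TRUE) {
  seq <- if (inherits(cluster, "cluster_record")) cluster$sequence
         else as.character(cluster)
  strand <- "+"
  if (check_strand) {
    m1 <- refs$sequence[refs$module_index == 1L][1]
    fwd_n <- nrow(.kmer_anchors(m1, Biostrings::DNAString(seq),
      n_seeds = 20L))
    rc <- .revcomp(seq)
    rev_n <- nrow(.kmer_anchors(m1, Biostrings::DNAString(rc),
      n_seeds = 20L))
    if (rev_n > fwd_n) {
      seq <- rc
      strand <- "-"
    }
  }
  subject_dna <- Biostrings::DNAString(seq)
  subject_chars <- strsplit(seq, "")[[1]]
  out <- do.call(rbind, lapply(1:7, function(i) {
    cand <- refs[refs$module_index == i, , drop = FALSE]
    hits <- lapply(cand$sequence, .module_hit, subject_dna = subject_dna,
      subject_chars = subject_chars)
    ids <- vapply(hits, `[[`, numeric(1), "identity")
    j <- which.max(ids)
    if (ids[j] < floor_identity) {
      data.frame(position = i, call = "unknown", identity = ids[j],
        start = NA_integer_, end = NA_integer_)
    } else {
      data.frame(position = i, call = cand$amino_acid[j],
        identity = ids[j], start = hits[[j]]$start, end = hits[[j]]$end)
    }
  }))
  attr(out, "strand") <- strand
  out
}

#' Map a called heptapeptide to a compound
#'
#' Exact match against the registry. A heptapeptide that starts with the
#' conserved Asn-Tyr-Asn head but matches no registry entry is a
#' `"novel variant"`; one that lacks the head is `"not iturinic"`; any
#' `"unknown"` module call yields `"indeterminate"` (with the reason in the
#' `reason` attribute).
#'
#' @param calls Character vector of 7 three-letter residue calls, or the
#'   data frame returned by [call_modules()].
#' @param registry Compound registry.
#' @return Character scalar: a compound name, `"novel variant"`,
#'   `"not iturinic"` or `"indeterminate"`.
#' @examples
#' heptapeptide_to_compound(c("Asn", "Tyr", "Asn", "Pro", "Glu", "Ser",
#'   "Thr"))
#' @export
heptapeptide_to_compound <- function(calls, registry = compound_registry()) {
  if (is.data.frame(calls)) calls <- calls$call
  stopifnot(length(calls) == 7L)
  if (any(calls == "unknown")) {
    out <- "indeterminate"
    attr(out, "reason") <- paste0("module position(s) ",
      paste(which(calls == "unknown"), collapse = ","),
      " could not be called")
    return(out)
  }
  hepta <- apply(registry[, paste0("aa", 1:7)], 1, paste, collapse = "-")
  i <- match(paste(calls, collapse = "-"), hepta)
  if (!is.na(i)) {
    return(registry$name[i])
  }
  if (identical(calls[1:3], c("Asn", "Tyr", "Asn"))) "novel variant"
  else "not iturinic"
}

#' Group clusters by species and nucleotide similarity
#'
#' Single-linkage grouping within each species: two clusters are linked
#' when their pairwise nucleotide identity exceeds `identity_threshold` and
#' the compared region covers at least `coverage_threshold` of both
#' sequences ("full alignment length"); connected components are the cluster
#' groups. A module swap replaces 3-4 kb of sequence, breaks coverage, and
#' therefore always founds a new group, mirroring how cluster types are
#' separated within a species.
#'
#' @param clusters List of `cluster_record` objects (all with
#'   `species_label`).
#' @param identity_threshold Identity required for an edge (default 0.94,
#'   exclusive).
#' @param coverage_threshold Mutual coverage required for an edge (default
#'   0.95).
#' @return Data frame with columns `id`, `species`, `group` (integer group
#'   id, numbered in input order).
#' @export
group_clusters <- function(clusters, identity_threshold = 0.94,
                           coverage_threshold = 0.95) {
  stopifnot(length(clusters) >= 1L)
  ids <- vapply(clusters, `[[`, character(1), "id")
  species <- vapply(clusters, `[[`, character(1), "species_label")
  if (anyNA(species) || any(!nzchar(species))) {
    stop("every cluster needs a species_label for grouping")
  }
  n <- length(clusters)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || species[i] != species[j]) next
      pr <- .pair_identity(clusters[[i]]$sequence, clusters[[j]]$sequence)
      if (pr$identity > identity_threshold &&
          pr$coverage_a >= coverage_threshold &&
          pr$coverage_b >= coverage_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  data.frame(
    id = ids, species = species,
    group = as.integer(factor(roots, levels = unique(roots)))
  )
}

#' Detect the sfp activation gene in a proteome
#'
#' The 4'-phosphopantetheinyl transferase (sfp) is required to activate the
#' NRPS carrier domains; a genome carrying an iturinic cluster but no sfp
#' homolog is predicted to be a non-producer. Each protein is aligned
#' locally (BLOSUM62) against the reference; presence requires identity and
#' reference coverage above the thresholds.
#'
#' @param proteome Character vector of protein sequences (or
#'   `AAStringSet`).
#' @param reference_sfp Reference sfp protein sequence.
#' @param min_identity Identity threshold over the aligned region (default
#'   0.4).
#' @param min_coverage Minimum fraction of the reference covered by the
#'   local alignment (default 0.7).
#' @return List: `present` (logical), `best_identity`, `best_coverage`,
#'   `best_index` (index into `proteome`, `NA` when empty input matches
#'   nothing).
#' @export
sfp_present <- function(proteome, reference_sfp, min_identity = 0.4,
                        min_coverage = 0.7) {
  proteome <- as.character(proteome)
  stopifnot(length(proteome) >= 1L)
  ref <- Biostrings::AAString(reference_sfp)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  hits <- do.call(rbind, lapply(seq_along(proteome), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      ref, Biostrings::AAString(proteome[i]),
      type = "local", substitutionMatrix = get("BLOSUM62"),
      gapOpening = 10, gapExtension = 0.5
    )
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    data.frame(
      index = i,
      identity = if (alen > 0) Biostrings::nmatch(aln) / alen else 0,
      coverage = alen / nchar(reference_sfp)
    )
  }))
  passing <- hits$identity >= min_identity & hits$coverage >= min_coverage
  # Best hit: prefer hits meeting coverage, then highest identity.
  ord <- order(-(hits$coverage >= min_coverage), -hits$identity)
  best <- hits[ord[1], ]
  list(
    present = any(passing),
    best_identity = best$identity,
    best_coverage = best$coverage,
    best_index = best$index
  )
}
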