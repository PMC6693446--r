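# Self-contained nucleotide similarity search: exact k-mer anchoring with
# offset voting, direct base comparison on anchored runs, and a
# dynamic-programming fallback when anchors disagree (indels).

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Exact k-mer anchors of `query` (character) in `subject` (DNAString).
# Seeds are taken every `step` positions (or `n_seeds` evenly spaced).
# Only seeds with a unique exact hit are kept: offset = subject - query pos.
.kmer_anchors <- function(query, subject, k = 21L, step = NULL,
                          n_seeds = NULL) {
  nq <- nchar(query)
  if (nq < k) return(data.frame(qpos = integer(0), offset = integer(0)))
  last <- nq - k + 1L
  qpos <- if (!is.null(step)) {
    seq(1L, last, by = step)
  } else {
    unique(as.integer(round(seq(1L, last, length.out = n_seeds))))
  }
  res <- lapply(qpos, function(q) {
    hits <- Biostrings::matchPattern(substr(query, q, q + k - 1L), subject)
    if (length(hits) == 1L) {
      data.frame(qpos = q, offset = IRanges::start(hits)[1] - q)
    } else {
      NULL
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(qpos = integer(0), offset = integer(0))
  else out
}

# Percent of identical bases between query and subject at a fixed offset,
# over query positions [qs, qe].
.offset_matches <- function(qchars, schars, offset, qs, qe) {
  qs <- max(qs, 1L, 1L - offset)
  qe <- min(qe, length(qchars), length(schars) - offset)
  if (qe < qs) return(c(matches = 0, compared = 0))
  idx <- qs:qe
  c(
    matches = sum(qchars[idx] == schars[idx + offset]),
    compared = length(idx)
  )
}

# Best local placement of a ~3 kb module reference inside a cluster
# sequence. Fast path: consistent anchor offset + direct comparison.
# Fallback (inconsistent offsets, i.e. indels): global-local DP alignment of
# the reference against the anchored window.
.module_hit <- function(query, subject_dna, subject_chars,
                        k = 21L, n_seeds = 40L, min_support = 3L) {
  miss <- list(identity = 0, start = NA_integer_, end = NA_integer_,
    method = "none")
  anchors <- .kmer_anchors(query, subject_dna, k = k, n_seeds = n_seeds)
  if (nrow(anchors) < min_support) return(miss)
  tab <- table(anchors$offset)
  best_off <- as.integer(names(tab)[which.max(tab)])
  support <- max(tab)
  if (support < min_support) return(miss)
  nq <- nchar(query)
  qchars <- strsplit(query, "")[[1]]
  if (support / nrow(anchors) >= 0.9) {
    mc <- .offset_matches(qchars, subject_chars, best_off, 1L, nq)
    return(list(
      identity = unname(mc["matches"]) / nq,
      start = best_off + 1L, end = best_off + nq, method = "anchored"
    ))
  }
  # Indel-tolerant fallback on the window spanned by the anchors.
  lo <- max(1L, min(anchors$offset) + 1L - 100L)
  hi <- min(length(subject_chars), max(anchors$offset) + nq + 100L)
  window <- paste(subject_chars[lo:hi], collapse = "")
  aln <- Biostrings::pairwiseAlignment(query, window,
    type = "global-local")
  list(
    identity = Biostrings::nmatch(aln) / nq,
    start = lo + IRanges::start(Biostrings::subject(aln)) - 1L,
    end = lo + IRanges::end(Biostrings::subject(aln)) - 1L,
    method = "dp"
  )
}

# Whole-sequence pairwise identity and mutual coverage, by maximal runs of
# consistent anchor offset. The outer runs are extended toward the sequence
# ends by at most 3 seed steps (anchors thin out near the ends when sites
# are mutated, but a genuinely divergent end must not be claimed), so for
# substitution-only divergence this closely tracks the Hamming identity of
# a gap-free global alignment.
.pair_identity <- function(a, b, k = 21L, step = 200L) {
  na_ <- nchar(a)
  nb_ <- nchar(b)
  bdna <- Biostrings::DNAString(b)
  anchors <- .kmer_anchors(a, bdna, k = k, step = step)
  if (nrow(anchors) == 0L) {
    return(list(identity = 0, coverage_a = 0, coverage_b = 0))
  }
  anchors <- anchors[order(anchors$qpos), , drop = FALSE]
  run_id <- cumsum(c(TRUE, diff(anchors$offset) != 0))
  achars <- strsplit(a, "")[[1]]
  bchars <- strsplit(b, "")[[1]]
  total <- c(matches = 0, compared = 0)
  n_runs <- max(run_id)
  for (r in seq_len(n_runs)) {
    ra <- anchors[run_id == r, , drop = FALSE]
    off <- ra$offset[1]
    qs <- min(ra$qpos)
    qe <- max(ra$qpos) + k - 1L
    if (r == 1L) qs <- max(1L, qs - 3L * step)
    if (r == n_runs) qe <- min(na_, qe + 3L * step)
    total <- total + .offset_matches(achars, bchars, off, qs, qe)
  }
  compared <- unname(total["compared"])
  list(
    identity = if (compared > 0) unname(total["matches"]) / compared else 0,
    coverage_a = compared / na_,
    coverage_b = compared / nb_
  )
}
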