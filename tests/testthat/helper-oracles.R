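# Independent oracles used to freeze expected values. These deliberately do
# NOT reuse the package's mass tables or alignment machinery: residue masses
# are hand-typed from standard monoisotopic tables, fragment enumeration is
# a direct brute-force loop, and sequence identity is a direct per-base
# comparison.

ORACLE_RESIDUE <- c(
  Gly = 57.02146, Ser = 87.03203, Pro = 97.05276, Thr = 101.04768,
  Asn = 114.04293, Gln = 128.05858, Glu = 129.04259, Tyr = 163.06333
)
ORACLE_PROTON <- 1.0072765
ORACLE_WATER <- 18.0105646
ORACLE_KETENE <- 42.0105647

# Beta-amino fatty-acyl residue CnH(2n-1)NO, summed from atomic masses.
oracle_beta_mass <- function(n) {
  n * 12 + (2 * n - 1) * 1.0078250 + 14.0030740 + 15.9949146
}

# Neutral cyclic parent: plain residue sum, no water (amide ring closure).
oracle_parent_mass <- function(hepta, n) {
  sum(ORACLE_RESIDUE[hepta]) + oracle_beta_mass(n)
}

# Brute-force enumeration of the unique fragment m/z values that
# diagnostic_table() should contain for a compound with heptapeptide
# `hepta`, proline position `pro_pos` (NA when absent) and chain length n:
# b/y series (k = 1..7) from the tail opening and, when a proline exists,
# from the opening N-terminal to it, plus the Tyr immonium-type ion and the
# beta ketene-loss ion. Returns the sorted unique m/z at 1e-4 Da.
oracle_fragment_mzs <- function(hepta, pro_pos, n) {
  units <- c(ORACLE_RESIDUE[hepta], beta = oracle_beta_mass(n))
  openings <- 8L
  if (!is.na(pro_pos)) openings <- c(openings, pro_pos - 1L)
  mzs <- c(
    ORACLE_RESIDUE[["Tyr"]] - 27.9949146 + ORACLE_PROTON,
    oracle_beta_mass(n) + ORACLE_PROTON - ORACLE_KETENE
  )
  for (site in openings) {
    linear <- units[((site + 1:8 - 1L) %% 8L) + 1L]
    for (k in 1:7) {
      mzs <- c(
        mzs,
        sum(linear[1:k]) + ORACLE_PROTON,
        sum(linear[(8 - k + 1):8]) + ORACLE_WATER + ORACLE_PROTON
      )
    }
  }
  mzs <- sort(mzs)
  mzs[c(TRUE, diff(mzs) > 1e-4)]
}

# Direct per-base identity of two equal-length sequences (the brute-force
# identity for substitution-only divergence, where the optimal gap-free
# global alignment is the diagonal).
oracle_hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

# Independent single-linkage partition from a pairwise edge matrix.
oracle_components <- function(edge) {
  n <- nrow(edge)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(edge[v, ] & is.na(comp)))
    }
  }
  comp
}

# Random sequences for negative controls.
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
    collapse = "")
}

# Mutate exactly `count` positions of a nucleotide string.
mutate_exact <- function(seq, count, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  idx <- sample(length(chars), count)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# Mutate a protein at exactly `count` positions.
mutate_protein <- function(seq, count, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  idx <- sample(length(chars), count)
  for (i in idx) chars[i] <- sample(setdiff(aa, chars[i]), 1)
  paste(chars, collapse = "")
}
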