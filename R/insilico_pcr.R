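# In-silico PCR for the B. velezensis ituB diagnostic assay: the three
# primer sets share a forward primer on the conserved AA#3 module and
# differ in reverse primers on the variable AA#4 module, yielding bands of
# ~1,113 bp (iturin), ~732 bp (bacillomycin D) and ~1,016 bp (bacillomycin
# L) that are separated on an agarose gel.

#' The three ituB primer sets
#'
#' @param path Optional path to an alternative tab-separated primer table;
#'   defaults to the sets shipped with the package.
#' @return Data frame with columns `name`, `forward`, `reverse` (both
#'   5'->3'), `expected_band` (bp), `target_compound`.
#' @examples
#' primer_sets()[, c("name", "expected_band", "target_compound")]
#' @export
primer_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "primer_sets.tsv",
      package = "iturityper", mustWork = TRUE
    )
  }
  ps <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (length(unique(ps$forward)) != 1L) {
    stop("the ituB primer sets must share one forward primer")
  }
  ps
}

.primer_hits <- function(primer, subject, max_mismatch) {
  hits <- Biostrings::matchPattern(primer, subject,
    max.mismatch = max_mismatch)
  if (length(hits) == 0L || max_mismatch == 0L) return(hits)
  # The 3 bases at the 3' end must match exactly or extension fails.
  keep <- vapply(seq_along(hits), function(i) {
    found <- as.character(hits[[i]])
    substr(found, nchar(primer) - 2L, nchar(primer)) ==
      substr(primer, nchar(primer) - 2L, nchar(primer))
  }, logical(1))
  hits[keep]
}

#' Predict amplicons of one primer set on a template
#'
#' The forward primer is matched on the plus strand and the
#' reverse-complemented reverse primer downstream of it; the symmetric
#' orientation (primers annealing to the other strand) is searched too, so
#' a template and its reverse complement give identical products. Up to
#' `max_mismatch` mismatches are allowed per primer, but the three terminal
#' 3' bases must match exactly; products longer than 5 kb are not reported
#' (they would not amplify efficiently).
#'
#' @param template Nucleotide string (or `DNAString`).
#' @param pset One row of [primer_sets()] (data frame or list with
#'   `name`, `forward`, `reverse`, `expected_band`, `target_compound`).
#' @param max_mismatch Mismatches tolerated per primer (default 0,
#'   conservative: the assay was validated with exact-matching strains).
#' @return Data frame of products: `set`, `start`, `end` (1-based,
#'   inclusive of both primer footprints), `length`, `strand`. Zero rows
#'   when nothing amplifies.
#' @examples
#' ps <- primer_sets()
#' tpl <- gen_ituB_template("bacillomycin D", generator_config(seed = 1))
#' find_amplicons(tpl, ps[2, ])
#' @export
find_amplicons <- function(template, pset, max_mismatch = 0L) {
  template <- as.character(template)
  if (is.data.frame(pset)) pset <- as.list(pset[1, ])
  fwd <- toupper(pset$forward)
  rev <- toupper(pset$reverse)
  if (nchar(template) < nchar(fwd) + nchar(rev)) {
    stop("template shorter than the combined primer length")
  }
  subject <- Biostrings::DNAString(template)
  scan <- function(p_left, p_right, strand) {
    lhits <- .primer_hits(p_left, subject, max_mismatch)
    rhits <- .primer_hits(.revcomp(p_right), subject, max_mismatch)
    if (length(lhits) == 0L || length(rhits) == 0L) return(NULL)
    combos <- expand.grid(
      li = seq_along(lhits), ri = seq_along(rhits)
    )
    res <- lapply(seq_len(nrow(combos)), function(r) {
      s <- IRanges::start(lhits)[combos$li[r]]
      e <- IRanges::end(rhits)[combos$ri[r]]
      len <- e - s + 1L
      if (e > s && len <= 5000L &&
          len >= nchar(p_left) + nchar(p_right)) {
        data.frame(set = pset$name, start = s, end = e, length = len,
          strand = strand)
      } else {
        NULL
      }
    })
    do.call(rbind, res)
  }
  out <- rbind(
    scan(fwd, rev, "+"),
    scan(rev, fwd, "-")
  )
  if (is.null(out)) {
    out <- data.frame(set = character(0), start = integer(0),
      end = integer(0), length = integer(0), strand = character(0))
  }
  # A product found in both orientations is the same physical amplicon.
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a template by its band pattern across the three sets
#'
#' Runs [find_amplicons()] for every primer set and applies the gel-reading
#' rule: exactly one set with a product within `band_tolerance` of its
#' expected band calls that set's target compound; no such product is
#' `"no product"`; more than one set is `"ambiguous"`.
#'
#' @param template Nucleotide string, or a precomputed products data frame
#'   (with a `set` column) if `products` is given instead.
#' @param psets Primer sets.
#' @param max_mismatch Passed to [find_amplicons()].
#' @param band_tolerance Relative band-size tolerance (default 0.10,
#'   emulating agarose-gel resolution).
#' @param species_label Optional; a warning is issued for species other
#'   than B. velezensis, for which alone the assay has been validated.
#' @return List of class `pcr_call`: `classified_compound`, `products`
#'   (all products, with an `in_band` flag).
#' @export
classify_by_band <- function(template, psets = primer_sets(),
                             max_mismatch = 0L, band_tolerance = 0.10,
                             species_label = NULL) {
  if (!is.null(species_label) &&
      !grepl("velezensis", species_label, ignore.case = TRUE)) {
    warning("the ituB primer assay is validated only for B. velezensis; ",
      "calls for '", species_label, "' need independent confirmation")
  }
  products <- do.call(rbind, lapply(seq_len(nrow(psets)), function(i) {
    pr <- find_amplicons(template, psets[i, ], max_mismatch)
    if (nrow(pr)) {
      pr$expected_band <- psets$expected_band[i]
      pr$target_compound <- psets$target_compound[i]
    }
    pr
  }))
  if (is.null(products) || nrow(products) == 0L) {
    return(structure(
      list(classified_compound = "no product",
        products = data.frame()),
      class = "pcr_call"
    ))
  }
  products$in_band <- abs(products$length - products$expected_band) <=
    band_tolerance * products$expected_band
  sets_in_band <- unique(products$set[products$in_band])
  call <- if (length(sets_in_band) == 0L) {
    "no product"
  } else if (length(sets_in_band) > 1L) {
    "ambiguous"
  } else {
    products$target_compound[products$in_band][1]
  }
  structure(
    list(classified_compound = call, products = products),
    class = "pcr_call"
  )
}

#' @export
print.pcr_call <- function(x, ...) {
  cat("PCR call:", x$classified_compound, "\n")
  if (nrow(x$products)) {
    print(x$products[, c("set", "length", "expected_band", "in_band")])
  }
  invisible(x)
}

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K), for 5'->3' dinucleotides on the top
# strand paired with their complements.
.NN_DH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
  GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4, CT = -21.0,
  GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9
)

#' Nearest-neighbor melting temperature of a primer
#'
#' Unified nearest-neighbor thermodynamics with terminal initiation terms,
#' the entropic salt correction 0.368 (N-1) ln[Na+], and the CT/4
#' concentration term for non-self-complementary duplexes. Defaults: 50 mM
#' Na+, 0.5 uM total oligo. Absolute values are method- and
#' condition-dependent; within one method the ranking and spacing of
#' primers is what matters.
#'
#' @param primer Nucleotide string (ACGT only), length >= 10.
#' @param na_molar Monovalent cation concentration (mol/L, default 0.05).
#' @param oligo_molar Total oligo concentration (mol/L, default 5e-7).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' estimate_tm("CACGAACAGACAAAACA")
#' @export
estimate_tm <- function(primer, na_molar = 0.05, oligo_molar = 5e-7) {
  primer <- toupper(primer)
  n <- nchar(primer)
  if (n < 10L) stop("primer too short for a nearest-neighbor estimate")
  chars <- strsplit(primer, "")[[1]]
  if (!all(chars %in% .BASES)) {
    stop("primer must contain only A, C, G, T")
  }
  pairs <- paste0(chars[-n], chars[-1])
  dh <- sum(.NN_DH[pairs])
  ds <- sum(.NN_DS[pairs])
  for (terminal in chars[c(1, n)]) {
    if (terminal %in% c("G", "C")) {
      dh <- dh + 0.1
      ds <- ds - 2.8
    } else {
      dh <- dh + 2.3
      ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  gas_const <- 1.98722 # cal/(mol K)
  1000 * dh / (ds + gas_const * log(oligo_molar / 4)) - 273.15
}
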