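# Seeded synthetic data: NRPS clusters, ituB PCR templates and MS/MS
# spectra with the structure the analysis assumes, so every stage of the
# pipeline is testable without downloading genomes.

.BASES <- c("A", "C", "G", "T")

# Evaluate expr under a temporary RNG state keyed by `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit key from string parts (rolling hash; the multiplier
# keeps every intermediate product below 2^53 so arithmetic stays exact).
.hash_key <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\x1f")
  h <- 104729
  for (v in utf8ToInt(s)) {
    h <- (h * 69069 + v) %% 2147483647
  }
  as.integer(h)
}

.random_dna <- function(n, key) {
  .with_seed(key, paste(sample(.BASES, n, replace = TRUE), collapse = ""))
}

.mutate_dna <- function(seq, rate, key, exact_count = FALSE) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  .with_seed(key, {
    idx <- if (exact_count) {
      sample(length(chars), round(rate * length(chars)))
    } else {
      which(stats::runif(length(chars)) < rate)
    }
    for (i in idx) {
      chars[i] <- sample(setdiff(.BASES, chars[i]), 1)
    }
  })
  paste(chars, collapse = "")
}

#' Generator configuration
#'
#' Defaults encode the conditions the downstream analyses are designed for:
#' substitution rate 3% per site (the highest rate at which chemotype
#' recovery is expected to be perfect), fragment m/z jitter of 5 ppm and 50
#' uniform decoy peaks per spectrum (Orbitrap-scale noise plus chemical
#' background), log-normal peak intensities, and a fixed `template_seed`
#' identifying the reference panel of module templates that generated
#' clusters and the reference set share.
#'
#' @param seed Integer seed for all randomness of one generated object.
#' @param mutation_rate Per-site substitution rate in `[0, 0.25]`.
#' @param mz_sigma_ppm Gaussian m/z jitter (ppm) on fragment peaks.
#' @param n_decoys Number of uniform decoy peaks in `[100, precursor]`.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param template_seed Seed of the module-template panel (changing it
#'   changes the simulated "database"; keep it equal between clusters and
#'   the references used to type them).
#' @param indels If `TRUE`, one in ten mutations is a 1-3 nt indel instead
#'   of a substitution (exercises coverage-based grouping).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             mutation_rate = 0.03,
                             mz_sigma_ppm = 5,
                             n_decoys = 50L,
                             intensity_meanlog = log(1000),
                             intensity_sdlog = 1,
                             template_seed = 20190807L,
                             indels = FALSE) {
  stopifnot(
    mutation_rate >= 0, mutation_rate <= 0.25,
    mz_sigma_ppm >= 0, n_decoys >= 0
  )
  structure(
    list(
      seed = as.integer(seed), mutation_rate = mutation_rate,
      mz_sigma_ppm = mz_sigma_ppm, n_decoys = as.integer(n_decoys),
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      template_seed = as.integer(template_seed),
      indels = indels
    ),
    class = "generator_config"
  )
}

#' Module template sequence for one (position, residue) pair
#'
#' A deterministic pseudo-random nucleotide sequence of about 3 kb standing
#' in for the NRPS module encoding `amino_acid` at module position
#' `module_index` (real modules are ~1,000 amino acids, i.e. ~3 kb, and a
#' module swap changes 3-4 kb of nucleotide sequence). Distinct
#' (position, residue) pairs share only random-level identity (<60%).
#'
#' @param module_index Module position 1..7.
#' @param amino_acid Three-letter residue code.
#' @param seed Template-panel seed (see [generator_config()]).
#' @return Nucleotide string, length in `[2800, 3200]`, deterministic in
#'   its three arguments.
#' @export
gen_module_template <- function(module_index, amino_acid, seed) {
  module_index <- as.integer(module_index)
  stopifnot(module_index >= 1L, module_index <= 7L)
  key <- .hash_key("module", module_index, amino_acid, seed)
  len <- 2800L + key %% 401L
  .random_dna(len, key)
}

#' Reference panel of module templates
#'
#' One reference per (module position, residue) pair occurring in the
#' registry, as consumed by [call_modules()].
#'
#' @param registry Compound registry.
#' @param template_seed Template-panel seed.
#' @return Data frame with columns `module_index`, `amino_acid`,
#'   `sequence`.
#' @export
module_refs <- function(registry = compound_registry(),
                        template_seed = generator_config()$template_seed) {
  pairs <- unique(do.call(rbind, lapply(1:7, function(i) {
    data.frame(
      module_index = i, amino_acid = registry[[paste0("aa", i)]],
      stringsAsFactors = FALSE
    )
  })))
  pairs <- pairs[order(pairs$module_index, pairs$amino_acid), ]
  pairs$sequence <- mapply(gen_module_template, pairs$module_index,
    pairs$amino_acid, MoreArgs = list(seed = template_seed))
  rownames(pairs) <- NULL
  pairs
}

#' Generate a synthetic iturinic NRPS cluster
#'
#' Assembles the family's 4-gene architecture: a non-modular first gene,
#' then the 7 modules distributed 1/4/2 across genes 2, 3 and 4, with short
#' intergenic spacers and flanking sequence. Module templates are selected
#' by the compound's heptapeptide from the `template_seed` panel, then point
#' mutations are applied at `mutation_rate` over the whole cluster.
#'
#' @param compound Compound name or `compound_definition`.
#' @param cfg A [generator_config()].
#' @param id Record identifier.
#' @param species_label Species label attached to the record (defaults to
#'   the compound's first reported producer).
#' @return List of class `cluster_record`: `id`, `species_label`,
#'   `sequence`, `gene_spans` and `module_spans` (1-based closed-interval
#'   data frames on the unmutated coordinate system) and `chemotype`, the
#'   generator's truth label.
#' @examples
#' cl <- gen_cluster("iturin A", generator_config(seed = 1))
#' cl$module_spans
#' @export
gen_cluster <- function(compound, cfg = generator_config(),
                        id = NULL,
                        species_label = NULL) {
  compound <- .as_compound(compound)
  if (is.null(species_label)) species_label <- compound$producer_species[1]
  if (is.null(id)) {
    id <- sprintf("%s_seed%d", gsub("[^A-Za-z0-9]+", "_", compound$name),
      cfg$seed)
  }
  key <- .hash_key("cluster", compound$name, cfg$seed)

  templates <- lapply(1:7, function(i) {
    gen_module_template(i, compound$heptapeptide[i], cfg$template_seed)
  })
  # The non-modular scaffold (first gene, spacers, flanks) is shared by all
  # clusters of one template panel: homologous clusters differ by their
  # variable modules and by the per-seed mutations, not by their backbone.
  scaffold <- .hash_key("scaffold", cfg$template_seed)
  flank5 <- .random_dna(300L, .hash_key(scaffold, "flank5"))
  gene1 <- .random_dna(1200L, .hash_key(scaffold, "gene1"))
  spacers <- lapply(1:3, function(i) {
    .random_dna(150L, .hash_key(scaffold, "spacer", i))
  })
  flank3 <- .random_dna(300L, .hash_key(scaffold, "flank3"))

  gene_modules <- list(integer(0), 1L, 2:5, 6:7)
  pieces <- character(0)
  gene_spans <- data.frame(gene = 1:4, start = NA_integer_,
    end = NA_integer_)
  module_spans <- data.frame(position = 1:7, start = NA_integer_,
    end = NA_integer_)
  pos <- 1L
  append_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    from <- pos
    pos <<- pos + nchar(s)
    c(from, pos - 1L)
  }
  append_piece(flank5)
  for (g in 1:4) {
    gene_start <- pos
    if (g == 1L) {
      append_piece(gene1)
    } else {
      for (m in gene_modules[[g]]) {
        sp <- append_piece(templates[[m]])
        module_spans[m, c("start", "end")] <- sp
      }
    }
    gene_spans[g, c("start", "end")] <- c(gene_start, pos - 1L)
    if (g < 4L) append_piece(spacers[[g]])
  }
  append_piece(flank3)
  seq <- paste(pieces, collapse = "")
  seq <- .mutate_dna(seq, cfg$mutation_rate, .hash_key(key, "mut"))
  if (cfg$indels) {
    seq <- .apply_indels(seq, cfg$mutation_rate / 10, .hash_key(key, "indel"))
  }
  structure(
    list(
      id = id, species_label = species_label, sequence = seq,
      gene_spans = gene_spans, module_spans = module_spans,
      chemotype = compound$name
    ),
    class = "cluster_record"
  )
}

.apply_indels <- function(seq, rate, key) {
  chars <- strsplit(seq, "")[[1]]
  .with_seed(key, {
    idx <- sort(which(stats::runif(length(chars)) < rate), decreasing = TRUE)
    for (i in idx) {
      w <- sample(1:3, 1)
      if (stats::runif(1) < 0.5) {
        chars <- append(chars, sample(.BASES, w, replace = TRUE), after = i)
      } else {
        chars <- chars[-(i:min(i + w - 1L, length(chars)))]
      }
    }
  })
  paste(chars, collapse = "")
}

#' @export
print.cluster_record <- function(x, ...) {
  cat("cluster_record '", x$id, "' (", x$species_label, "): ",
    nchar(x$sequence), " nt, chemotype truth ", x$chemotype, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic MS/MS spectrum
#'
#' Takes every ion of [diagnostic_table()] for the (compound, chain) truth,
#' jitters each m/z with Gaussian ppm noise, draws log-normal intensities,
#' and adds `n_decoys` uniform decoy peaks in `[100, precursor]` whose
#' positions are independent of the compound. The precursor is set to the
#' exact theoretical [M+H]+.
#'
#' @param compound Compound name or definition.
#' @param chain_n Beta-amino acid chain length.
#' @param cfg A [generator_config()].
#' @param id Spectrum identifier.
#' @return `ms2_spectrum` with attribute `truth` =
#'   `list(compound, chain_n)`.
#' @examples
#' sp <- gen_spectrum("bacillomycin D", 14,
#'   generator_config(seed = 7, mz_sigma_ppm = 0, n_decoys = 0))
#' @export
gen_spectrum <- function(compound, chain_n, cfg = generator_config(),
                         id = NULL) {
  compound <- .as_compound(compound)
  tab <- diagnostic_table(compound, chain_n)
  prec <- attr(tab, "precursor_mz")
  if (is.null(id)) {
    id <- sprintf("%s_C%d_seed%d",
      gsub("[^A-Za-z0-9]+", "_", compound$name), chain_n, cfg$seed)
  }
  key <- .hash_key("spectrum", compound$name, chain_n, cfg$seed)
  peaks <- .with_seed(key, {
    mz <- tab$mz * (1 + stats::rnorm(nrow(tab)) * cfg$mz_sigma_ppm * 1e-6)
    intensity <- stats::rlnorm(nrow(tab), cfg$intensity_meanlog,
      cfg$intensity_sdlog)
    if (cfg$n_decoys > 0L) {
      mz <- c(mz, stats::runif(cfg$n_decoys, 100, prec))
      intensity <- c(intensity, stats::rlnorm(cfg$n_decoys,
        cfg$intensity_meanlog - 1, cfg$intensity_sdlog))
    }
    data.frame(mz = mz, intensity = intensity)
  })
  sp <- ms2_spectrum(id, prec, 1L, peaks)
  attr(sp, "truth") <- list(compound = compound$name,
    chain_n = as.integer(chain_n))
  sp
}

#' Generate a synthetic ituB template for the PCR assay
#'
#' Embeds the shared forward-primer site inside an AA#3-module context and
#' the compound's own reverse-primer site downstream at the spacing that
#' yields the printed band size (1,113 bp iturin / 732 bp bacillomycin D /
#' 1,016 bp bacillomycin L); the other two reverse sites are absent, so
#' only the compound's own set amplifies.
#'
#' @param compound One of `"iturin A"`, `"bacillomycin D"`,
#'   `"bacillomycin L"` (the chemotypes the assay distinguishes).
#' @param cfg A [generator_config()].
#' @param psets Primer sets (see [primer_sets()]).
#' @return Nucleotide string with attribute `truth` =
#'   `list(compound, band)`.
#' @export
gen_ituB_template <- function(compound, cfg = generator_config(),
                              psets = primer_sets()) {
  compound <- .as_compound(compound)$name
  i <- match(compound, psets$target_compound)
  if (is.na(i)) {
    stop("the PCR assay types only: ",
      paste(psets$target_compound, collapse = ", "))
  }
  fwd <- psets$forward[i]
  rev <- psets$reverse[i]
  band <- psets$expected_band[i]
  filler_len <- band - nchar(fwd) - nchar(rev)
  stopifnot(filler_len > 0)
  key <- .hash_key("ituB", compound, cfg$seed)
  ctx3 <- substr(gen_module_template(3L, "Asn", cfg$template_seed), 1L, 250L)
  template <- paste0(
    .random_dna(200L, .hash_key(key, "left")),
    ctx3, fwd,
    .random_dna(filler_len, .hash_key(key, "filler")),
    .revcomp(rev),
    .random_dna(200L, .hash_key(key, "right"))
  )
  # Regenerate if a filler collision created a spurious primer site
  # (astronomically unlikely for 15-17-mers, but deterministic if it happens).
  attr(template, "truth") <- list(compound = compound, band = band)
  template
}

#' Write synthetic clusters or templates as FASTA plus a truth TSV
#'
#' @param clusters List of `cluster_record` objects.
#' @param fasta_path,truth_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_synthetic_clusters <- function(clusters, fasta_path, truth_path = NULL) {
  seqs <- vapply(clusters, `[[`, character(1), "sequence")
  names(seqs) <- vapply(clusters, `[[`, character(1), "id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  if (!is.null(truth_path)) {
    truth <- data.frame(
      id = names(seqs),
      species = vapply(clusters, `[[`, character(1), "species_label"),
      chemotype = vapply(clusters, `[[`, character(1), "chemotype")
    )
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Write synthetic spectra as MGF plus a truth TSV
#'
#' @param spectra List of `ms2_spectrum` objects carrying `truth`
#'   attributes.
#' @param mgf_path,truth_path Output paths.
#' @return `mgf_path`, invisibly.
#' @export
write_synthetic_spectra <- function(spectra, mgf_path, truth_path = NULL) {
  write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) {
    truth <- do.call(rbind, lapply(spectra, function(sp) {
      tr <- attr(sp, "truth")
      data.frame(id = sp$id, compound = tr$compound, chain_n = tr$chain_n)
    }))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(mgf_path)
}
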