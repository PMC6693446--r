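# Module calling, heptapeptide mapping, grouping and sfp detection.

test_that("module calls recover the generator truth at 0% and 5% mutation
          and return unknown on scrambled input", {
  cl0 <- gen_cluster("iturin A", generator_config(seed = 1,
    mutation_rate = 0))
  calls0 <- call_modules(cl0)
  expect_equal(calls0$call,
    c("Asn", "Tyr", "Asn", "Gln", "Pro", "Asn", "Ser"))
  expect_true(all(calls0$identity == 1))
  # footprints coincide with the generator's module spans
  expect_equal(calls0$start, cl0$module_spans$start)
  expect_equal(calls0$end, cl0$module_spans$end)

  cl5 <- gen_cluster("iturin A", generator_config(seed = 1,
    mutation_rate = 0.05))
  calls5 <- call_modules(cl5)
  expect_equal(calls5$call, calls0$call)
  expect_true(all(calls5$identity > 0.9))

  scramble <- random_dna(20000, seed = 99)
  expect_equal(call_modules(scramble)$call, rep("unknown", 7))
})

test_that("reverse-strand clusters are normalized before calling", {
  cl <- gen_cluster("bacillomycin D", generator_config(seed = 2,
    mutation_rate = 0.01))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cl$sequence)))
  calls <- call_modules(rc)
  expect_equal(attr(calls, "strand"), "-")
  expect_equal(as.character(heptapeptide_to_compound(calls)),
    "bacillomycin D")
})

test_that("heptapeptide_to_compound maps registry rows, novel variants and
          non-family peptides", {
  expect_equal(
    heptapeptide_to_compound(c("Asn", "Tyr", "Asn", "Pro", "Glu", "Ser",
      "Thr")),
    "bacillomycin D"
  )
  expect_equal(
    heptapeptide_to_compound(c("Asn", "Tyr", "Asn", "Gln", "Pro", "Asn",
      "Asn")),
    "mojavensin A"
  )
  expect_equal(
    heptapeptide_to_compound(c("Asn", "Tyr", "Asn", "Gln", "Gln", "Gln",
      "Gln")),
    "novel variant"
  )
  expect_equal(heptapeptide_to_compound(rep("Gly", 7)), "not iturinic")
  ind <- heptapeptide_to_compound(c("Asn", "unknown", "Asn", "Gln", "Pro",
    "Asn", "Ser"))
  expect_equal(as.character(ind), "indeterminate")
  expect_match(attr(ind, "reason"), "position")
})

test_that("grouping follows species then similarity: identical sequences
          group, 93% identity splits, species labels split", {
  base <- random_dna(3000, seed = 5)
  rec <- function(id, seq, sp) {
    structure(list(id = id, species_label = sp, sequence = seq,
      chemotype = NA), class = "cluster_record")
  }
  same <- group_clusters(list(
    rec("a", base, "B. velezensis"), rec("b", base, "B. velezensis")))
  expect_equal(same$group, c(1L, 1L))

  mutated <- mutate_exact(base, round(0.07 * nchar(base)), seed = 6)
  expect_equal(oracle_hamming_identity(base, mutated), 0.93,
    tolerance = 0.001)
  split <- group_clusters(list(
    rec("a", base, "B. velezensis"), rec("b", mutated, "B. velezensis")))
  expect_equal(split$group, c(1L, 2L))

  by_species <- group_clusters(list(
    rec("a", base, "B. velezensis"), rec("b", base, "B. siamensis")))
  expect_equal(by_species$group, c(1L, 2L))
})

test_that("grouping equals a brute-force all-pairs identity partition", {
  set.seed(7)
  base <- random_dna(2500, seed = 7)
  seqs <- c(
    list(base),
    lapply(1:4, function(i) mutate_exact(base, 25 * i, seed = 10 + i)),
    lapply(1:3, function(i) {
      mutate_exact(random_dna(2500, seed = 20 + i), 10, seed = 30 + i)
    })
  )
  recs <- lapply(seq_along(seqs), function(i) {
    structure(list(id = paste0("s", i), species_label = "B. velezensis",
      sequence = seqs[[i]], chemotype = NA), class = "cluster_record")
  })
  got <- group_clusters(recs)

  n <- length(seqs)
  edge <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    edge[i, j] <- i != j &&
      oracle_hamming_identity(seqs[[i]], seqs[[j]]) > 0.94
  }
  want <- oracle_components(edge)
  # same partition up to relabeling
  expect_equal(
    as.integer(factor(got$group, levels = unique(got$group))),
    as.integer(factor(want, levels = unique(want)))
  )
})

test_that("a single AA#4 module swap breaks coverage and founds a new
          group, for every compound", {
  cfg <- generator_config(seed = 3, mutation_rate = 0)
  reg <- compound_registry()
  for (cmp in reg$name) {
    cl <- gen_cluster(cmp, cfg)
    own_aa4 <- compound_definition(cmp)$heptapeptide[4]
    other_aa4 <- setdiff(unique(reg$aa4), own_aa4)[1]
    sp4 <- cl$module_spans[4, ]
    swapped <- cl
    swapped$id <- paste0(cl$id, "_swap")
    swapped$sequence <- paste0(
      substr(cl$sequence, 1, sp4$start - 1),
      gen_module_template(4, other_aa4, cfg$template_seed),
      substr(cl$sequence, sp4$end + 1, nchar(cl$sequence))
    )
    swapped$species_label <- cl$species_label
    grp <- group_clusters(list(cl, swapped))
    expect_equal(grp$group, c(1L, 2L), label = cmp)
    pr <- iturityper:::.pair_identity(cl$sequence, swapped$sequence)
    expect_lt(pr$coverage_a, 0.95)
  }
})

test_that("sfp detection: exact copy hits at 100%, random proteomes miss,
          a 30%-mutated copy still passes 40%/70%", {
  ref <- random_protein(220, seed = 42)
  exact <- sfp_present(c(random_protein(180, seed = 1), ref), ref)
  expect_true(exact$present)
  expect_equal(exact$best_identity, 1.0)
  expect_equal(exact$best_index, 2L)

  noise <- sfp_present(
    vapply(1:5, function(i) random_protein(200, seed = 100 + i),
      character(1)),
    ref
  )
  expect_false(noise$present)

  mutated <- mutate_protein(ref, round(0.30 * nchar(ref)), seed = 8)
  hit <- sfp_present(c(mutated), ref)
  expect_true(hit$present)
  expect_gte(hit$best_identity, 0.4)
  expect_gte(hit$best_coverage, 0.7)
})
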