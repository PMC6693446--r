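# Candidate enumeration, peak matching and chemotype assignment.

test_that("candidate_set finds isobars and respects tolerance", {
  # iturin A C14 / mycosubtilin C14 share the precursor exactly
  cands <- candidate_set(1043.55, 1)
  pairs <- paste(cands$compound, cands$chain_n)
  expect_true(all(c("iturin A 14", "mycosubtilin 14") %in% pairs))
  # below the family mass range: empty, not an error
  expect_equal(nrow(candidate_set(500, 1)), 0L)
  # the 14.02 Da ambiguity class: chain +1 vs Ser-to-Thr
  cands <- candidate_set(1057.57, 1)
  pairs <- paste(cands$compound, cands$chain_n)
  expect_setequal(pairs,
    c("iturin A 15", "mycosubtilin 15", "bacillomycin F 14"))
})

test_that("match_peaks: self-match scores 1, the wrong chain misses its
          beta-diagnostic ion, empty spectra score 0", {
  cfg <- match_config()
  noiseless <- generator_config(seed = 1, mz_sigma_ppm = 0, n_decoys = 0)
  sp <- gen_spectrum("bacillomycin D", 14, noiseless)
  own <- match_peaks(sp, diagnostic_table("bacillomycin D", 14), cfg)
  expect_equal(own$score, 1.0)
  expect_true(own$invariant_ok && own$beta_ok)

  wrong_chain <- match_peaks(sp, diagnostic_table("bacillomycin D", 15), cfg)
  expect_false(wrong_chain$beta_ok)
  expect_lt(wrong_chain$score, 1.0)

  empty <- ms2_spectrum("e", 1031.54, 1,
    data.frame(mz = numeric(0), intensity = numeric(0)))
  expect_equal(match_peaks(empty, diagnostic_table("bacillomycin D", 14),
    cfg)$score, 0)
})

test_that("each observed peak is consumed at most once", {
  # two theoretical ions close together, one observed peak: one match only
  tab <- diagnostic_table("iturin A", 14)
  sp <- ms2_spectrum("one-peak", attr(tab, "precursor_mz"), 1,
    data.frame(mz = 278.1135, intensity = 1))
  m <- match_peaks(sp, tab, match_config())
  expect_equal(m$n_matched, 1L)
})

test_that("assignment gates: a spectrum missing the 278.11 head ion is
          unassigned", {
  noiseless <- generator_config(seed = 2, mz_sigma_ppm = 0, n_decoys = 0)
  sp <- gen_spectrum("iturin A", 15, noiseless)
  peaks <- sp$peaks[abs(sp$peaks$mz - 278.1135) > 0.01, ]
  crippled <- ms2_spectrum(sp$id, sp$precursor_mz, 1, peaks)
  a <- assign_chemotype(crippled)
  expect_equal(a$compound, "unassigned")
  expect_match(a$reason, "invariant")
})

test_that("precursor-less spectra are rejected with a clear error", {
  sp <- ms2_spectrum("nope", NA_real_, 1,
    data.frame(mz = 278.11, intensity = 1))
  expect_error(assign_chemotype(sp), "no precursor")
})

test_that("noiseless isobar discrimination: iturin A vs mycosubtilin
          tables differ in >= 2 ions and the truth always wins", {
  t_itu <- diagnostic_table("iturin A", 14)
  t_myc <- diagnostic_table("mycosubtilin", 14)
  in_other <- vapply(t_itu$mz[t_itu$series != "precursor"], function(m) {
    any(abs(t_myc$mz - m) < 1e-4)
  }, logical(1))
  expect_gte(sum(!in_other), 2L)

  noiseless <- generator_config(seed = 3, mz_sigma_ppm = 0, n_decoys = 0)
  for (truth in c("iturin A", "mycosubtilin")) {
    a <- assign_chemotype(gen_spectrum(truth, 14, noiseless))
    expect_equal(a$compound, truth)
    expect_equal(a$chain_n, 14L)
  }
})

test_that("the bacillomycin F C14 / iturin A C15 isobar is resolved by the
          beta-diagnostic ion", {
  noiseless <- generator_config(seed = 4, mz_sigma_ppm = 0, n_decoys = 0)
  a <- assign_chemotype(gen_spectrum("bacillomycin F", 14, noiseless))
  expect_equal(a$compound, "bacillomycin F")
  expect_equal(a$chain_n, 14L)
  beta_hits <- a$matched_ions[a$matched_ions$series == "beta_diagnostic", ]
  expect_equal(round(beta_hits$mz, 2), 184.21)

  b <- assign_chemotype(gen_spectrum("iturin A", 15, noiseless))
  expect_equal(b$compound, "iturin A")
  expect_equal(b$chain_n, 15L)
})

test_that("assignment under default noise recovers the truth and is
          deterministic", {
  for (cmp in c("iturin A", "bacillomycin L", "mojavensin A")) {
    for (s in 1:3) {
      sp <- gen_spectrum(cmp, 15, generator_config(seed = s))
      a1 <- assign_chemotype(sp)
      a2 <- assign_chemotype(sp)
      expect_equal(a1$compound, cmp, label = sprintf("%s seed %d", cmp, s))
      expect_equal(a1$chain_n, 15L)
      expect_identical(a1, a2) # same spectrum + config => same assignment
    }
  }
})

test_that("MGF files round-trip spectra including precursor-less entries", {
  spectra <- list(
    gen_spectrum("iturin A", 14, generator_config(seed = 1)),
    ms2_spectrum("no-precursor", NA_real_, 1,
      data.frame(mz = c(100.1, 200.2), intensity = c(5, 1)))
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$id, spectra[[1]]$id)
  expect_equal(back[[1]]$peaks$mz, spectra[[1]]$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$precursor_mz, spectra[[1]]$precursor_mz,
    tolerance = 1e-6)
  expect_true(is.na(back[[2]]$precursor_mz))
  expect_error(read_mgf(withr::local_tempfile(lines = "BEGIN IONS")),
    "malformed MGF")
})
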