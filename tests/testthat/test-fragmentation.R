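# Ring openings, b/y series and diagnostic tables.

test_that("ring opening is a rotation that preserves the residue multiset", {
  for (site in 1:8) {
    op <- open_ring("mycosubtilin", 15, site)
    expect_equal(sort(op$units$label),
      sort(c(compound_definition("mycosubtilin")$heptapeptide, "C15")),
      label = sprintf("site %d", site))
    # linear order starts right after the broken bond
    expect_equal(op$units$position[1], site %% 8 + 1)
  }
  expect_error(open_ring("iturin A", 14, 0), "1..8")
  expect_error(open_ring("iturin A", 14, 9), "1..8")
})

test_that("tail opening linearizes AA#1..AA#7 then the lipid; proline
          opening starts at the proline", {
  tail_op <- open_ring("iturin A", 14, 8)
  expect_equal(tail_op$units$label,
    c("Asn", "Tyr", "Asn", "Gln", "Pro", "Asn", "Ser", "C14"))
  pro_op <- open_ring("iturin A", 14, 4)
  expect_equal(pro_op$units$label,
    c("Pro", "Asn", "Ser", "C14", "Asn", "Tyr", "Asn", "Gln"))
})

test_that("tail-opening b2/b3 reproduce the conserved-head ions", {
  ions <- b_y_series(open_ring("bacillomycin L", 16, 8))
  b <- ions[ions$series == "b", ]
  expect_equal(round(b$mz[b$k == 2], 2), 278.11)
  expect_equal(round(b$mz[b$k == 3], 2), 392.16) # printed as 392.15
  expect_equal(b$composition[b$k == 2], "Asn-Tyr")
})

test_that("b/y complementarity: b7 + y1 = [M+H]+ + proton + water", {
  k <- mass_constants()
  for (cmp in c("iturin A", "bacillomycin D")) {
    ions <- b_y_series(open_ring(cmp, 14, 8))
    b7 <- ions$mz[ions$series == "b" & ions$k == 7]
    y1 <- ions$mz[ions$series == "y" & ions$k == 1]
    expect_equal(
      b7 + y1,
      protonated_mz(cyclic_parent_mass(cmp, 14)) + k[["proton"]] +
        k[["water"]],
      tolerance = 1e-6, label = cmp
    )
  }
})

test_that("beta-diagnostic ions give 184.21 (C14), 198.22 (C15), 212.24
          (C16) and step by one methylene", {
  expect_equal(round(beta_diagnostic_ion(14)$mz, 2), 184.21) # printed 184.20
  expect_equal(round(beta_diagnostic_ion(15)$mz, 2), 198.22)
  expect_equal(round(beta_diagnostic_ion(16)$mz, 2), 212.24)
  mzs <- vapply(13:18, function(n) beta_diagnostic_ion(n)$mz, numeric(1))
  expect_equal(diff(mzs), rep(mass_constants()[["methylene"]], 5),
    tolerance = 1e-6)
})

test_that("the invariant ion trio is identical across all compounds and
          chain lengths", {
  ref <- NULL
  for (cmp in compound_registry()$name) {
    for (n in c(13L, 15L, 18L)) {
      tab <- diagnostic_table(cmp, n)
      trio <- sort(tab$mz[tab$is_invariant])
      expect_length(trio, 3L)
      if (is.null(ref)) ref <- trio
      expect_equal(trio, ref, tolerance = 1e-4,
        label = sprintf("%s C%d", cmp, n))
    }
  }
  expect_equal(round(ref, 2), c(136.08, 278.11, 392.16))
  expect_equal(round(ref[1], 3), 136.076)
})

test_that("diagnostic tables contain the four quoted ions, deduplicate at
          1e-4 Da, and match a brute-force enumeration", {
  reg <- compound_registry()
  for (i in seq_len(nrow(reg))) {
    cmp <- reg$name[i]
    tab <- diagnostic_table(cmp, 14)
    ions <- tab[tab$series != "precursor", ]
    # contains the printed masses
    for (target in c(278.11, 392.16, 136.08, 184.21)) {
      expect_true(any(abs(round(ions$mz, 2) - target) < 0.005),
        label = sprintf("%s: ion %.2f", cmp, target))
    }
    # deduplicated at 1e-4
    expect_true(all(diff(sort(ions$mz)) > 1e-4), label = cmp)
    # same unique m/z set as the independent enumerator
    hepta <- unlist(reg[i, paste0("aa", 1:7)])
    oracle <- oracle_fragment_mzs(hepta, reg$proline_position[i], 14)
    expect_equal(length(oracle), nrow(ions), label = cmp)
    expect_equal(sort(ions$mz), oracle, tolerance = 5e-4, label = cmp)
  }
})

test_that("bacillomycin L, lacking proline, has no proline-opening series
          and hence fewer ions", {
  bacl <- diagnostic_table("bacillomycin L", 15)
  expect_false(any(bacl$opening == "proline", na.rm = TRUE))
  itu <- diagnostic_table("iturin A", 15)
  expect_true(any(itu$opening == "proline", na.rm = TRUE))
  expect_lt(nrow(bacl), nrow(itu))
})

test_that("every b ion lies below the precursor m/z", {
  for (cmp in compound_registry()$name) {
    tab <- diagnostic_table(cmp, 17)
    b <- tab$mz[tab$series == "b"]
    expect_true(all(b < attr(tab, "precursor_mz")), label = cmp)
  }
})

test_that("neutral-loss satellites appear only on request", {
  plain <- diagnostic_table(compound_definition("iturin A"), beta_acyl(14))
  with_losses <- diagnostic_table(compound_definition("iturin A"),
    beta_acyl(14), neutral_losses = TRUE)
  expect_gt(nrow(with_losses), nrow(plain))
  expect_true(any(grepl("_loss", with_losses$series)))
  expect_false(any(grepl("_loss", plain$series)))
})

test_that("fragment tables survive a TSV round trip", {
  tab <- diagnostic_table("mojavensin A", 16)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(tab, path)
  back <- read_fragment_table(path)
  expect_equal(back$mz, tab$mz, tolerance = 1e-9)
  expect_equal(back$series, tab$series)
  expect_equal(attr(back, "compound"), "mojavensin A")
  expect_equal(attr(back, "chain_n"), 16L)
  expect_equal(unclass(back$positions), unclass(tab$positions))
})
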