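Package: iturityper
Title: Typing of Iturinic Lipopeptides from Gene Clusters, Tandem Mass
    Spectra and Diagnostic PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification of the six iturinic lipopeptides (iturin A,
    mycosubtilin, bacillomycins D, F and L, and mojavensin A) produced by
    members of the Bacillus subtilis species group. Provides monoisotopic
    mass arithmetic and a registry of the family's cyclic heptapeptides;
    enumeration of theoretical MS/MS fragment ions through the family's two
    ring-opening pathways and assignment of compound and beta-amino fatty
    acid chain length to observed spectra; calling of the seven
    non-ribosomal peptide synthetase modules from nucleotide cluster
    sequences with mapping of the inferred heptapeptide to a chemotype,
    similarity-based grouping of clusters and detection of the sfp
    activation gene; in-silico PCR prediction for the three Bacillus
    velezensis ituB primer sets with band-size classification; and a seeded
    synthetic-data generator producing clusters, ituB templates and MS/MS
    peak lists so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
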