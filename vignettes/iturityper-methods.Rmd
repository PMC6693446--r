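---
title: "Typing iturinic lipopeptides: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing iturinic lipopeptides: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iturityper)
```

This vignette documents the science and the engineering decisions behind
`iturityper`: the mass model, the fragmentation model, the sequence-typing
model, the PCR model, the synthetic-data generator that stands in for real
genomes and spectra, and the numerical choices each stage makes.

## The compound family and the mass model

The six iturinic lipopeptides are cyclic heptapeptides closed through a
β-amino fatty-acid residue (C~n~H~2n-1~NO as incorporated, n = 13–18).
The registry shipped in `inst/extdata/compound_registry.tsv` records each
compound's heptapeptide, proline position and reported producers:

```{r}
compound_registry()[, c("name", paste0("aa", 1:7), "proline_position")]
```

Positions AA#1–AA#3 are the conserved Asn-Tyr-Asn head; AA#4–AA#7 define
the chemotype. Two transcription decisions deserve a note. First, some
older structural literature gives Asp at AA#1 for the bacillomycins; the
registry uses Asn for all six compounds, the consensus this package
follows, and a user who disagrees can point `compound_registry(path =)` at
an edited table. Second, mojavensin A's heptapeptide equals that of
paenilarvin; the registry keeps one row under the mojavensin name.

Masses are monoisotopic throughout, built from IUPAC atomic masses with at
least five decimals, with the proton at 1.007276 Da (the hydrogen atom
minus an electron — using 1.00794 or 1.00783 would shift every printed
comparison). The cyclic parent is a pure residue sum: no terminal water,
because the macrocycle is closed by an amide bond. Two family-level
identities are worth internalizing, because they are the whole reason
MS-based typing is delicate:

* iturin A and mycosubtilin have identical residue multisets, hence
  identical parent masses at every chain length (exact isobars);
* a chain-length step (+CH~2~, 14.0157 Da) equals a Ser→Thr substitution,
  so e.g. bacillomycin F (C14) and iturin A (C15) share a precursor.

Stereochemistry (D-/L-) and iso/anteiso branching of the alkyl tail carry
no mass and are not modelled; only the nature of the cyclic peptide and
the chain length are represented.

A note on printed reference values: the exact b3 (Asn-Tyr-Asn) ion is
392.1565 and the C14 chain-length ion is 184.2060. Reference listings that
truncate rather than round show 392.15 and 184.20; this package computes
and reports the exact values, rounded half-even when a comparison at a
stated precision is needed, and treats one unit in the last printed digit
as agreement when a source value is evidently truncated.

## Fragmentation model

Collision-induced fragmentation of the macrocycle proceeds through two
dominant ring openings: between the lipid tail and AA#1 (the "tail"
opening, giving the linear order AA#1..AA#7-tail), and at the amide bond
N-terminal to the proline (absent in bacillomycin L, which consequently
has a more uniform fragmentation pattern). The proline-side cleavage is
modelled N-terminal to Pro, the standard CID preference. Each opening is a
rotation of the 8-unit cycle; `open_ring()` exposes all 8 bonds, and
`diagnostic_table()` uses the two chemically dominant ones.

For each opening, b~k~ ions are the first k residue masses plus a proton
and y~k~ ions the last k plus water plus a proton, k = 1..7 (the k = 8 ion
is the opened precursor). Only singly charged fragments are generated —
the diagnostic ions are all 1+ in practice — and neutral-loss satellites
(−NH~3~, −H~2~O) are off by default behind the `neutral_losses` flag,
since assignments rest on the plain series. Tables are deduplicated at
1e-4 Da and sorted.

Three ions are invariant across all six compounds and all chain lengths
because they contain no tail and only conserved residues: b2 (278.1135),
b3 (392.1565) and the Tyr immonium-type ion (136.0757, modelled as residue
− CO + proton; it arises from double backbone fragmentation of the
tyrosine). The chain length is read from the ketene-loss ion of the
β-residue (C14 → 184.206, one methylene per chain step). Intensities are
never predicted: collision-energy settings are acquisition parameters, not
observables this model computes.

## Spectrum matching

`assign_chemotype()` mechanizes manual interpretation. Candidates are all
registry × chain combinations whose [M+zH]^z+^ matches the precursor
within tolerance — isobars included by construction. Each candidate table
is matched greedily in m/z order, nearest unused peak within tolerance;
the score is the matched fraction of the candidate's fragment ions.

Defaults (all configurable through `match_config()`):

| parameter | default | rationale |
|---|---|---|
| fragment tolerance | 10 ppm, 0.01 Da floor | Orbitrap-scale accuracy; the floor keeps low-mass windows realistic |
| precursor tolerance | 10 ppm | same instrument class |
| `min_variable_ions` | 2 | at least two AA#4–AA#7 ions so isomers are separated by evidence, not by score noise |
| `ambiguity_margin` | 0.05 | runner-ups within 0.05 score are reported, not hidden |

A call additionally requires all three invariant ions and the
β-diagnostic ion. Spectra failing a gate are `"unassigned"` with a reason,
never a low-confidence guess. At an exact score tie the match with more
variable-region ions (then alphabetical order) is ranked first and the tie
is visible in `ambiguous_with` — reporting ambiguity is preferred over
silent tie-breaking because low-information spectra are exactly where
misassignment historically happened. There were no published thresholds to
adopt for these four parameters; the defaults above are this package's
stated choices.

MGF is read and written by a small built-in parser (TITLE/PEPMASS/CHARGE
headers, whitespace peak lines); no installed R package parses MGF peak
lists, and the format is simple enough that a dependency would not pay for
itself. mzML support was deliberately left out.

## Cluster typing

The biosynthetic cluster has four genes; the seven ~1,000-amino-acid
modules are distributed 1/4/2 across genes 2–4, and a module swap changes
3–4 kb of nucleotide sequence. Typing therefore reduces to locating each
module and asking which (position, residue) reference it most resembles.

`call_modules()` uses a self-contained anchored search rather than an
external aligner: exact 21-mer seeds are sampled across each reference,
matched in the cluster, and vote on an offset; a consistent offset is
followed by direct base comparison over the reference footprint, and an
inconsistent one (indels) falls back to a banded dynamic-programming
alignment of the anchored window. A 21-mer balances specificity (a random
hit in a 25 kb cluster has probability ≈ 2.5e-9) against mutation
tolerance (at 5% divergence a seed survives with probability 0.34, and
40 seeds give ample support). Calls below 50% identity become
`"unknown"`; random sequence scores ≈ 25% and never crosses that floor.
Reverse-strand input is detected with the conserved module-1 reference and
normalized first. Coordinates in reports are 1-based closed intervals, the
R/Bioconductor convention.

`group_clusters()` implements within-species single linkage: an edge
requires pairwise identity > 0.94 **and** mutual coverage ≥ 0.95. The
identity threshold is the family's published grouping rule; the coverage
quantifier for "full alignment length" is this package's choice (no number
was published) and is configurable. Coverage is computed from maximal runs
of consistent anchor offset, with the outer runs extended at most three
seed steps toward the ends — enough to absorb anchor thinning from
mutations, but a genuinely divergent end or a swapped module (~3 kb with
no anchors) stays uncovered, which is what makes "one module swap founds a
new group" a structural consequence rather than a tuned outcome. The >90%
cross-species confidence rule for labelling unverified groups is exposed
as a secondary threshold, not applied silently.

`sfp_present()` does protein-level presence/absence with Smith-Waterman
(BLOSUM62, gap open 10/extend 0.5): present means ≥ 40% identity over
≥ 70% of the reference. Those two numbers are conservative choices for
"recognizable homolog", made here, not published values.

## In-silico PCR

The three primer sets share the forward primer
`CACGAACAGACAAAACA` (conserved AA#3 module); the reverse primers sit on
the variable AA#4 module and give bands of 1,113 / 732 / 1,016 bp.
`find_amplicons()` matches primers on both orientations (a template and
its reverse complement give identical products), allows `max_mismatch`
mismatches per primer — default 0, because the assay was validated on
exact-matching strains — but never in the three 3′-terminal bases, and
drops products over 5 kb. `classify_by_band()` reads the virtual gel:
exactly one set within ±10% of its expected band (agarose resolution)
calls that set's compound; zero is `"no product"`, several `"ambiguous"`.
The assay is validated only for *B. velezensis*; passing any other
`species_label` triggers a warning rather than a refusal.

`estimate_tm()` implements unified nearest-neighbor thermodynamics
(ΔH/ΔS per dinucleotide, terminal initiation terms, entropic salt
correction 0.368 (N−1) ln[Na⁺], CT/4 concentration term) at 50 mM Na⁺ and
0.5 µM oligo. Absolute Tm values are notoriously method-dependent — the
shipped primers evaluate to roughly 48–53 °C under this model, while
their design target was 55 ± 2 °C under the designers' software — so the
function documents its constants and the tests pin it against an
independent implementation of the same parameter set, not against the
design target.

## The synthetic-data generator

The generator exists so that every stage is testable offline, and its
defaults are the study conditions the tests assume:

* **Clusters** (`gen_cluster()`): 4 genes, modules 1/4/2 on genes 2–4,
  ~3 kb pseudo-random module templates keyed by (position, residue,
  `template_seed`), 150 nt spacers, 300 nt flanks, a 1.2 kb non-modular
  first gene. The non-modular scaffold is shared across all clusters of a
  template panel, since homologous clusters differ by variable modules
  and strain-level mutations, not by their backbone. Default substitution
  rate 3% per site — realistic within-species divergence, and the highest
  rate at which typing is expected to stay perfect. Substitutions only by
  default; an `indels` flag exercises the coverage logic.
* **Spectra** (`gen_spectrum()`): every table ion with Gaussian 5 ppm m/z
  jitter, log-normal intensities, 50 uniform decoys in [100, precursor],
  precursor at the exact theoretical [M+H]⁺. Decoy positions are
  independent of the compound, so nothing outside the declared truth
  labels leaks the answer.
* **PCR templates** (`gen_ituB_template()`): forward site in an
  AA#3-module context, the compound's own reverse site at exactly the
  printed band spacing, the other reverse sites absent.

Everything is deterministic in (key, seed); changing only the seed changes
sequences and noise but never truth labels. What the generator does *not*
emulate: codon structure and NRPS domain grammar (module identity is
pseudo-random sequence, not biology), intergenic content beyond short
spacers, isotope envelopes, charge states above 1+, chimeric or
contaminated spectra, and real strain-to-strain indel structure. Passing
tests therefore demonstrate that the algorithms are correct under the
family's documented structure and realistic noise — not that the specific
thresholds are optimal for any particular instrument or sequencing
pipeline.

## Test design and problem sizes

The suite checks values against independent oracles (hand-typed residue
masses, a brute-force fragment enumerator, direct Hamming identity and an
independent connected-components pass), and properties as round trips
through the generator. The headline experiments run at sizes chosen to
make the statistics meaningful while keeping the suite quick to iterate
on: spectrum recovery uses 100 seeded replicates per (compound, chain)
over chains 14–17 with the default noise model, plus a noiseless sweep
that must be perfect; cluster typing uses 10 seeds per compound at 3%
mutation; grouping is compared against brute force on batches of ≤ 10
sequences; the PCR round trip runs 5 seeds per chemotype.

## Known limitations

* The registry is the closed world: a genuinely novel heptapeptide is
  reported as `"novel variant"`, never structurally elucidated.
* Module boundaries are reference footprints, not NRPS domain grammar;
  on real genes the footprint edges are approximate.
* Spectrum scoring is presence/absence; intensity information is carried
  but unused, which discards some real-world evidence.
* The anchored identity estimate assumes mostly-collinear homology; it is
  not a general-purpose aligner and will under-cover heavily rearranged
  sequences (which, for this grouping rule, is the conservative
  direction).
* Database-scale results — compound inventories across hundreds of
  genomes, phylogenies, average nucleotide identity tables — require
  external genome downloads and are out of scope; the package provides
  the per-cluster machinery such a survey would run.
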