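# iturityper

Strains of the *Bacillus subtilis* species group are workhorse biocontrol
agents largely because they secrete iturinic lipopeptides — cyclic
heptapeptides carrying a β-amino fatty-acid tail — that punch pores into
fungal membranes. The family has six members (iturin A, mycosubtilin,
bacillomycin D, bacillomycin F, bacillomycin L, mojavensin A) that share a
conserved Asn-Tyr-Asn head (positions AA#1–AA#3) and differ only at the
variable positions AA#4–AA#7 and in the tail length (C13–C18). Telling
them apart matters — strain registration, product labelling and
resistance-management all hinge on which compound a strain makes — but it
is genuinely hard: iturin A and mycosubtilin are exact sequence isomers,
and a one-methylene chain step (+14.02 Da) is isobaric with a Ser→Thr
substitution, so parent masses alone routinely mislead.

`iturityper` identifies the compound three independent ways:

1. **Gene clusters.** The compounds are made by a 4-gene NRPS cluster with
   7 modules (distributed 1/4/2 over genes 2–4), one module per residue.
   `call_modules()` locates each module by similarity against a reference
   panel, `heptapeptide_to_compound()` maps the inferred heptapeptide to a
   chemotype, `group_clusters()` partitions clusters within a species by
   >94 % nucleotide identity over the full alignment length, and
   `sfp_present()` checks for the 4′-phosphopantetheinyl transferase
   required for NRPS activation.
2. **Tandem mass spectra.** The macrocycle opens along two dominant
   pathways — between the lipid tail and AA#1, or N-terminal to the
   proline — and the resulting linear peptides fragment into b/y series.
   `diagnostic_table()` enumerates the theoretical ions, including the
   invariant trio (b2 Asn-Tyr at *m/z* 278.11, b3 Asn-Tyr-Asn at 392.16,
   the Tyr immonium-type ion at 136.076) and the chain-length diagnostic
   ion from the 42.01 Da ketene loss (C14 → 184.21, C15 → 198.22).
   `assign_chemotype()` mechanizes spectrum interpretation: a call needs
   the invariant trio, the β-diagnostic ion, and variable-region ions.
3. **Diagnostic PCR.** For *B. velezensis*, three primer sets sharing one
   forward primer on the conserved AA#3 module yield bands of ~1,113 bp
   (iturin), ~732 bp (bacillomycin D) or ~1,016 bp (bacillomycin L);
   `find_amplicons()` and `classify_by_band()` predict and read the gel.

A seeded generator (`gen_cluster()`, `gen_spectrum()`,
`gen_ituB_template()`) produces synthetic clusters, spectra and templates
with exactly this structure, so the whole pipeline is testable offline.

## Worked example

```r
library(iturityper)

## the family-wide diagnostic ions for iturin A with a C14 tail
tab <- diagnostic_table("iturin A", 14)
round(sort(tab$mz[tab$is_invariant | tab$series == "beta_diagnostic"]), 3)
#> [1] 136.076 184.206 278.114 392.156

## a noisy synthetic spectrum of bacillomycin F (C14): its precursor is
## isobaric with iturin A (C15), but the 184.21 beta-diagnostic ion
## resolves the 14.02 Da ambiguity
sp <- gen_spectrum("bacillomycin F", 14, generator_config(seed = 42))
assign_chemotype(sp)
#> bacillomycin F, C14 chain (score 1.000, 30 ions matched)

## type a synthetic NRPS cluster (3% per-site mutations) from sequence
cl <- gen_cluster("bacillomycin D", generator_config(seed = 7))
heptapeptide_to_compound(call_modules(cl))
#> [1] "bacillomycin D"

## read the PCR assay on a synthetic ituB template
tpl <- gen_ituB_template("bacillomycin L", generator_config(seed = 3))
classify_by_band(tpl)
#> PCR call: bacillomycin L
#>         set length expected_band in_band
#> 1 ituB-bacL   1016          1016    TRUE
```

The first block prints the four masses every assignment rests on: the
three tail-independent head ions shared by all six compounds and the
C14 chain-length ion. The spectrum call shows all 30 theoretical ions of
the true compound matched (score 1.0); the cluster call shows the module
path recovering the heptapeptide despite mutations; the PCR call shows the
1,016 bp band that identifies a bacillomycin L producer on a gel.

File-level pipelines (`type_clusters()`, `assign_spectra()`,
`pcr_type()`) take FASTA/MGF in and write TSV reports;
`inst/scripts/itupipe.R` wraps them for shell use, including a `simulate`
subcommand that writes a full synthetic batch.

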