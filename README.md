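# pgtsma

Computational workflow for microsatellite-panel-based preimplantation
genetic testing (PGT-M) of spinal muscular atrophy (SMA).

SMA is caused by homozygous loss of *SMN1*, which sits in a ~1.7 Mb
duplicated region on chromosome 5q13.2 together with its near-identical
paralog *SMN2*. Direct single-cell assays can only detect presence or
absence of *SMN1* and are vulnerable to allele dropout (ADO) after
whole-genome amplification (WGA). A panel of 13 highly polymorphic
microsatellite markers closely flanking the duplicon (six upstream, seven
downstream) makes an indirect, ADO-tolerant linkage diagnosis possible:
phase each parent's mutant (*SMN1*-deleted) and wild-type haplotype from an
affected reference, then decide which haplotypes each embryo inherited.

`pgtsma` implements that workflow end to end, for pipeline developers and
method evaluators rather than for clinical use:

* **Repeat mining** — di- to penta-nucleotide tandem-repeat discovery with
  wraparound dynamic-programming alignment scores (match/mismatch/indel
  weights +2/−7/−7) and the strict filters `percent match > 80` and motif
  length-specific score thresholds `> 54/80/66/52`; flanking-window
  selection around the duplicon.
* **Population statistics** — expected/observed heterozygosity
  (`He = 1 − Σ pᵢ²`, `Ho = n_het / n_typed`) and panel informativeness
  profiles (fraction of individuals heterozygous for ≥ k markers, total and
  per side).
* **Trio phasing** — Mendelian assignment of each parent's mutant-linked and
  wild-linked allele from an affected child (both alleles of the affected
  reference tag the two parental *SMN1*-deleted chromosomes), with explicit
  ambiguity and inconsistency statuses, and an embryo-based variant that
  guards against ADO.
* **Embryo diagnosis** — a direct *SMN1* call from triplex minisequencing
  signals (e7/i7/e8, triple redundancy with an SMN2 amplification control),
  contamination screening, scoring of the four inheritance hypotheses with
  per-marker support/ADO-compatible/conflict classification, a conservative
  ≥ 2-supporting-markers-per-side call rule, and a direct/indirect
  concordance policy.
* **ADO QC** — per-marker allele-dropout and amplification-failure rates
  from replicate single cells with known truth genotypes.
* **Synthetic data** — seeded generators for Hardy–Weinberg cohorts,
  carrier×carrier trios with an affected child, embryo meioses with a
  Haldane recombination model (~1 cM/Mb), and single-cell WGA artifacts
  (per-allele dropout, locus/cell failure, contamination), so the whole
  pipeline is testable without any external data.

The default `sma_panel()` carries the 13 marker names, motifs, amplicon
size ranges, and published Chinese/Caucasian heterozygosities; base-pair
positions are synthetic placements consistent with the published map (the
markers' Haldane recombination risk with *SMN1* stays below 2% upstream and
1% downstream at 1 cM/Mb).

## Worked example

```r
library(pgtsma)

panel <- sma_panel()
freqs <- default_allele_frequencies(panel, "chinese")

# a carrier x carrier trio with an affected child, and the parents'
# genomic-DNA genotypes
trio   <- simulate_trio(panel, freqs, seed = 7)
father <- parental_genotype(trio$father, "father", "father")
mother <- parental_genotype(trio$mother, "mother", "mother")

# phase each parent's mutant-linked / wild-linked allele per marker
phased <- phase_trio(father, mother, trio$child, panel)
head(phased, 4)
#>    marker parent mutant_allele wild_allele                   status possible_ado
#> 1 D5S1417 father           208         206                 assigned        FALSE
#> 2 D5S1417 mother           214         206                 assigned        FALSE
#> 3 D5S1413 father           143         143 uninformative_for_parent        FALSE
#> 4 D5S1413 mother           143         149                 assigned        FALSE
```

Each `assigned` row names the allele riding on that parent's
*SMN1*-deleted chromosome (`mutant_allele`) and on the wild-type one.
For this trio, 19 of the 26 parent-marker combinations phase to
`assigned`; the rest are homozygous in that parent and carry no linkage
information.

```r
# five embryos through meiosis, WGA artifacts, and both assays
params  <- sim_params(p_ado = 0.2, p_locus_fail = 0.05, p_cell_fail = 0)
embryos <- simulate_embryos(trio$father, trio$mother, panel, 5, params, seed = 8)
for (i in seq_along(embryos)) {
  e   <- embryos[[i]]
  obs <- apply_wga_artifacts(e$genotype, params, seed = 100 + i)
  sig <- simulate_minisequencing_signals(e$truth$smn1_copies,
                                         e$truth$smn2_copies, params,
                                         seed = 200 + i)
  rep <- diagnose_embryo(obs, sig, phased, father, mother, panel)
  cat(sprintf("%s: %s (direct %s, indirect %s)\n", e$genotype$sample_id,
              rep$final_status, rep$direct_call, rep$indirect_status))
}
#> E001: unaffected (direct SMN1_PRESENT, indirect unaffected)
#> E002: carrier_paternal (direct SMN1_PRESENT, indirect carrier_paternal)
#> E003: inconclusive (direct SMN1_PRESENT, indirect inconclusive)
#> E004: carrier_paternal (direct SMN1_PRESENT, indirect carrier_paternal)
#> E005: unaffected (direct SMN1_PRESENT, indirect unaffected)
```

All five embryos inherited at least one wild-type haplotype, matching the
direct calls. Embryo `E003` lost too many markers to dropout to reach the
required two fully supporting markers on each side of the duplicon, so it
is reported `inconclusive` rather than guessed — under heavy artifact
loads the pipeline trades conclusiveness for safety, never accuracy.

The same stages are scriptable through `run_pipeline()` (subcommands
`simulate`, `mine`, `stats`, `phase`, `diagnose`, `qc`) or the thin
wrapper `inst/scripts/pgtsma.R`.

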