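---
title: "Methods: marker-based PGT-M of SMA in pgtsma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based PGT-M of SMA in pgtsma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtsma)
```

# The diagnostic problem

Spinal muscular atrophy is recessive: an embryo is affected only if it
inherits an *SMN1*-deleted chromosome from both parents. Because *SMN1*
lies inside a ~1.7 Mb duplicon shared with the near-identical *SMN2*,
markers inside the region are duplicated and useless for linkage, and a
direct single-cell *SMN1* assay sees only presence/absence — it cannot
separate carriers from non-carriers, and a dropout of the *SMN1* signal
mimics an affected genotype. `pgtsma` implements the two complementary
assays and the logic that combines them:

* an **indirect** test: 13 single-copy microsatellites flanking the
  duplicon are phased onto each parent's mutant and wild-type chromosome
  using an affected reference, and each embryo's inherited haplotypes are
  inferred from its marker genotypes;
* a **direct** test: triplex minisequencing of three paralog-discriminating
  sites (exon 7, intron 7, exon 8), giving three independent chances to
  see *SMN1* and a three-signal *SMN2* amplification control.

# Phasing model

For every marker, both alleles carried by an affected reference are, by
definition of its genotype, linked to the two parental *SMN1*-deleted
chromosomes. `phase_trio()` performs the Mendelian deduction per marker:

* each child allele is attributed to the parent(s) that carry it; if the
  attribution is unique, the attributed allele is that parent's
  mutant-linked allele and the parent's other allele its wild-linked one;
* if the child is heterozygous and both parents carry both child alleles,
  the marker is `ambiguous` — it is kept in the output so that diagnosis
  can ignore it explicitly; ties are never silently resolved;
* a child allele carried by neither parent marks the marker
  `inconsistent`, and inconsistent markers never contribute to diagnosis;
* a homozygous parent is `uninformative_for_parent`: its contributed
  allele is known, but which chromosome carried it is not — such markers
  still constrain the expected embryo genotype through the *other*
  parent.

The trio workflow assumes a genomic-DNA reference (no dropout). When the
reference is itself a single-cell observation (an affected embryo
identified by the direct assay), `phase_from_affected_embryo()` applies
the same deduction but refuses to assign any marker where the embryo
shows a single allele while either parent is heterozygous: a second,
dropped allele cannot be excluded, so the marker is flagged
`possible_ado` and left ambiguous. This costs information but can never
phase a marker wrongly from a dropout; with per-allele dropout at 0.2 the
assigned markers are correct in >99% of simulated replicates (in our
simulations, errors would require coincidences the single-flag guard
already excludes).

Marker informativeness follows the transmission-resolution view:
*fully* informative means both parents heterozygous with different allele
pairs (then every possible child genotype identifies both transmitted
chromosomes — verified by exhaustive enumeration in the test suite);
exactly one heterozygous parent, or identical heterozygous pairs, is
*partially* informative; two homozygous parents are *uninformative*.

# Embryo diagnosis

`score_haplotype_hypotheses()` evaluates the four inheritance hypotheses
(paternal mutant/wild × maternal mutant/wild). For each usable marker
(phase assigned or parent-homozygous for both parents, not
possible-ADO, at least one observed allele), the observation is:

* **supporting** — observed alleles equal the expected pair exactly;
* **ADO-compatible** — a non-empty strict subset of the expected pair
  (consistent, but one allele may have dropped);
* **conflicting** — any observed allele the hypothesis cannot explain.

`call_embryo()` selects the unique hypothesis with zero conflicts and
demands at least two *supporting* (not merely ADO-compatible) markers on
each side of the duplicon (`min_support_per_side`, default 2,
configurable). The per-side requirement protects against an undetected
recombination between the markers of one side and the gene; the
strictness (ADO-compatible does not count) means a call is only made on
markers observed in full. Consequences of this choice, measured in the
acceptance simulations at per-allele dropout 0.2 and locus-failure 0.05:
no wrong status in 10,000 embryos, at the price of roughly 2% of embryos
being reported inconclusive (the binomial tail of having fewer than two
fully observed supporting markers among the six upstream markers is the
dominant term). Dropout moves embryos only from conclusive to
inconclusive, never to a wrong call, and the suite checks this
monotonicity directly.

Degenerate inputs are handled explicitly: if no marker is phase-assigned
at all, scoring signals an error rather than returning an empty table;
if several hypotheses are conflict-free (e.g. an embryo homozygous
everywhere for alleles shared by both parents), the call is inconclusive.
When *no* hypothesis is conflict-free, the caller checks whether flipping
one parent's haplotype on a contiguous distal segment of one side would
explain all conflicts; if so the embryo is reported inconclusive with
`recombination_suspected`. Suspected recombinants are deliberately not
re-phased: a recombinant chromosome's gene status is exactly what the
distal markers no longer attest to, so a conservative refusal is the only
safe output.

Contamination screening is independent of phase: more than two alleles at
a marker, or any allele outside the union of the parental alleles, raises
the flag; a flagged embryo is reported inconclusive outright. The direct
call (`call_direct_smn1()`) returns `SMN1_PRESENT` on any surviving
SMN1-specific signal, `SMN1_ABSENT` only when all three SMN1 signals are
absent *and* all three SMN2 signals are present, and `INCONCLUSIVE`
otherwise — a sample genuinely lacking *SMN2* can therefore never produce
an ABSENT call; such samples are outside the assay's validated scope and
surface as inconclusive rather than as a silent wrong call.

`combine_calls()` enforces concordance whenever both assays conclude
(`SMN1_ABSENT` ⇔ affected), alarms on discordance, and implements two
policies: `indirect-primary` (default; the indirect call stands alone
when the direct assay fails, appropriate when haplotypes were phased from
a genomic-DNA reference) and `both-required`.

# Repeat mining

`score_repeat_candidate()` aligns a candidate tract globally against the
unbounded perfect tandem array of its motif with wraparound dynamic
programming, free start/end phase. The weights default to +2 per match
and −7 per mismatch or indel; published work on this marker panel states
the score thresholds (>54, >80, >66, >52 for motif lengths 2–5) and the
\>80% match filter but not the weights, so the familiar Tandem Repeats
Finder weighting was adopted — under it the thresholds correspond to
roughly 27/40/33/26 matched bases, and all weights are configurable.
Percent match is matching columns over all alignment columns; among
equally scoring paths the DP prefers more matches, then fewer columns, so
the reported percentage is deterministic. `N` bases never match.

`find_tandem_repeats()` seeds on exact adjacent unit copies, merges seed
neighbourhoods (50 bp gap and margin — with −7 penalties a qualifying
tract cannot extend further through non-repeat sequence), scores every
candidate window in a seeded region, and keeps maximal non-overlapping
hits: candidates ordered by score, then shorter motif, then leftmost
start, then shorter tract, kept greedily. The test suite proves the whole
procedure equal to brute-force enumeration of every (start, end, motif)
triple on short sequences, and checks strand symmetry. Motif units that
are powers of shorter units are rejected; motifs are reported as the
lexicographically smallest rotation over both strands. Coordinates are
0-based half-open throughout, matching the BED output.

Mining is intended for region-scale FASTA input (the ~0.5 Mb windows
flanking a locus of interest); genome-scale scans are out of scope.

# Synthetic data: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis relies
on, with defaults fixed to the study conditions of the tridecaplex panel:

* **Allele frequencies.** One spectrum per marker over the allele ladder
  implied by the marker's amplicon size range at 2 bp spacing, solved so
  that `1 − Σp²` equals the published population He (0.52–0.84). The
  one-major-allele shape is a simplification; every downstream statistic
  depends on the frequencies only through `Σp²`.
* **Cohorts** are drawn under Hardy–Weinberg proportions, independently
  across markers (no linkage disequilibrium between panel markers — real
  flanking markers this close may show LD, which would lower the panel's
  effective redundancy relative to these simulations).
* **Trios**: each parent carries one mutant (0 *SMN1* copies) and one
  wild haplotype; the affected child receives both mutant haplotypes.
* **Meiosis**: crossover probability between the gene and a marker
  follows the Haldane map function of physical distance at `cm_per_mb`
  (default 1 cM/Mb ≈ the genome average; the panel geometry then bounds
  recombination risk below 2% upstream and 1% downstream). Markers on the
  same side share a single crossover point per meiosis ("positional
  coherence"): one uniform draw per side flips exactly the markers whose
  Haldane fraction exceeds it, giving each marker its exact marginal
  recombination fraction while keeping flips distal-contiguous. Double
  crossovers within a flank are ignored — adequate at these distances.
* **WGA artifacts**: whole-cell failure (`p_cell_fail`, default 0.04,
  matching the observed rate of fully failed single-cell reactions), then
  per-locus failure (`p_locus_fail`, default 0.05), then independent
  per-allele dropout (`p_ado`, default 0.2 — the observed single-allele
  rate among amplified heterozygous loci is then `2p(1−p)/(1−p²) = 1/3`,
  within the published 0–40% per-marker range). A heterozygous locus
  losing both alleles is recorded as locus failure, as fragment data
  cannot tell the two apart. Contaminating alleles are drawn from
  population frequencies excluding the parental alleles, so contamination
  is in principle always detectable; real contamination by a relative
  could share parental alleles and evade the screen.
* **Minisequencing**: per-amplicon dropout scales as
  `base × 2·other/(own+other)` — the base rate at a 1:1 copy ratio,
  rising when the targeted gene is outnumbered, reproducing the observed
  excess dropout of *SMN1* signals at a 1:5 *SMN1*:*SMN2* ratio.

Not modelled: PCR stutter and peak-height artifacts (alleles are opaque
integer labels, as in fragment-size genotyping), preferential
amplification, mosaicism and aneuploidy, and LD between markers. Passing
tests therefore demonstrate the logic of the pipeline under the stated
artifact model, not performance on raw electropherograms.

# Numerical and interface conventions

* Allele labels are integers (amplicon sizes in bp by convention; repeat
  counts work identically). Missing data token is `.` in all TSVs; a
  locus with more than two observed alleles is written as multiple rows.
* Frequencies must sum to 1 within 1e-9; probabilities are validated to
  [0, 1]; `cm_per_mb = 0` is accepted and simply disables recombination.
* Observed heterozygosity excludes failed genotypes from the denominator;
  informativeness profiles count a missing genotype as non-heterozygous —
  the conservative direction for panel-redundancy claims. Expected
  heterozygosity uses the plug-in estimator by default; the `n/(n−1)`
  small-sample correction is available behind a flag but off, since
  published He tables for this panel use the plain estimator's scale.
* Every simulation entry point takes an integer seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs, and
  `run_pipeline()` records the tool version, seed, and a configuration
  hash alongside every output set.

# Problem sizes used by the test suite

The suite favours analytic fixed points where they exist (hand-scored
alignments, closed-form Haldane fractions, exact ADO arithmetic) and uses
simulation sizes chosen so that Monte-Carlo bands are decisive:
100,000 individuals for panel-redundancy percentages, 10,000 embryos for
the diagnosis-safety property, 1,000 trios for the phasing round trip,
1,000 cells for ADO-estimator recovery, and 3-SE bands for
Hardy–Weinberg recovery at 10,000 individuals. Brute-force mining
equivalence runs on sequences of ~100–120 bp, where exhaustive
enumeration of all (start, end, motif) triples is feasible.

# Known limitations

* The embryo-based phasing path requires one affected embryo with a clean
  direct ABSENT call; with none, indirect diagnosis is impossible and
  only the direct assay remains.
* The ≥2-per-side support rule is conservative by design; couples with
  few informative markers on one side will see elevated inconclusive
  rates rather than riskier calls.
* Synthetic marker positions reproduce the published panel geometry
  (side assignment, distance bounds), not true genomic coordinates.
* The direct-assay model treats the three amplicons as independent;
  correlated dropout (e.g. degraded WGA product) is only captured through
  the whole-cell failure channel.
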