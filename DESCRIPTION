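Package: pgtsma
Title: Microsatellite Panel Workflow for Haplotype-Based Preimplantation
    Genetic Testing of Spinal Muscular Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational workflow behind a microsatellite-panel-based
    preimplantation genetic test (PGT-M) for the SMN1 deletion locus that
    causes spinal muscular atrophy. Provides tandem-repeat mining with
    wraparound dynamic-programming alignment scores and flanking-window
    selection, per-marker heterozygosity and panel informativeness
    statistics, trio-based phasing of mutant and wild-type parental
    haplotypes from an affected reference, allele-dropout-tolerant
    single-cell embryo diagnosis combining an indirect haplotype call with
    a redundant direct SMN1 minisequencing call, allele-dropout and
    amplification-failure QC, and a seeded synthetic-data generator that
    emulates single-cell whole-genome-amplification artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
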