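# Synthetic-data generator: populations, carrier trios, embryo meioses, and
# single-cell WGA artifacts. Every function is deterministic given `seed`.

#' Simulation parameters for single-cell artifacts and meiosis
#'
#' @param p_ado Per-allele dropout probability after whole-genome
#'   amplification (each allele of a locus drops independently).
#' @param p_locus_fail Per-locus amplification failure probability.
#' @param p_cell_fail Probability that a whole cell yields no product.
#' @param p_contam Per-locus probability that one foreign allele is
#'   injected.
#' @param cm_per_mb Genetic/physical rate used to convert marker-gene
#'   distances to recombination fractions via [haldane_r()]. `0` disables
#'   recombination.
#' @param smn_signal_dropout_base Per-amplicon signal dropout probability at
#'   a balanced 1:1 SMN1:SMN2 copy ratio; dropout scales up as the targeted
#'   gene's share of total SMN copies shrinks (see
#'   [simulate_minisequencing_signals()]).
#' @param contam_freqs Optional allele-frequency list used to draw
#'   contaminating alleles.
#' @param parental_alleles Optional named list (by marker) of parental
#'   allele labels excluded when drawing contaminants, so contamination is
#'   in principle detectable.
#' @return A `sim_params` list.
#' @export
sim_params <- function(p_ado = 0.2, p_locus_fail = 0.05, p_cell_fail = 0.04,
                       p_contam = 0, cm_per_mb = 1,
                       smn_signal_dropout_base = 0.1,
                       contam_freqs = NULL, parental_alleles = NULL) {
  for (p in list(p_ado, p_locus_fail, p_cell_fail, p_contam,
                 smn_signal_dropout_base))
    if (!is_prob(p))
      stop_pgtsma("artifact probabilities must lie in [0, 1]",
                  "pgtsma_config_error")
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || cm_per_mb < 0)
    stop_pgtsma("cm_per_mb must be a non-negative number",
                "pgtsma_config_error")
  structure(list(p_ado = p_ado, p_locus_fail = p_locus_fail,
                 p_cell_fail = p_cell_fail, p_contam = p_contam,
                 cm_per_mb = cm_per_mb,
                 smn_signal_dropout_base = smn_signal_dropout_base,
                 contam_freqs = contam_freqs,
                 parental_alleles = parental_alleles),
            class = "sim_params")
}

#' Construct a parental haplotype
#'
#' @param carrier_status `"mutant"` (SMN1-deleted) or `"wild"`
#'   (SMN1-positive).
#' @param alleles Named integer vector, one marker allele per panel marker.
#' @param smn1_copies,smn2_copies Non-negative gene copy numbers on this
#'   chromosome; a mutant haplotype must carry zero SMN1 copies and a wild
#'   one at least one.
#' @return An `sma_haplotype` object.
#' @export
sma_haplotype <- function(carrier_status = c("mutant", "wild"), alleles,
                          smn1_copies = if (carrier_status == "mutant") 0L else 1L,
                          smn2_copies = 1L) {
  carrier_status <- match.arg(carrier_status)
  if (carrier_status == "mutant" && smn1_copies != 0L)
    stop_pgtsma("mutant haplotype must have smn1_copies = 0",
                "pgtsma_config_error")
  if (carrier_status == "wild" && smn1_copies < 1L)
    stop_pgtsma("wild haplotype must have smn1_copies >= 1",
                "pgtsma_config_error")
  if (smn2_copies < 0L)
    stop_pgtsma("smn2_copies must be non-negative", "pgtsma_config_error")
  structure(list(carrier_status = carrier_status,
                 alleles = alleles,
                 smn1_copies = as.integer(smn1_copies),
                 smn2_copies = as.integer(smn2_copies)),
            class = "sma_haplotype")
}

draw_haplotype_alleles <- function(panel, freqs) {
  a <- vapply(panel$name, function(m) {
    p <- freqs[[m]]
    as.integer(names(p)[sample.int(length(p), 1L, prob = p)])
  }, integer(1))
  stats::setNames(a, panel$name)
}

#' Simulate a population cohort under Hardy-Weinberg proportions
#'
#' Draws `n` individuals; at each marker the two alleles are independent
#' draws from that marker's frequency spectrum.
#'
#' @param panel An `sma_panel`.
#' @param freqs Allele-frequency list, one spectrum per panel marker (see
#'   [default_allele_frequencies()]).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Genotype data frame (`sample_id`, `role`, `marker`, `allele1`,
#'   `allele2`), with `allele1 <= allele2`.
#' @export
simulate_population <- function(panel, freqs, n, seed = NULL) {
  stopifnot(is_count(n))
  validate_frequencies(freqs, panel)
  with_seed_or_not(seed, {
    per_marker <- lapply(panel$name, function(m) {
      p <- freqs[[m]]
      labels <- as.integer(names(p))
      a1 <- labels[sample.int(length(p), n, replace = TRUE, prob = p)]
      a2 <- labels[sample.int(length(p), n, replace = TRUE, prob = p)]
      data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                 role = "sample", marker = m,
                 allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
    })
    out <- do.call(rbind, per_marker)
    out <- out[order(out$sample_id), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a carrier x carrier trio with an affected child
#'
#' Each parent receives one mutant (SMN1-deleted) and one wild haplotype
#' with marker alleles drawn from the population spectra; the affected
#' child inherits both mutant haplotypes, so its genotype at every marker
#' is the pair of parental mutant-linked alleles.
#'
#' @inheritParams simulate_population
#' @return List with elements `father` and `mother` (each a list with
#'   `mutant` and `wild` `sma_haplotype`s) and `child` (a
#'   `sample_genotype` with role `"affected"` and zero SMN1 copies by
#'   construction).
#' @export
simulate_trio <- function(panel, freqs, seed = NULL) {
  validate_frequencies(freqs, panel)
  with_seed_or_not(seed, {
    parent <- function() {
      list(mutant = sma_haplotype("mutant", draw_haplotype_alleles(panel, freqs),
                                  smn1_copies = 0L, smn2_copies = 1L),
           wild = sma_haplotype("wild", draw_haplotype_alleles(panel, freqs),
                                smn1_copies = 1L, smn2_copies = 1L))
    }
    father <- parent()
    mother <- parent()
    child_alleles <- lapply(panel$name, function(m) {
      c(father$mutant$alleles[[m]], mother$mutant$alleles[[m]])
    })
    names(child_alleles) <- panel$name
    list(father = father, mother = mother,
         child = sample_genotype("affected_child", child_alleles,
                                 role = "affected"))
  })
}

transmit_haplotype <- function(parent, panel, cm_per_mb, sides) {
  transmitted <- sample(c("mutant", "wild"), 1L)
  other <- setdiff(c("mutant", "wild"), transmitted)
  alleles <- parent[[transmitted]]$alleles
  dist_mb <- marker_distances_mb(panel)
  recombined <- character(0)
  if (cm_per_mb > 0) {
    # one crossover point per side per meiosis: a single uniform draw per
    # side flips every marker whose Haldane fraction exceeds it, so markers
    # on the same side switch coherently, distal-first, with exact
    # per-marker marginal recombination fractions
    for (side_markers in sides) {
      u <- stats::runif(1)
      flip <- side_markers[haldane_r(dist_mb[side_markers], cm_per_mb) > u]
      if (length(flip) > 0L) {
        alleles[flip] <- parent[[other]]$alleles[flip]
        recombined <- c(recombined, flip)
      }
    }
  }
  list(status = transmitted, alleles = alleles, recombined = recombined,
       smn1_copies = parent[[transmitted]]$smn1_copies,
       smn2_copies = parent[[transmitted]]$smn2_copies)
}

#' Simulate embryo meioses from a phased parent pair
#'
#' Each embryo inherits one (possibly recombinant) haplotype per parent.
#' Crossovers between the gene and a marker occur with the Haldane
#' probability of the marker-gene distance; markers on the same side of the
#' duplicon share a crossover point (positional coherence).
#'
#' @param father,mother Lists with `mutant` and `wild` `sma_haplotype`s, as
#'   produced by [simulate_trio()].
#' @param panel An `sma_panel`.
#' @param n_embryos Number of embryos.
#' @param params A `sim_params` (only `cm_per_mb` is used here).
#' @param seed Integer seed.
#' @return List of embryos, each a list with `truth` (paternal/maternal
#'   transmitted haplotype at the gene, recombined markers, SMN copy
#'   numbers) and `genotype` (artifact-free `sample_genotype`, role
#'   `"embryo"`).
#' @export
simulate_embryos <- function(father, mother, panel, n_embryos,
                             params = sim_params(), seed = NULL) {
  stopifnot(is_count(n_embryos))
  sides <- markers_by_side(panel)
  with_seed_or_not(seed, {
    lapply(seq_len(n_embryos), function(i) {
      pat <- transmit_haplotype(father, panel, params$cm_per_mb, sides)
      mat <- transmit_haplotype(mother, panel, params$cm_per_mb, sides)
      alleles <- lapply(panel$name, function(m) {
        c(pat$alleles[[m]], mat$alleles[[m]])
      })
      names(alleles) <- panel$name
      list(truth = list(paternal = pat$status, maternal = mat$status,
                        recombined_paternal = pat$recombined,
                        recombined_maternal = mat$recombined,
                        smn1_copies = pat$smn1_copies + mat$smn1_copies,
                        smn2_copies = pat$smn2_copies + mat$smn2_copies),
           genotype = sample_genotype(sprintf("E%03d", i), alleles,
                                      role = "embryo"))
    })
  })
}

#' Genomic-DNA genotype of a phased parent
#'
#' Collapses a parent's mutant and wild haplotypes into the unordered
#' allele pairs a genomic-DNA genotyping run would observe.
#'
#' @param parent List with `mutant` and `wild` `sma_haplotype`s.
#' @param sample_id,role Sample metadata for the result.
#' @return A `sample_genotype` with length-2 allele vectors.
#' @export
parental_genotype <- function(parent, sample_id, role = "father") {
  sample_genotype(sample_id,
                  Map(c, parent$mutant$alleles, parent$wild$alleles),
                  role = role)
}

draw_contaminant <- function(marker, exclude, params) {
  pool <- NULL
  if (!is.null(params$contam_freqs)) {
    p <- params$contam_freqs[[marker]]
    if (!is.null(p)) {
      keep <- !(as.integer(names(p)) %in% exclude)
      if (any(keep)) {
        p <- p[keep] / sum(p[keep])
        pool <- as.integer(names(p)[sample.int(length(p), 1L, prob = p)])
      }
    }
  }
  # no sampleable foreign allele: fabricate an off-ladder label
  if (is.null(pool)) pool <- max(exclude, 0L) + 3L
  pool
}

#' Apply single-cell WGA artifacts to a genotype
#'
#' Models the observation process of a whole-genome-amplified single cell:
#' with probability `p_cell_fail` the whole cell fails (all loci missing);
#' otherwise each locus fails with `p_locus_fail`, each allele copy then
#' drops independently with `p_ado`, and a foreign allele is injected with
#' `p_contam`. A heterozygous locus losing both alleles is recorded as a
#' locus failure (the two are indistinguishable in fragment data).
#'
#' @param gt A `sample_genotype` with true allele pairs.
#' @param params A `sim_params`.
#' @param seed Integer seed.
#' @return A `sample_genotype` of observed alleles: each locus holds the
#'   distinct observed labels (length 0 = no amplification).
#' @export
apply_wga_artifacts <- function(gt, params = sim_params(), seed = NULL) {
  with_seed_or_not(seed, {
    cell_failed <- stats::runif(1) < params$p_cell_fail
    obs <- lapply(names(gt$alleles), function(m) {
      a <- gt$alleles[[m]]
      observed <- if (cell_failed || length(a) == 0L ||
                      stats::runif(1) < params$p_locus_fail) {
        integer(0)
      } else {
        kept <- a[stats::runif(length(a)) >= params$p_ado]
        unique(kept)
      }
      if (params$p_contam > 0 && stats::runif(1) < params$p_contam) {
        exclude <- unique(c(params$parental_alleles[[m]], a))
        observed <- c(observed, draw_contaminant(m, as.integer(exclude), params))
      }
      sort(observed)
    })
    names(obs) <- names(gt$alleles)
    sample_genotype(gt$sample_id, obs, role = gt$role)
  })
}

#' Simulate triplex minisequencing signals
#'
#' Simulates the e7/i7/e8 triplex readout for a cell with the given SMN1
#' and SMN2 copy numbers. A gene's amplicon can only be detected if the
#' gene is present; detection failure occurs per amplicon with probability
#' `base * 2 * other/(own + other)`, i.e. the base rate at a balanced 1:1
#' ratio, rising as the gene is outnumbered (and capped at 1). This
#' reproduces the observation that SMN1-specific signals drop out more
#' often when SMN2 is in large excess.
#'
#' @param smn1_copies,smn2_copies Non-negative copy numbers.
#' @param params A `sim_params` (uses `smn_signal_dropout_base`).
#' @param seed Integer seed.
#' @return Data frame with columns `amplicon` (`e7`, `i7`, `e8`),
#'   `smn1_detected`, `smn2_detected`.
#' @export
simulate_minisequencing_signals <- function(smn1_copies, smn2_copies,
                                            params = sim_params(),
                                            seed = NULL) {
  stopifnot(smn1_copies >= 0, smn2_copies >= 0)
  total <- smn1_copies + smn2_copies
  p_drop <- function(own, other) {
    if (own == 0L) return(1)
    if (total == 0L) return(1)
    min(1, params$smn_signal_dropout_base * 2 * other / total)
  }
  p1 <- p_drop(smn1_copies, smn2_copies)
  p2 <- p_drop(smn2_copies, smn1_copies)
  with_seed_or_not(seed, {
    data.frame(amplicon = c("e7", "i7", "e8"),
               smn1_detected = smn1_copies > 0 & stats::runif(3) >= p1,
               smn2_detected = smn2_copies > 0 & stats::runif(3) >= p2)
  })
}

#' Simulate per-individual heterozygous-marker counts directly
#'
#' Marks each marker heterozygous independently with the given per-marker
#' probability and tallies counts per individual, total and per side of the
#' duplicon. This is the Bernoulli model used to project panel redundancy
#' from published per-marker observed heterozygosities.
#'
#' @param panel An `sma_panel`.
#' @param het_prob Per-marker heterozygosity probabilities: a numeric
#'   vector in panel order (or named by marker).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Data frame with columns `total`, `upstream`, `downstream` (one
#'   row per individual).
#' @export
simulate_het_counts <- function(panel, het_prob, n, seed = NULL) {
  stopifnot(is_count(n), length(het_prob) == nrow(panel))
  if (!is.null(names(het_prob))) het_prob <- het_prob[panel$name]
  stopifnot(all(vapply(het_prob, is_prob, logical(1))))
  with_seed_or_not(seed, {
    het <- matrix(stats::runif(n * nrow(panel)) <
                    rep(het_prob, each = n), nrow = n)
    up <- panel$side == "upstream"
    data.frame(total = rowSums(het),
               upstream = rowSums(het[, up, drop = FALSE]),
               downstream = rowSums(het[, !up, drop = FALSE]))
  })
}
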