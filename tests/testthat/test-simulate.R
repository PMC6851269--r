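panel <- sma_panel()

test_that("frequency calibration hits the target expected heterozygosity", {
  for (pop in c("chinese", "caucasian")) {
    freqs <- default_allele_frequencies(panel, pop)
    he <- vapply(freqs, function(p) 1 - sum(p^2), numeric(1))
    expect_equal(unname(he), panel[[paste0("he_", pop)]], tolerance = 1e-9)
    expect_true(all(vapply(freqs, function(p) abs(sum(p) - 1) < 1e-9,
                           logical(1))))
  }
  expect_error(freqs_matching_he(0.9, c(1, 2)), "unreachable",
               class = "pgtsma_error")
})

test_that("population simulation follows Hardy-Weinberg structure", {
  # monomorphic marker: every genotype is the single allele
  freqs <- default_allele_frequencies(panel, "chinese")
  mono <- lapply(freqs, function(p) stats::setNames(1, names(p)[1]))
  cohort <- simulate_population(panel, mono, 5, seed = 1)
  expect_true(all(cohort$allele1 == cohort$allele2))

  # two equifrequent alleles: Ho near 0.5 (3-SE band at n = 10,000)
  half <- lapply(freqs, function(p)
    stats::setNames(c(0.5, 0.5), names(p)[1:2]))
  cohort2 <- simulate_population(panel, half, 10000, seed = 2)
  ho <- heterozygosity_stats(cohort2, panel)$ho
  expect_true(all(abs(ho - 0.5) < 3 * sqrt(0.25 / 10000)))

  # determinism
  expect_identical(simulate_population(panel, freqs, 50, seed = 7),
                   simulate_population(panel, freqs, 50, seed = 7))
  expect_error(simulate_population(panel, freqs[-1], 5, seed = 1),
               class = "pgtsma_error")
})

test_that("simulated trios have carrier parents and an affected child", {
  freqs <- default_allele_frequencies(panel, "chinese")
  for (seed in 1:5) {
    trio <- simulate_trio(panel, freqs, seed = seed)
    for (parent in list(trio$father, trio$mother)) {
      expect_equal(parent$mutant$smn1_copies, 0L)
      expect_gte(parent$wild$smn1_copies, 1L)
    }
    # the child carries both mutant haplotypes: zero SMN1 copies and, at
    # each marker, exactly the two parental mutant-linked alleles
    for (mk in panel$name) {
      expect_setequal(pgtsma:::gt_alleles(trio$child, mk),
                      c(trio$father$mutant$alleles[[mk]],
                        trio$mother$mutant$alleles[[mk]]))
    }
    # Mendelian consistency with the parents
    father <- parental_genotype(trio$father, "F")
    mother <- parental_genotype(trio$mother, "M", "mother")
    for (mk in panel$name) {
      ch <- pgtsma:::gt_alleles(trio$child, mk)
      expect_true(ch[1] %in% pgtsma:::gt_alleles(father, mk) ||
                    ch[1] %in% pgtsma:::gt_alleles(mother, mk))
    }
  }
})

test_that("phasing recovers the generating haplotypes (round trip)", {
  freqs <- default_allele_frequencies(panel, "chinese")
  withr::with_seed(11, {
    for (rep in 1:25) {
      trio <- simulate_trio(panel, freqs)
      phased <- phase_trio(parental_genotype(trio$father, "F"),
                           parental_genotype(trio$mother, "M", "mother"),
                           trio$child, panel)
      for (i in seq_len(nrow(phased))) {
        if (phased$status[i] != "assigned") next
        side <- if (phased$parent[i] == "father") trio$father else trio$mother
        expect_equal(phased$mutant_allele[i],
                     unname(side$mutant$alleles[[phased$marker[i]]]))
        expect_equal(phased$wild_allele[i],
                     unname(side$wild$alleles[[phased$marker[i]]]))
      }
    }
  })
})

test_that("embryo meiosis respects the genetic map", {
  freqs <- default_allele_frequencies(panel, "chinese")
  trio <- simulate_trio(panel, freqs, seed = 3)

  # cm_per_mb = 0: transmitted haplotypes are exact parental copies
  emb <- simulate_embryos(trio$father, trio$mother, panel, 20,
                          sim_params(cm_per_mb = 0), seed = 5)
  for (e in emb) {
    expect_length(e$truth$recombined_paternal, 0)
    pat_hap <- trio$father[[e$truth$paternal]]$alleles
    for (mk in panel$name)
      expect_true(pat_hap[[mk]] %in% pgtsma:::gt_alleles(e$genotype, mk))
  }

  # reproducibility
  e1 <- simulate_embryos(trio$father, trio$mother, panel, 5,
                         sim_params(), seed = 9)
  e2 <- simulate_embryos(trio$father, trio$mother, panel, 5,
                         sim_params(), seed = 9)
  expect_identical(e1, e2)

  # per-meiosis switch probability of the most distal upstream marker
  # matches the Haldane closed form (Monte Carlo, 3-SE band)
  distal <- panel$name[panel$side == "upstream"][1]
  r_expect <- haldane_r(marker_distances_mb(panel)[[distal]], 1)
  n <- 4000
  emb2 <- simulate_embryos(trio$father, trio$mother, panel, n,
                           sim_params(cm_per_mb = 1), seed = 13)
  switched <- vapply(emb2, function(e)
    distal %in% e$truth$recombined_paternal, logical(1))
  se <- sqrt(r_expect * (1 - r_expect) / n)
  expect_lt(abs(mean(switched) - r_expect), 3 * se + 1e-9)

  # positional coherence: a switched proximal marker implies the more
  # distal markers on that side switched too
  up_markers <- panel$name[panel$side == "upstream"]
  d <- marker_distances_mb(panel)
  for (e in emb2[1:500]) {
    rec <- e$truth$recombined_paternal
    rec_up <- intersect(rec, up_markers)
    if (length(rec_up) > 0) {
      dmin <- min(d[rec_up])
      expect_setequal(rec_up, up_markers[d[up_markers] >= dmin])
    }
  }
})

test_that("WGA artifact model reproduces its analytic dropout rates", {
  freqs <- default_allele_frequencies(panel, "chinese")
  trio <- simulate_trio(panel, freqs, seed = 17)
  gt <- trio$child

  # all probabilities zero: observation equals truth (as allele sets)
  clean <- apply_wga_artifacts(gt, sim_params(p_ado = 0, p_locus_fail = 0,
                                              p_cell_fail = 0, p_contam = 0),
                               seed = 1)
  for (mk in panel$name)
    expect_setequal(pgtsma:::gt_alleles(clean, mk),
                    unique(pgtsma:::gt_alleles(gt, mk)))

  # whole-cell failure wipes every locus
  dead <- apply_wga_artifacts(gt, sim_params(p_cell_fail = 1), seed = 1)
  expect_true(all(lengths(dead$alleles) == 0))

  # at p_ado = 0.2, the fraction of amplified truly-het loci showing one
  # allele is 2p(1-p)/(1-p^2) = 1/3
  params <- sim_params(p_ado = 0.2, p_locus_fail = 0, p_cell_fail = 0,
                       p_contam = 0)
  het_markers <- panel$name[vapply(panel$name, function(mk)
    length(unique(pgtsma:::gt_alleles(gt, mk))) == 2L, logical(1))]
  one <- 0; amp <- 0
  withr::with_seed(23, {
    for (i in 1:600) {
      obs <- apply_wga_artifacts(gt, params)
      for (mk in het_markers) {
        a <- pgtsma:::gt_alleles(obs, mk)
        if (length(a) > 0) {
          amp <- amp + 1
          if (length(a) == 1) one <- one + 1
        }
      }
    }
  })
  expect_equal(expected_ado_rate(0.2), 1 / 3, tolerance = 1e-12)
  se <- sqrt((1 / 3) * (2 / 3) / amp)
  expect_lt(abs(one / amp - 1 / 3), 3 * se)
})

test_that("contamination injects detectable foreign alleles", {
  freqs <- default_allele_frequencies(panel, "chinese")
  trio <- simulate_trio(panel, freqs, seed = 29)
  parental <- lapply(panel$name, function(mk)
    unique(c(trio$father$mutant$alleles[[mk]], trio$father$wild$alleles[[mk]],
             trio$mother$mutant$alleles[[mk]], trio$mother$wild$alleles[[mk]])))
  names(parental) <- panel$name
  params <- sim_params(p_ado = 0, p_locus_fail = 0, p_cell_fail = 0,
                       p_contam = 1, contam_freqs = freqs,
                       parental_alleles = parental)
  obs <- apply_wga_artifacts(trio$child, params, seed = 31)
  for (mk in panel$name) {
    extra <- setdiff(pgtsma:::gt_alleles(obs, mk), parental[[mk]])
    expect_length(extra, 1)
  }
})

test_that("minisequencing signals reflect copy numbers and copy ratio", {
  p0 <- sim_params(smn_signal_dropout_base = 0)
  # affected: no SMN1, clean SMN2 control
  sig <- simulate_minisequencing_signals(0, 2, p0, seed = 1)
  expect_false(any(sig$smn1_detected))
  expect_true(all(sig$smn2_detected))
  # 1:1 with no dropout: all six signals
  sig2 <- simulate_minisequencing_signals(1, 1, p0, seed = 1)
  expect_true(all(sig2$smn1_detected) && all(sig2$smn2_detected))

  # SMN1 outnumbered 1:5 drops out at least as often as 1:1 (10,000 draws)
  pb <- sim_params(smn_signal_dropout_base = 0.15)
  drop_rate <- function(smn1, smn2, seed) {
    withr::with_seed(seed, {
      mean(vapply(1:10000, function(i)
        sum(!simulate_minisequencing_signals(smn1, smn2, pb)$smn1_detected),
        numeric(1))) / 3
    })
  }
  expect_gte(drop_rate(1, 5, 37), drop_rate(1, 1, 38))
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(p_ado = 1.2), class = "pgtsma_error")
  expect_error(sim_params(cm_per_mb = -1), class = "pgtsma_error")
  expect_silent(sim_params(cm_per_mb = 0))
  expect_error(sma_haplotype("mutant", c(a = 1L), smn1_copies = 1L),
               class = "pgtsma_error")
  expect_error(sma_haplotype("wild", c(a = 1L), smn1_copies = 0L),
               class = "pgtsma_error")
})
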