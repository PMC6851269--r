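panel <- sma_panel()

sig_frame <- function(smn1, smn2) {
  data.frame(amplicon = c("e7", "i7", "e8"),
             smn1_detected = smn1, smn2_detected = smn2)
}

test_that("direct SMN1 call uses triple redundancy with an SMN2 control", {
  # affected pattern: only SMN2 signals
  expect_equal(call_direct_smn1(sig_frame(c(F, F, F), c(T, T, T))),
               "SMN1_ABSENT")
  # a single surviving SMN1 amplicon suffices for presence
  expect_equal(call_direct_smn1(sig_frame(c(F, F, T), c(T, T, T))),
               "SMN1_PRESENT")
  expect_equal(call_direct_smn1(sig_frame(c(T, F, T), c(T, T, T))),
               "SMN1_PRESENT")
  # incomplete SMN2 control blocks an ABSENT call
  expect_equal(call_direct_smn1(sig_frame(c(F, F, F), c(T, F, T))),
               "INCONCLUSIVE")
  # total amplification failure
  expect_equal(call_direct_smn1(sig_frame(c(F, F, F), c(F, F, F))),
               "INCONCLUSIVE")
})

test_that("contamination screen flags extra and non-parental alleles", {
  fx <- make_trio_fixture(seed = 301)
  embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 1,
                              sim_params(cm_per_mb = 0), seed = 1)
  clean <- embryos[[1]]$genotype
  expect_false(detect_contamination(clean, fx$father, fx$mother,
                                    fx$panel)$flag)

  mk <- fx$panel$name[4]
  three <- clean
  three$alleles[[mk]] <- unique(c(three$alleles[[mk]], 9991L, 9992L))
  res <- detect_contamination(three, fx$father, fx$mother, fx$panel)
  expect_true(res$flag)
  expect_true(mk %in% res$markers)

  foreign <- clean
  foreign$alleles[[mk]] <- c(foreign$alleles[[mk]][1], 9991L)
  expect_true(detect_contamination(foreign, fx$father, fx$mother,
                                   fx$panel)$flag)
})

diagnose_fixture <- function(seed) {
  fx <- make_trio_fixture(seed = seed)
  fx$phased <- phase_trio(fx$father, fx$mother, fx$trio$child, fx$panel)
  fx
}

test_that("hypothesis scoring supports the true diplotype and rejects others", {
  fx <- diagnose_fixture(401)
  embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 10,
                              sim_params(cm_per_mb = 0), seed = 2)
  for (e in embryos) {
    sup <- score_haplotype_hypotheses(e$genotype, fx$phased, fx$panel)
    truth <- sup$paternal == e$truth$paternal &
      sup$maternal == e$truth$maternal
    expect_equal(sup$n_conflict[truth], 0)
    expect_equal(sup$n_ado_compatible[truth], 0)
    call <- call_embryo(sup)
    expect_equal(call$status,
                 pgtsma:::embryo_status(e$truth$paternal, e$truth$maternal))
  }
})

test_that("single-marker dropout moves a marker to ADO-compatible only", {
  fx <- diagnose_fixture(409)
  embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 5,
                              sim_params(cm_per_mb = 0), seed = 3)
  for (e in embryos) {
    sup0 <- score_haplotype_hypotheses(e$genotype, fx$phased, fx$panel)
    win0 <- which(sup0$n_conflict == 0)
    detail <- attr(sup0, "detail")
    # drop one allele at a usable marker with a heterozygous expectation
    usable <- names(which(detail$usable))
    cand <- usable[vapply(usable, function(mk)
      length(unique(pgtsma:::gt_alleles(e$genotype, mk))) == 2, logical(1))]
    if (length(cand) == 0) next
    mk <- cand[1]
    dropped <- e$genotype
    dropped$alleles[[mk]] <- unique(dropped$alleles[[mk]])[1]
    sup1 <- score_haplotype_hypotheses(dropped, fx$phased, fx$panel)
    win1 <- which(sup1$n_conflict == 0)
    expect_true(win0 %in% win1)
    cls <- attr(sup1, "detail")$cls
    expect_equal(unname(cls[mk, win0]), "ado")
    call <- call_embryo(sup1)
    if (call$status != "inconclusive")
      expect_equal(call$status,
                   pgtsma:::embryo_status(e$truth$paternal, e$truth$maternal))
  }
})

test_that("degenerate homozygous observations tie and are not called", {
  # both parents identically homozygous everywhere: all four hypotheses fit
  alleles <- stats::setNames(
    lapply(seq_len(nrow(panel)), function(i) c(100L, 100L)), panel$name)
  father <- sample_genotype("F", alleles, "father")
  mother <- sample_genotype("M", alleles, "mother")
  child <- sample_genotype("C", alleles, "affected")
  phased <- phase_trio(father, mother, child, panel)
  expect_error(score_haplotype_hypotheses(child, phased, panel),
               class = "pgtsma_error")  # nothing assigned at all

  # mixed case: one informative marker, everything else shared-homozygous
  alleles2 <- alleles
  alleles2[[panel$name[1]]] <- c(100L, 102L)
  father2 <- sample_genotype("F", alleles2, "father")
  embryo <- sample_genotype("E", lapply(alleles, unique), "embryo")
  phased2 <- phase_trio(father2, mother, child, panel)
  sup <- score_haplotype_hypotheses(embryo, phased2, panel)
  expect_gt(sum(sup$n_conflict == 0), 1)
  call <- call_embryo(sup)
  expect_equal(call$status, "inconclusive")
  expect_true(call$flags$insufficient_support)
})

test_that("support below two markers on a side is inconclusive", {
  fx <- diagnose_fixture(419)
  embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 1,
                              sim_params(cm_per_mb = 0), seed = 5)
  e <- embryos[[1]]
  # erase all upstream loci but one supporting marker
  detail <- attr(score_haplotype_hypotheses(e$genotype, fx$phased, fx$panel),
                 "detail")
  up_usable <- names(which(detail$usable))[
    panel$side[match(names(which(detail$usable)), panel$name)] == "upstream"]
  gt <- e$genotype
  for (mk in up_usable[-1]) gt$alleles[[mk]] <- integer(0)
  sup <- score_haplotype_hypotheses(gt, fx$phased, fx$panel)
  call <- call_embryo(sup)
  expect_equal(call$status, "inconclusive")
  expect_true(call$flags$insufficient_support)
})

test_that("a side-coherent haplotype switch raises the recombination flag", {
  fx <- diagnose_fixture(431)
  params <- sim_params(cm_per_mb = 0)
  e <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 1,
                        params, seed = 7)[[1]]
  # force a paternal crossover: the two most distal upstream markers come
  # from the haplotype opposite the transmitted one
  up <- panel$name[panel$side == "upstream"]
  d <- marker_distances_mb(panel)
  distal <- up[order(-d[up])][1:2]
  other <- setdiff(c("mutant", "wild"), e$truth$paternal)
  gt <- e$genotype
  for (mk in distal) {
    gt$alleles[[mk]] <- c(fx$trio$father[[other]]$alleles[[mk]],
                          fx$trio$mother[[e$truth$maternal]]$alleles[[mk]])
  }
  sup <- score_haplotype_hypotheses(gt, fx$phased, fx$panel)
  call <- call_embryo(sup)
  # conflicts at phase-visible switched markers should be explained by a
  # single distal switch; if the switch is invisible (parent homozygous
  # there) the call simply stays correct
  if (any(sup$n_conflict > 0) && all(sup$n_conflict > 0)) {
    expect_equal(call$status, "inconclusive")
    expect_true(call$flags$recombination_suspected)
  } else {
    expect_equal(call$status,
                 pgtsma:::embryo_status(e$truth$paternal, e$truth$maternal))
  }
})

test_that("direct and indirect calls combine under the stated policies", {
  fx <- diagnose_fixture(443)
  carrier <- structure(list(paternal_inherited = "mutant",
                            maternal_inherited = "wild",
                            status = "carrier_paternal",
                            flags = list(ado_markers = character(0),
                                         contamination = FALSE,
                                         recombination_suspected = FALSE,
                                         insufficient_support = FALSE),
                            support = NULL), class = "embryo_call")
  unaffected <- carrier
  unaffected$paternal_inherited <- "wild"
  unaffected$status <- "unaffected"
  inconclusive <- carrier
  inconclusive$status <- "inconclusive"

  res <- combine_calls("SMN1_PRESENT", carrier)
  expect_equal(res$final_status, "carrier_paternal")
  expect_equal(res$concordance, "concordant")

  res <- combine_calls("SMN1_ABSENT", unaffected)
  expect_equal(res$final_status, "inconclusive")
  expect_equal(res$concordance, "discordant")
  expect_true(res$flags$discordance)

  res <- combine_calls("INCONCLUSIVE", carrier, policy = "indirect-primary")
  expect_equal(res$final_status, "carrier_paternal")
  expect_true(res$flags$direct_inconclusive)

  res <- combine_calls("INCONCLUSIVE", carrier, policy = "both-required")
  expect_equal(res$final_status, "inconclusive")

  res <- combine_calls("SMN1_PRESENT", inconclusive)
  expect_equal(res$final_status, "inconclusive")

  expect_error(combine_calls("SMN1_PRESENT", carrier, policy = "bogus"),
               class = "pgtsma_error")
})

test_that("artifact-free embryos are always called correctly and concordantly", {
  fx <- diagnose_fixture(457)
  params <- sim_params(p_ado = 0, p_locus_fail = 0, p_cell_fail = 0,
                       p_contam = 0, cm_per_mb = 0,
                       smn_signal_dropout_base = 0)
  embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel, 200,
                              params, seed = 11)
  for (i in seq_along(embryos)) {
    e <- embryos[[i]]
    sig <- simulate_minisequencing_signals(e$truth$smn1_copies,
                                           e$truth$smn2_copies, params,
                                           seed = 100 + i)
    rep <- diagnose_embryo(e$genotype, sig, fx$phased, fx$father, fx$mother,
                           fx$panel)
    expect_equal(rep$final_status,
                 pgtsma:::embryo_status(e$truth$paternal, e$truth$maternal))
    expect_equal(rep$concordance, "concordant")
  }
})

test_that("raising dropout never raises the miscall rate (monotonic safety)", {
  fx <- diagnose_fixture(461)
  miscalls <- vapply(c(0.1, 0.3), function(p_ado) {
    params <- sim_params(p_ado = p_ado, p_locus_fail = 0.05,
                         p_cell_fail = 0, p_contam = 0, cm_per_mb = 0)
    embryos <- simulate_embryos(fx$trio$father, fx$trio$mother, fx$panel,
                                300, params, seed = 13)
    wrong <- 0
    withr::with_seed(17, {
      for (e in embryos) {
        obs <- apply_wga_artifacts(e$genotype, params)
        call <- call_embryo(score_haplotype_hypotheses(obs, fx$phased,
                                                       fx$panel))
        truth <- pgtsma:::embryo_status(e$truth$paternal, e$truth$maternal)
        if (call$status != "inconclusive" && call$status != truth)
          wrong <- wrong + 1
      }
    })
    wrong
  }, numeric(1))
  expect_true(all(miscalls == 0))
})
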