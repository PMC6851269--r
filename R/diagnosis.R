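# Embryo diagnosis: direct SMN1 minisequencing call, contamination screen,
# ADO-tolerant haplotype-hypothesis scoring, the support-based call rule,
# and the direct/indirect concordance policy.

DIRECT_CALLS <- c("SMN1_PRESENT", "SMN1_ABSENT", "INCONCLUSIVE")

#' Direct SMN1 call from triplex minisequencing signals
#'
#' The three amplicons (e7, i7, e8) provide triple redundancy:
#' `SMN1_PRESENT` as soon as any SMN1-specific signal is detected;
#' `SMN1_ABSENT` only when all three SMN1 signals are absent *and* all
#' three SMN2 signals are present (the SMN2 triplet acts as the
#' amplification control); anything else - including total amplification
#' failure - is `INCONCLUSIVE`.
#'
#' @param sig Data frame with columns `amplicon`, `smn1_detected`,
#'   `smn2_detected` (three rows).
#' @return One of `"SMN1_PRESENT"`, `"SMN1_ABSENT"`, `"INCONCLUSIVE"`.
#' @export
call_direct_smn1 <- function(sig) {
  stopifnot(nrow(sig) == 3L)
  if (any(sig$smn1_detected)) {
    "SMN1_PRESENT"
  } else if (all(sig$smn2_detected)) {
    "SMN1_ABSENT"
  } else {
    "INCONCLUSIVE"
  }
}

#' Screen an embryo observation for exogenous DNA contamination
#'
#' Flags the embryo if any marker shows more than two alleles, or any
#' observed allele is absent from the union of the parental alleles at
#' that marker.
#'
#' @param embryo_gt Observed embryo `sample_genotype`.
#' @param father_gt,mother_gt Complete parental `sample_genotype`s.
#' @param panel An `sma_panel`.
#' @return List with `flag` (logical) and `markers` (offending marker
#'   names).
#' @export
detect_contamination <- function(embryo_gt, father_gt, mother_gt, panel) {
  offending <- character(0)
  for (mk in panel$name) {
    obs <- unique(gt_alleles(embryo_gt, mk))
    parental <- unique(c(gt_alleles(father_gt, mk), gt_alleles(mother_gt, mk)))
    if (length(obs) > 2L || any(!(obs %in% parental)))
      offending <- c(offending, mk)
  }
  list(flag = length(offending) > 0L, markers = offending)
}

# expected allele lookup per parent: markers x c("mutant", "wild"); NA for
# markers whose phase is not usable for that parent
expected_allele_matrix <- function(phased, parent) {
  d <- phased[phased$parent == parent, , drop = FALSE]
  usable <- d$status %in% c("assigned", "uninformative_for_parent") &
    !d$possible_ado
  m <- cbind(mutant = ifelse(usable, d$mutant_allele, NA_integer_),
             wild = ifelse(usable, d$wild_allele, NA_integer_))
  rownames(m) <- d$marker
  m
}

classify_observation <- function(obs, expected_pair) {
  exp_set <- unique(expected_pair)
  if (any(!(obs %in% exp_set))) "conflict"
  else if (setequal(obs, exp_set)) "support"
  else "ado"
}

#' Score the four inheritance hypotheses for an embryo
#'
#' For each hypothesis (paternal mutant/wild x maternal mutant/wild) and
#' each phase-assigned marker, the observation either *supports* the
#' hypothesis (observed alleles equal the expected pair), is
#' *compatible with ADO* (a non-empty strict subset of the expected pair),
#' or *conflicts* (an observed allele the hypothesis cannot explain).
#' Ambiguous-phase, possible-ADO, inconsistent, and unamplified markers
#' contribute nothing. Supporting counts are aggregated per side of the
#' duplicon.
#'
#' @param embryo_gt Observed embryo `sample_genotype`.
#' @param phased Phased-haplotype data frame from [phase_trio()] or
#'   [phase_from_affected_embryo()].
#' @param panel An `sma_panel`.
#' @return Data frame with one row per hypothesis: `paternal`, `maternal`,
#'   `n_support_upstream`, `n_support_downstream`, `n_ado_compatible`,
#'   `n_conflict`; per-marker detail is attached as attribute `"detail"`.
#' @export
score_haplotype_hypotheses <- function(embryo_gt, phased, panel) {
  if (!any(phased$status == "assigned"))
    stop_pgtsma("no phase-assigned marker available for diagnosis",
                "pgtsma_undetermined")
  pat_exp <- expected_allele_matrix(phased, "father")
  mat_exp <- expected_allele_matrix(phased, "mother")
  markers <- panel$name
  obs_list <- lapply(markers, function(mk) unique(gt_alleles(embryo_gt, mk)))
  names(obs_list) <- markers
  usable <- vapply(markers, function(mk) {
    !anyNA(pat_exp[mk, ]) && !anyNA(mat_exp[mk, ]) &&
      length(obs_list[[mk]]) > 0L
  }, logical(1))
  hyps <- expand.grid(paternal = c("mutant", "wild"),
                      maternal = c("mutant", "wild"),
                      stringsAsFactors = FALSE)
  cls <- matrix(NA_character_, nrow = length(markers), ncol = nrow(hyps),
                dimnames = list(markers, NULL))
  for (h in seq_len(nrow(hyps))) {
    for (mk in markers[usable]) {
      cls[mk, h] <- classify_observation(
        obs_list[[mk]],
        c(pat_exp[mk, hyps$paternal[h]], mat_exp[mk, hyps$maternal[h]]))
    }
  }
  up <- markers[usable & panel$side == "upstream"]
  down <- markers[usable & panel$side == "downstream"]
  support <- cbind(hyps, data.frame(
    n_support_upstream = colSums(cls[up, , drop = FALSE] == "support"),
    n_support_downstream = colSums(cls[down, , drop = FALSE] == "support"),
    n_ado_compatible = colSums(cls[c(up, down), , drop = FALSE] == "ado"),
    n_conflict = colSums(cls[c(up, down), , drop = FALSE] == "conflict")))
  rownames(support) <- NULL
  attr(support, "detail") <- list(
    cls = cls, usable = usable, obs = obs_list,
    pat_exp = pat_exp, mat_exp = mat_exp,
    side = stats::setNames(panel$side, markers),
    dist = marker_distances_mb(panel))
  support
}

embryo_status <- function(paternal, maternal) {
  if (paternal == "mutant" && maternal == "mutant") "affected"
  else if (paternal == "wild" && maternal == "wild") "unaffected"
  else if (paternal == "mutant") "carrier_paternal"
  else "carrier_maternal"
}

# Does flipping `parent`'s expected allele at the `n_flip` most distal
# usable markers of `side` leave hypothesis `h` without conflicts?
switch_explains <- function(detail, hyps, h, parent, side, n_flip) {
  markers <- names(detail$side)
  usable <- markers[detail$usable]
  side_markers <- usable[detail$side[usable] == side]
  side_markers <- side_markers[order(-detail$dist[side_markers])]
  if (n_flip > length(side_markers)) return(FALSE)
  flip <- side_markers[seq_len(n_flip)]
  exp_of <- function(mk, who, state) {
    mat <- if (who == "father") detail$pat_exp else detail$mat_exp
    mat[mk, state]
  }
  for (mk in usable) {
    pstate <- hyps$paternal[h]
    mstate <- hyps$maternal[h]
    if (mk %in% flip) {
      if (parent == "father") pstate <- setdiff(c("mutant", "wild"), pstate)
      else mstate <- setdiff(c("mutant", "wild"), mstate)
    }
    expected <- c(exp_of(mk, "father", pstate), exp_of(mk, "mother", mstate))
    if (classify_observation(detail$obs[[mk]], expected) == "conflict")
      return(FALSE)
  }
  TRUE
}

#' Call an embryo from its hypothesis support table
#'
#' Selects the unique hypothesis with zero conflicting markers and
#' requires at least `min_support_per_side` fully supporting (not merely
#' ADO-compatible) markers on each side of the duplicon. Ties between
#' zero-conflict hypotheses or insufficient support give an inconclusive
#' call with `insufficient_support`. When no hypothesis is conflict-free
#' but a single side-consistent haplotype switch of one parent would
#' explain all conflicts, the embryo is reported inconclusive with
#' `recombination_suspected` (suspected recombinants are never re-phased).
#'
#' @param support Support table from [score_haplotype_hypotheses()].
#' @param min_support_per_side Support threshold per side (default 2).
#' @return An `embryo_call` list: `paternal_inherited`,
#'   `maternal_inherited` (`mutant`, `wild`, or `unknown`), `status`
#'   (`affected`, `carrier_paternal`, `carrier_maternal`, `unaffected`, or
#'   `inconclusive`), and `flags` (`ado_markers`, `contamination`,
#'   `recombination_suspected`, `insufficient_support`).
#' @export
call_embryo <- function(support, min_support_per_side = 2L) {
  detail <- attr(support, "detail")
  flags <- list(ado_markers = character(0), contamination = FALSE,
                recombination_suspected = FALSE, insufficient_support = FALSE)
  zero <- which(support$n_conflict == 0L)
  inconclusive <- function(flags) {
    structure(list(paternal_inherited = "unknown",
                   maternal_inherited = "unknown",
                   status = "inconclusive", flags = flags,
                   support = support),
              class = "embryo_call")
  }
  if (length(zero) == 0L) {
    hyps <- support[c("paternal", "maternal")]
    for (h in seq_len(nrow(support))) {
      for (parent in c("father", "mother")) {
        for (side in c("upstream", "downstream")) {
          n_side <- sum(detail$usable & detail$side[names(detail$usable)] == side)
          for (n_flip in seq_len(max(n_side, 0L))) {
            if (switch_explains(detail, hyps, h, parent, side, n_flip)) {
              flags$recombination_suspected <- TRUE
              return(inconclusive(flags))
            }
          }
        }
      }
    }
    flags$insufficient_support <- TRUE
    return(inconclusive(flags))
  }
  if (length(zero) > 1L) {
    flags$insufficient_support <- TRUE
    return(inconclusive(flags))
  }
  h <- zero
  if (support$n_support_upstream[h] < min_support_per_side ||
      support$n_support_downstream[h] < min_support_per_side) {
    flags$insufficient_support <- TRUE
    return(inconclusive(flags))
  }
  flags$ado_markers <- rownames(detail$cls)[!is.na(detail$cls[, h]) &
                                              detail$cls[, h] == "ado"]
  structure(list(paternal_inherited = support$paternal[h],
                 maternal_inherited = support$maternal[h],
                 status = embryo_status(support$paternal[h],
                                        support$maternal[h]),
                 flags = flags, support = support),
            class = "embryo_call")
}

#' @export
print.embryo_call <- function(x, ...) {
  cat(sprintf("<embryo_call> %s (paternal %s / maternal %s)\n",
              x$status, x$paternal_inherited, x$maternal_inherited))
  invisible(x)
}

#' Combine the direct SMN1 call with the indirect haplotype call
#'
#' Whenever both calls are conclusive, they must agree (`SMN1_ABSENT` with
#' an affected haplotype call; `SMN1_PRESENT` with a non-affected one);
#' discordance yields a final inconclusive with an alarm. Under the
#' `"indirect-primary"` policy the indirect call stands alone when the
#' direct assay is inconclusive (the phased reference makes it
#' self-sufficient), with a caveat flag; `"both-required"` demands both
#' assays be conclusive.
#'
#' @param direct Direct-call string from [call_direct_smn1()].
#' @param indirect An `embryo_call`.
#' @param policy `"indirect-primary"` or `"both-required"`.
#' @return List with `final_status`, `direct_call`, `indirect_status`,
#'   `concordance` (`"concordant"`, `"discordant"`, or `NA`), and `flags`.
#' @export
combine_calls <- function(direct, indirect,
                          policy = c("indirect-primary", "both-required")) {
  if (!is.character(policy) ||
      !all(policy %in% c("indirect-primary", "both-required")))
    stop_pgtsma(sprintf("unknown policy '%s'", policy[1L]),
                "pgtsma_config_error")
  policy <- match.arg(policy)
  stopifnot(direct %in% DIRECT_CALLS)
  flags <- indirect$flags
  flags$direct_inconclusive <- direct == "INCONCLUSIVE"
  flags$discordance <- FALSE
  direct_ok <- direct != "INCONCLUSIVE"
  indirect_ok <- indirect$status != "inconclusive"
  result <- function(status, concordance) {
    list(final_status = status, direct_call = direct,
         indirect_status = indirect$status, concordance = concordance,
         policy = policy, flags = flags)
  }
  if (direct_ok && indirect_ok) {
    concordant <- (direct == "SMN1_ABSENT") == (indirect$status == "affected")
    if (!concordant) {
      flags$discordance <- TRUE
      return(result("inconclusive", "discordant"))
    }
    return(result(indirect$status, "concordant"))
  }
  if (policy == "both-required") return(result("inconclusive", NA_character_))
  if (indirect_ok) return(result(indirect$status, NA_character_))
  result("inconclusive", NA_character_)
}

#' Diagnose one embryo end to end
#'
#' Runs the contamination screen, the direct minisequencing call, the
#' hypothesis scoring and support-rule call, and the concordance policy.
#' A contaminated observation is reported inconclusive outright.
#'
#' @param embryo_gt Observed embryo `sample_genotype`.
#' @param sig Minisequencing signal data frame for the embryo (or `NULL`
#'   for no direct assay, treated as `INCONCLUSIVE`).
#' @param phased Phased-haplotype data frame.
#' @param father_gt,mother_gt Parental `sample_genotype`s.
#' @param panel An `sma_panel`.
#' @param min_support_per_side Support threshold per side.
#' @param policy Concordance policy, see [combine_calls()].
#' @return Report list from [combine_calls()] with the embryo id and the
#'   underlying `embryo_call` attached.
#' @export
diagnose_embryo <- function(embryo_gt, sig, phased, father_gt, mother_gt,
                            panel, min_support_per_side = 2L,
                            policy = "indirect-primary") {
  contam <- detect_contamination(embryo_gt, father_gt, mother_gt, panel)
  direct <- if (is.null(sig)) "INCONCLUSIVE" else call_direct_smn1(sig)
  if (contam$flag) {
    indirect <- structure(
      list(paternal_inherited = "unknown", maternal_inherited = "unknown",
           status = "inconclusive",
           flags = list(ado_markers = character(0), contamination = TRUE,
                        recombination_suspected = FALSE,
                        insufficient_support = FALSE,
                        contamination_markers = contam$markers),
           support = NULL),
      class = "embryo_call")
  } else {
    support <- score_haplotype_hypotheses(embryo_gt, phased, panel)
    indirect <- call_embryo(support, min_support_per_side)
  }
  report <- combine_calls(direct, indirect, policy)
  report$embryo_id <- embryo_gt$sample_id
  report$indirect <- indirect
  report
}
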