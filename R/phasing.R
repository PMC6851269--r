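# Trio-based phasing of parental mutant (SMN1-deleted) and wild-type
# haplotypes from an affected reference, and marker informativeness
# classification.

#' Classify marker informativeness from the parental genotypes
#'
#' A marker is *fully* informative when both parents are heterozygous with
#' different allele pairs (every possible child genotype then resolves
#' both parental transmissions), *partially* informative when exactly one
#' parent is heterozygous or both are heterozygous with identical pairs,
#' and *uninformative* when both parents are homozygous.
#'
#' @param father_gt,mother_gt Length-2 integer vectors (unordered allele
#'   pairs; a homozygote repeats its allele).
#' @return `"fully"`, `"partially"`, or `"uninformative"`.
#' @examples
#' classify_marker_informativeness(c(1, 2), c(3, 4))  # fully
#' @export
classify_marker_informativeness <- function(father_gt, mother_gt) {
  if (length(father_gt) != 2L || length(mother_gt) != 2L ||
      anyNA(father_gt) || anyNA(mother_gt))
    stop_pgtsma("informativeness is undetermined with missing genotypes",
                "pgtsma_undetermined")
  f_het <- father_gt[1L] != father_gt[2L]
  m_het <- mother_gt[1L] != mother_gt[2L]
  if (f_het && m_het) {
    if (setequal(father_gt, mother_gt)) "partially" else "fully"
  } else if (f_het || m_het) {
    "partially"
  } else {
    "uninformative"
  }
}

other_allele <- function(pair, allele) {
  if (pair[1L] == allele) pair[2L] else pair[1L]
}

phase_row <- function(marker, parent, mutant, wild, status,
                      possible_ado = FALSE) {
  data.frame(marker = marker, parent = parent,
             mutant_allele = as.integer(mutant),
             wild_allele = as.integer(wild),
             status = status, possible_ado = possible_ado)
}

# Core Mendelian deduction at one marker: the affected reference carries
# both parental mutant-linked alleles; `child_pair` is its length-2
# genotype. Returns two rows (father, mother).
phase_marker <- function(marker, f, m, child_pair) {
  assignments <- unique(list(c(pat = child_pair[1L], mat = child_pair[2L]),
                             c(pat = child_pair[2L], mat = child_pair[1L])))
  valid <- Filter(function(a) a[["pat"]] %in% f && a[["mat"]] %in% m,
                  assignments)
  if (length(valid) == 0L) {
    return(rbind(phase_row(marker, "father", NA, NA, "inconsistent"),
                 phase_row(marker, "mother", NA, NA, "inconsistent")))
  }
  pat_alleles <- unique(vapply(valid, `[[`, numeric(1), "pat"))
  mat_alleles <- unique(vapply(valid, `[[`, numeric(1), "mat"))
  parent_rows <- function(parent, pair, resolved) {
    het <- pair[1L] != pair[2L]
    if (length(resolved) > 1L) {
      phase_row(marker, parent, NA, NA, "ambiguous")
    } else if (het) {
      phase_row(marker, parent, resolved, other_allele(pair, resolved),
                "assigned")
    } else {
      phase_row(marker, parent, pair[1L], pair[1L], "uninformative_for_parent")
    }
  }
  rbind(parent_rows("father", f, pat_alleles),
        parent_rows("mother", m, mat_alleles))
}

complete_pair <- function(gt, marker, who) {
  a <- gt_alleles(gt, marker)
  if (length(a) == 1L) a <- c(a, a)  # genomic DNA: one peak = homozygote
  if (length(a) != 2L || anyNA(a))
    stop_pgtsma(sprintf("%s genotype at marker %s must be complete",
                        who, marker),
                "pgtsma_input_error")
  a
}

#' Phase parental haplotypes from an affected child (genomic DNA)
#'
#' At every marker, both alleles of the affected reference are assumed to
#' be linked to the parental SMN1-deleted chromosomes. Mendelian deduction
#' assigns each child allele to a parent; the assigned allele becomes that
#' parent's mutant-linked allele and the parent's other allele its
#' wild-type-linked allele. A child heterozygote whose two alleles are
#' both carried by both parents cannot be resolved and is reported
#' `ambiguous`; a child allele carried by neither required parent makes
#' the marker `inconsistent` (and it never contributes to diagnosis).
#'
#' @param father_gt,mother_gt,affected_gt `sample_genotype` objects with
#'   complete genotypes at every panel marker (the trio-DNA workflow
#'   assumes no dropout in the reference).
#' @param panel An `sma_panel`.
#' @return Phased-haplotype data frame: one row per marker per parent with
#'   `mutant_allele`, `wild_allele`, `status` (`assigned`, `ambiguous`,
#'   `uninformative_for_parent`, `inconsistent`), `possible_ado`.
#' @export
phase_trio <- function(father_gt, mother_gt, affected_gt, panel) {
  check_panel_markers(panel, father_gt, mother_gt, affected_gt)
  rows <- lapply(panel$name, function(mk) {
    f <- complete_pair(father_gt, mk, "father")
    m <- complete_pair(mother_gt, mk, "mother")
    ch <- complete_pair(affected_gt, mk, "affected reference")
    phase_marker(mk, f, m, ch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_panel_markers <- function(panel, ...) {
  for (gt in list(...)) {
    missing <- setdiff(panel$name, names(gt$alleles))
    if (length(missing) > 0L)
      stop_pgtsma(sprintf("sample %s lacks panel marker %s",
                          gt$sample_id, missing[1L]),
                  "pgtsma_config_error")
  }
}

#' Phase parental haplotypes from an affected embryo
#'
#' As [phase_trio()], but the reference is a single-cell observation and
#' may carry dropout: a marker where the embryo shows a single allele
#' while either parent is heterozygous could hide an allele dropout, so it
#' is flagged `possible_ado` and left `ambiguous` rather than assigned.
#' Requires the embryo's direct call to be `SMN1_ABSENT` (the embryo must
#' be affected for its alleles to tag the mutant haplotypes).
#'
#' @param father_gt,mother_gt Complete parental `sample_genotype`s.
#' @param embryo_gt Observed embryo `sample_genotype` (sets of observed
#'   alleles; loci may be missing).
#' @param panel An `sma_panel`.
#' @param direct_call Direct-call string for the embryo; must be
#'   `"SMN1_ABSENT"`.
#' @return Phased-haplotype data frame as in [phase_trio()].
#' @export
phase_from_affected_embryo <- function(father_gt, mother_gt, embryo_gt,
                                       panel, direct_call) {
  if (!identical(direct_call, "SMN1_ABSENT"))
    stop_pgtsma("embryo-based phasing requires a direct call of SMN1_ABSENT",
                "pgtsma_precondition_error")
  check_panel_markers(panel, father_gt, mother_gt)
  rows <- lapply(panel$name, function(mk) {
    f <- complete_pair(father_gt, mk, "father")
    m <- complete_pair(mother_gt, mk, "mother")
    obs <- unique(gt_alleles(embryo_gt, mk))
    f_het <- f[1L] != f[2L]
    m_het <- m[1L] != m[2L]
    if (length(obs) == 0L) {
      # no amplification: nothing to phase at this marker
      rbind(phase_row(mk, "father", NA, NA, "ambiguous"),
            phase_row(mk, "mother", NA, NA, "ambiguous"))
    } else if (length(obs) > 2L) {
      rbind(phase_row(mk, "father", NA, NA, "inconsistent"),
            phase_row(mk, "mother", NA, NA, "inconsistent"))
    } else if (length(obs) == 1L && (f_het || m_het)) {
      if (!(obs %in% c(f, m))) {
        rbind(phase_row(mk, "father", NA, NA, "inconsistent"),
              phase_row(mk, "mother", NA, NA, "inconsistent"))
      } else {
        # a dropped second allele cannot be excluded
        one <- function(parent, pair, het) {
          if (het) phase_row(mk, parent, NA, NA, "ambiguous",
                             possible_ado = TRUE)
          else phase_row(mk, parent, pair[1L], pair[1L],
                         "uninformative_for_parent")
        }
        rbind(one("father", f, f_het), one("mother", m, m_het))
      }
    } else {
      pair <- if (length(obs) == 1L) c(obs, obs) else obs
      phase_marker(mk, f, m, pair)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
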