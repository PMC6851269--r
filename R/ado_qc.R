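# Allele-dropout and amplification-failure QC from replicate single cells
# with known (cell-line) truth genotypes.

#' Estimate per-marker ADO rates against truth genotypes
#'
#' For each marker, the denominator is the number of cells heterozygous at
#' the marker by truth whose locus amplified (at least one allele
#' observed); the numerator is the number of those cells showing exactly
#' one of the two true alleles. Locus failures are excluded from the
#' denominator; markers heterozygous in no cell are reported
#' not-evaluable (`NA` rate).
#'
#' @param observed List of observed `sample_genotype`s (single cells).
#' @param truth Named list of truth `sample_genotype`s keyed by cell
#'   sample id (complete allele pairs). Cells without truth are skipped
#'   with a warning.
#' @param panel An `sma_panel`.
#' @return Data frame with one row per marker: `marker`, `n_informative`,
#'   `n_ado`, `rate`, `n_locus_fail`.
#' @export
estimate_ado_rates <- function(observed, truth, panel) {
  if (inherits(observed, "sample_genotype")) observed <- list(observed)
  stopifnot(length(observed) >= 1L)
  ids <- vapply(observed, function(x) x$sample_id, character(1))
  have_truth <- ids %in% names(truth)
  if (any(!have_truth)) {
    warning(sprintf("skipping %d cell(s) without truth genotypes: %s",
                    sum(!have_truth),
                    paste(ids[!have_truth], collapse = ", ")))
    observed <- observed[have_truth]
    ids <- ids[have_truth]
  }
  whole_fail <- vapply(observed, function(cell)
    all(lengths(cell$alleles) == 0L), logical(1))
  rows <- lapply(panel$name, function(mk) {
    n_informative <- 0L; n_ado <- 0L; n_locus_fail <- 0L
    for (i in seq_along(observed)) {
      if (whole_fail[i]) next
      tr <- unique(gt_alleles(truth[[ids[i]]], mk))
      obs <- unique(gt_alleles(observed[[i]], mk))
      if (length(obs) == 0L) n_locus_fail <- n_locus_fail + 1L
      if (length(tr) != 2L) next  # homozygous: ADO unobservable
      if (length(obs) == 0L) next
      n_informative <- n_informative + 1L
      if (length(obs) == 1L && obs %in% tr) n_ado <- n_ado + 1L
    }
    data.frame(marker = mk, n_informative = n_informative, n_ado = n_ado,
               rate = if (n_informative > 0L) n_ado / n_informative
                      else NA_real_,
               n_locus_fail = n_locus_fail)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate per-marker and whole-cell amplification failure rates
#'
#' Whole-cell failures (no locus amplified at all) are tallied separately
#' and excluded from the per-marker denominators, matching how a fully
#' failed WGA reaction is dropped from marker-level QC.
#'
#' @param observed List of observed `sample_genotype`s.
#' @param panel An `sma_panel`.
#' @return List with `per_marker` (data frame `marker`, `n_fail`, `n_cells`,
#'   `rate`), `n_cells`, `n_whole_cell_fail`, and `whole_cell_failures`
#'   (sample ids).
#' @export
estimate_failure_rates <- function(observed, panel) {
  if (inherits(observed, "sample_genotype")) observed <- list(observed)
  stopifnot(length(observed) >= 1L)
  whole_fail <- vapply(observed, function(cell)
    all(lengths(cell$alleles) == 0L), logical(1))
  usable <- observed[!whole_fail]
  per_marker <- do.call(rbind, lapply(panel$name, function(mk) {
    n_fail <- sum(vapply(usable, function(cell)
      length(gt_alleles(cell, mk)) == 0L, logical(1)))
    data.frame(marker = mk, n_fail = n_fail, n_cells = length(usable),
               rate = if (length(usable) > 0L) n_fail / length(usable)
                      else NA_real_)
  }))
  rownames(per_marker) <- NULL
  list(per_marker = per_marker,
       n_cells = length(observed),
       n_whole_cell_fail = sum(whole_fail),
       whole_cell_failures = vapply(observed[whole_fail],
                                    function(x) x$sample_id, character(1)))
}

#' Expected single-allele observation rate under per-allele dropout
#'
#' Among amplified heterozygous loci, the probability of seeing exactly
#' one allele is `2p(1-p) / (1-p^2)` when each allele drops independently
#' with probability `p` (the denominator removes double dropouts, which
#' are recorded as locus failures).
#'
#' @param p_ado Per-allele dropout probability.
#' @return Expected observed ADO rate.
#' @export
expected_ado_rate <- function(p_ado) {
  stopifnot(is_prob(p_ado))
  if (p_ado == 1) return(NaN)
  2 * p_ado * (1 - p_ado) / (1 - p_ado^2)
}
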