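# Per-marker polymorphism statistics and panel informativeness profiles.

#' Expected heterozygosity from allele counts
#'
#' Computes `He = 1 - sum(p^2)` with plug-in allele frequencies
#' `p_i = count_i / total`. With `unbiased = TRUE`, applies the
#' small-sample correction `n/(n-1)` (n = number of gene copies).
#'
#' @param allele_counts Named numeric vector of allele counts.
#' @param unbiased Apply Nei's sample-size correction (default `FALSE`).
#' @return Expected heterozygosity in `[0, 1]`.
#' @examples
#' expected_heterozygosity(c(A = 50, B = 30, C = 20))  # 0.62
#' @export
expected_heterozygosity <- function(allele_counts, unbiased = FALSE) {
  if (length(allele_counts) == 0L || sum(allele_counts) < 1)
    stop_pgtsma("allele counts must be non-empty with positive total",
                "pgtsma_input_error")
  n <- sum(allele_counts)
  p <- allele_counts / n
  he <- 1 - sum(p^2)
  if (unbiased && n > 1) he <- he * n / (n - 1)
  he
}

#' Observed heterozygosity at one marker
#'
#' Fraction of successfully typed individuals that are heterozygous.
#' Individuals with a missing genotype at the marker are excluded from the
#' denominator.
#'
#' @param genotypes Data frame with columns `allele1`, `allele2` (one row
#'   per individual at this marker; `NA` = missing). An individual typed
#'   with a single allele (`allele2` missing) counts as homozygous, the
#'   genomic-DNA convention.
#' @return List with `ho`, `n_typed`, `n_het`.
#' @export
observed_heterozygosity <- function(genotypes) {
  typed <- !is.na(genotypes$allele1)
  n_typed <- sum(typed)
  if (n_typed == 0L)
    stop_pgtsma("no successfully typed individuals at this marker",
                "pgtsma_input_error")
  het <- typed & !is.na(genotypes$allele2) &
    genotypes$allele1 != genotypes$allele2
  list(ho = sum(het) / n_typed, n_typed = n_typed, n_het = sum(het))
}

#' Per-marker heterozygosity statistics for a cohort
#'
#' @param cohort Genotype data frame (long format).
#' @param panel An `sma_panel`.
#' @param unbiased Passed to [expected_heterozygosity()].
#' @return Data frame with one row per marker: `marker`, `n_typed`,
#'   `n_het`, `ho`, `he`, `n_alleles`.
#' @export
heterozygosity_stats <- function(cohort, panel, unbiased = FALSE) {
  rows <- lapply(panel$name, function(m) {
    d <- cohort[cohort$marker == m, , drop = FALSE]
    obs <- observed_heterozygosity(d)
    counts <- allele_summary(cohort, m)
    data.frame(marker = m, n_typed = obs$n_typed, n_het = obs$n_het,
               ho = obs$ho,
               he = if (counts$n_alleles > 0L)
                 expected_heterozygosity(counts$counts, unbiased) else NA_real_,
               n_alleles = counts$n_alleles)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed alleles and frequencies at one marker
#'
#' @param cohort Genotype data frame.
#' @param marker Marker name.
#' @return List with `n_alleles`, `counts` (named allele counts over typed
#'   chromosomes; a single-allele genotype contributes two copies), and
#'   `frequencies` (summing to 1; empty if nothing typed).
#' @export
allele_summary <- function(cohort, marker) {
  d <- cohort[cohort$marker == marker, , drop = FALSE]
  a1 <- d$allele1
  a2 <- ifelse(is.na(d$allele2) & !is.na(d$allele1), d$allele1, d$allele2)
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L)
    return(list(n_alleles = 0L, counts = numeric(0), frequencies = numeric(0)))
  counts <- table(alleles)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  list(n_alleles = length(counts), counts = counts,
       frequencies = counts / sum(counts))
}

het_count_table <- function(cohort, panel) {
  samples <- unique(cohort$sample_id)
  up <- panel$name[panel$side == "upstream"]
  key <- paste(cohort$sample_id, cohort$marker)
  het_row <- !is.na(cohort$allele1) & !is.na(cohort$allele2) &
    cohort$allele1 != cohort$allele2
  het_by_key <- tapply(het_row, key, any)
  counts <- t(vapply(samples, function(s) {
    k_up <- paste(s, up)
    k_all <- paste(s, panel$name)
    h <- het_by_key[k_all]
    h[is.na(h)] <- FALSE  # missing genotype counts as non-heterozygous
    hu <- het_by_key[k_up]
    hu[is.na(hu)] <- FALSE
    c(total = sum(h), upstream = sum(hu), downstream = sum(h) - sum(hu))
  }, numeric(3)))
  data.frame(sample_id = samples, total = counts[, "total"],
             upstream = counts[, "upstream"],
             downstream = counts[, "downstream"], row.names = NULL)
}

#' Cumulative informativeness summary from heterozygous-marker counts
#'
#' @param counts Data frame with columns `total`, `upstream`, `downstream`
#'   (per-individual heterozygous-marker counts).
#' @param n_markers Panel size (sets the range of k).
#' @return Data frame with, for each `k` in `0..n_markers`, the fraction of
#'   individuals heterozygous for at least `k` markers in total, upstream,
#'   and downstream, plus `frac_ge2_both_sides` as an attribute-free extra
#'   column (fraction with >= 2 on each side, constant over k).
#' @export
informativeness_summary <- function(counts, n_markers) {
  ks <- 0:n_markers
  both <- mean(counts$upstream >= 2 & counts$downstream >= 2)
  data.frame(
    k = ks,
    frac_total_ge_k = vapply(ks, function(k) mean(counts$total >= k), numeric(1)),
    frac_upstream_ge_k = vapply(ks, function(k) mean(counts$upstream >= k), numeric(1)),
    frac_downstream_ge_k = vapply(ks, function(k) mean(counts$downstream >= k), numeric(1)),
    frac_ge2_both_sides = both
  )
}

#' Panel informativeness profile of a cohort
#'
#' Tallies, per individual, the number of heterozygous markers (total and
#' per side of the duplicon; a missing genotype counts as
#' non-heterozygous) and the cumulative fraction of individuals
#' heterozygous for at least k markers.
#'
#' @param cohort Genotype data frame.
#' @param panel An `sma_panel`.
#' @return List with `counts` (per-individual data frame) and `summary`
#'   (from [informativeness_summary()]).
#' @export
informativeness_profile <- function(cohort, panel) {
  counts <- het_count_table(cohort, panel)
  list(counts = counts,
       summary = informativeness_summary(counts, nrow(panel)))
}
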