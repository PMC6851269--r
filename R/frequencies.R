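# Synthetic allele-frequency specifications.

#' Allele frequencies matching a target expected heterozygosity
#'
#' Builds a frequency vector over `alleles` whose expected heterozygosity
#' `1 - sum(p^2)` equals `he`. One allele takes frequency `p1` and the rest
#' share the remainder equally; `p1` solves the quadratic
#' `p1^2 + (1 - p1)^2 / (k - 1) = 1 - he`. This one-major-allele shape is a
#' deliberate simplification: real microsatellite spectra are ragged, but
#' only `sum(p^2)` matters to every statistic computed downstream.
#'
#' @param he Target expected heterozygosity in `[0, 1 - 1/k]`.
#' @param alleles Integer vector of allele labels (k of them).
#' @return Named numeric vector of frequencies summing to 1.
#' @examples
#' p <- freqs_matching_he(0.75, seq(200, 220, by = 2))
#' 1 - sum(p^2)
#' @export
freqs_matching_he <- function(he, alleles) {
  k <- length(alleles)
  stopifnot(k >= 1L, is_prob(he))
  if (k == 1L) {
    if (he != 0) stop_pgtsma("one allele forces He = 0", "pgtsma_config_error")
    return(stats::setNames(1, alleles))
  }
  if (he > 1 - 1/k + 1e-12)
    stop_pgtsma(sprintf("He = %.3f unreachable with %d alleles (max %.3f)",
                        he, k, 1 - 1/k),
                "pgtsma_config_error")
  target <- 1 - he  # sum of squared frequencies
  # p1^2 + (1-p1)^2/(k-1) = target; take the root with p1 >= 1/k
  a <- 1 + 1 / (k - 1)
  b <- -2 / (k - 1)
  cc <- 1 / (k - 1) - target
  disc <- max(b^2 - 4 * a * cc, 0)
  p1 <- (-b + sqrt(disc)) / (2 * a)
  p <- c(p1, rep((1 - p1) / (k - 1), k - 1L))
  stats::setNames(p, alleles)
}

#' Default synthetic allele frequencies for a panel
#'
#' One frequency spectrum per marker, over the allele ladder implied by the
#' marker's amplicon size range at dinucleotide (2 bp) spacing, calibrated
#' so that expected heterozygosity matches the panel's published value for
#' the chosen population.
#'
#' @param panel An `sma_panel`.
#' @param population `"chinese"` or `"caucasian"`.
#' @return Named list (by marker) of named frequency vectors.
#' @export
default_allele_frequencies <- function(panel,
                                       population = c("chinese", "caucasian")) {
  population <- match.arg(population)
  he <- panel[[paste0("he_", population)]]
  out <- lapply(seq_len(nrow(panel)), function(i) {
    alleles <- seq(panel$size_min[i], panel$size_max[i], by = 2L)
    freqs_matching_he(he[i], alleles)
  })
  names(out) <- panel$name
  out
}

#' Validate an allele-frequency specification
#'
#' @param freqs Named list (by marker) of named non-negative frequency
#'   vectors each summing to 1 (tolerance 1e-9).
#' @param panel Panel whose marker set must be fully covered.
#' @return `freqs`, invisibly.
#' @export
validate_frequencies <- function(freqs, panel) {
  missing <- setdiff(panel$name, names(freqs))
  if (length(missing) > 0L)
    stop_pgtsma(sprintf("no allele frequencies for marker %s", missing[1L]),
                "pgtsma_config_error")
  for (m in panel$name) {
    p <- freqs[[m]]
    if (length(p) < 1L || any(p < 0) || abs(sum(p) - 1) > 1e-9 ||
        is.null(names(p)))
      stop_pgtsma(sprintf("invalid frequency spec for marker %s", m),
                  "pgtsma_config_error")
  }
  invisible(freqs)
}
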