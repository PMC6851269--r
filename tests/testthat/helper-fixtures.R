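# Shared fixtures and independent oracles, all built in code.

default_test_panel <- function() sma_panel()

# deterministic background sequence over G/T only, so it can never extend
# an embedded A/C-containing repeat in phase
gt_background <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("G", "T"), n, TRUE), collapse = ""))
}

embed_at <- function(background, insert, offset0) {
  # offset0 is the 0-based start of the insert; total length is preserved
  paste0(substr(background, 1, offset0),
         insert,
         substr(background, offset0 + nchar(insert) + 1, nchar(background)))
}

# simulated trio plus the genomic-DNA parental genotypes
make_trio_fixture <- function(seed, population = "chinese") {
  panel <- default_test_panel()
  freqs <- default_allele_frequencies(panel, population)
  trio <- simulate_trio(panel, freqs, seed = seed)
  list(panel = panel, freqs = freqs, trio = trio,
       father = parental_genotype(trio$father, "father", "father"),
       mother = parental_genotype(trio$mother, "mother", "mother"))
}

# Brute-force tandem-repeat mining oracle: enumerates every (start, end,
# motif-class) triple, scores each window with score_repeat_candidate,
# filters on the strict thresholds, and applies the documented greedy
# selection independently of find_tandem_repeats' seed-region pruning.
oracle_find_tandem_repeats <- function(seqv, cfg = mining_config()) {
  ch <- strsplit(toupper(seqv), "")[[1]]
  n <- length(ch)
  cand <- list()
  for (k in 2:5) {
    if (n < 2 * k) next
    units <- character(0)
    for (i in 1:(n - 2 * k + 1)) {
      u <- paste(ch[i:(i + k - 1)], collapse = "")
      v <- paste(ch[(i + k):(i + 2 * k - 1)], collapse = "")
      if (u == v && !grepl("N", u) && !pgtsma:::is_power_of_shorter(u))
        units <- c(units, u)
    }
    if (length(units) == 0) next
    classes <- unique(vapply(units, pgtsma:::rotation_class, character(1)))
    thr <- cfg$min_score_by_motif_len[[as.character(k)]]
    for (cls in classes) {
      mo <- strsplit(cls, "")[[1]]
      for (start in 1:(n - 2 * k + 1)) {
        # one DP sweep scores every (start, end) window; identical to
        # calling score_repeat_candidate per window, only faster
        dp <- pgtsma:::wrap_dp_all_ends(ch[start:n], mo, cfg)
        for (end in (start + 2 * k - 1):n) {
          idx <- end - start + 1
          pct <- 100 * dp$matches[idx] / dp$columns[idx]
          if (dp$score[idx] > thr && pct > cfg$min_percent_match) {
            cand[[length(cand) + 1]] <- data.frame(
              start = start - 1L, end = end,
              motif = canonical_motif(cls), motif_len = k,
              percent_match = pct,
              alignment_score = dp$score[idx])
          }
        }
      }
    }
  }
  if (length(cand) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_len = integer(0),
                      percent_match = numeric(0),
                      alignment_score = numeric(0)))
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(-cand$alignment_score, cand$motif_len, cand$start,
                     cand$end - cand$start), , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    overlap <- kept & cand$start < cand$end[i] & cand$end > cand$start[i]
    if (!any(overlap)) kept[i] <- TRUE
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
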