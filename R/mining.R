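# Tandem-repeat mining: canonical motifs, wraparound-DP alignment scoring
# against a perfect repeat array, hit extraction, and flanking-window
# selection around the duplicated region.

#' Mining configuration
#'
#' Filters and alignment weights for microsatellite mining. Both filters
#' are strict: a hit must have percent match `>` `min_percent_match` and
#' alignment score `>` the threshold for its motif length. The default
#' score thresholds are 54/80/66/52 for di-/tri-/tetra-/penta-nucleotide
#' motifs; with the default +2/-7/-7 weights (the Tandem Repeats Finder
#' convention) these correspond to roughly 27/40/33/26 matched bases.
#'
#' @param min_percent_match Minimum percent of matching columns (strict).
#' @param min_score_by_motif_len Named vector of score thresholds (strict)
#'   keyed by motif length `"2"`..`"5"`.
#' @param window_bp Flanking-window size around the duplicon used by
#'   [select_flanking_candidates()].
#' @param match_weight Positive per-match score.
#' @param mismatch_penalty,indel_penalty Negative penalties.
#' @param region_gap,region_margin Seed-region merging gap and extension
#'   margin (bp) used to bound the dynamic programming.
#' @return A `mining_config` list.
#' @export
mining_config <- function(min_percent_match = 80,
                          min_score_by_motif_len = c(`2` = 54, `3` = 80,
                                                     `4` = 66, `5` = 52),
                          window_bp = 500000,
                          match_weight = 2, mismatch_penalty = -7,
                          indel_penalty = -7,
                          region_gap = 50, region_margin = 50) {
  stopifnot(match_weight > 0, mismatch_penalty < 0, indel_penalty < 0,
            window_bp > 0)
  structure(list(min_percent_match = min_percent_match,
                 min_score_by_motif_len = min_score_by_motif_len,
                 window_bp = window_bp,
                 match_weight = match_weight,
                 mismatch_penalty = mismatch_penalty,
                 indel_penalty = indel_penalty,
                 region_gap = region_gap, region_margin = region_margin),
            class = "mining_config")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
}

is_power_of_shorter <- function(x) {
  n <- nchar(x)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0L && strrep(substr(x, 1, d), n / d) == x) return(TRUE)
  }
  FALSE
}

#' Canonical repeat motif
#'
#' Returns the lexicographically smallest rotation among all rotations of
#' the unit and of its reverse complement, so that, e.g., `TG`, `GT`, `CA`,
#' and `AC` all map to `AC`. Units that are powers of a shorter unit (such
#' as `ATAT`) are rejected.
#'
#' @param unit Nucleotide string over `ACGT`.
#' @return The canonical unit.
#' @examples
#' canonical_motif("TG")  # "AC"
#' @export
canonical_motif <- function(unit) {
  unit <- toupper(unit)
  if (!grepl("^[ACGT]+$", unit))
    stop_pgtsma(sprintf("motif unit '%s' contains non-ACGT characters", unit),
                "pgtsma_input_error")
  if (is_power_of_shorter(unit))
    stop_pgtsma(sprintf("unit '%s' is a power of a shorter unit", unit),
                "pgtsma_input_error")
  min(c(rotations(unit), rotations(revcomp(unit))))
}

canonical_motif_or_na <- function(unit) {
  tryCatch(canonical_motif(unit), error = function(e) NA_character_)
}

# strand-specific rotation class (no reverse complement), used to pick the
# motif text actually aligned against the sequence
rotation_class <- function(unit) min(rotations(unit))

# One forward pass of the wraparound DP of `w` (character vector) against
# the unbounded perfect tandem array of `motif`, free start/end phase.
# Returns per-end best (score, matches, columns); ends are positions in w.
#
# Path ties are broken lexicographically (higher score, then more matches,
# then fewer columns); the three quantities are packed into one numeric
# key so comparisons stay vectorized. Bounds: |score| <= 2e4, matches and
# columns <= 2e4, so the packing is exact in doubles.
wrap_dp_all_ends <- function(w, motif, cfg) {
  m <- length(motif)
  n <- length(w)
  S <- cfg$match_weight; X <- cfg$mismatch_penalty; G <- cfg$indel_penalty
  jm1 <- c(m, seq_len(m - 1L))
  KM <- 1e5   # matches stride
  KS <- 1e10  # score stride
  pack <- function(sc, mt, cl) sc * KS + mt * KM + (KM - 1 - cl)
  key <- rep(pack(0, 0, 0), m)
  sc <- rep(0, m); mt <- rep(0, m); cl <- rep(0, m)
  out_sc <- numeric(n); out_mt <- numeric(n); out_cl <- numeric(n)
  for (i in seq_len(n)) {
    is_match <- (w[i] == motif) & (w[i] != "N")
    d_sc <- sc[jm1] + ifelse(is_match, S, X)
    d_mt <- mt[jm1] + is_match
    d_cl <- cl[jm1] + 1
    d_key <- pack(d_sc, d_mt, d_cl)
    u_sc <- sc + G; u_cl <- cl + 1
    u_key <- pack(u_sc, mt, u_cl)
    take_d <- d_key >= u_key
    sc <- ifelse(take_d, d_sc, u_sc)
    mt <- ifelse(take_d, d_mt, mt)
    cl <- ifelse(take_d, d_cl, u_cl)
    key <- ifelse(take_d, d_key, u_key)
    # gap columns consuming motif characters: cyclic, relax twice around
    for (pass in 1:2) {
      for (j in seq_len(m)) {
        p <- jm1[j]
        c_key <- pack(sc[p] + G, mt[p], cl[p] + 1)
        if (c_key > key[j]) {
          sc[j] <- sc[p] + G; mt[j] <- mt[p]; cl[j] <- cl[p] + 1
          key[j] <- c_key
        }
      }
    }
    b <- which.max(key)
    out_sc[i] <- sc[b]; out_mt[i] <- mt[b]; out_cl[i] <- cl[b]
  }
  list(score = out_sc, matches = out_mt, columns = out_cl)
}

#' Score a window against a perfect tandem array of a motif
#'
#' Globally aligns the window against the unbounded perfect repetition of
#' `motif` using wraparound dynamic programming with the configured match
#' weight and mismatch/indel penalties; the alignment may start and end at
#' any motif phase. Percent match is the fraction of matching columns over
#' all alignment columns.
#'
#' @param window Nucleotide string (the candidate repeat tract).
#' @param motif Repeat unit (scored as given; rotations are equivalent).
#' @param cfg A `mining_config`.
#' @return List with `alignment_score`, `percent_match`, `matches`,
#'   `columns`.
#' @examples
#' cfg <- mining_config()
#' score_repeat_candidate(strrep("AC", 14), "AC", cfg)$alignment_score  # 56
#' @export
score_repeat_candidate <- function(window, motif, cfg = mining_config()) {
  w <- strsplit(toupper(window), "")[[1]]
  mo <- strsplit(toupper(motif), "")[[1]]
  if (length(w) < 2L * length(mo))
    stop_pgtsma("window must be at least twice the motif length",
                "pgtsma_input_error")
  dp <- wrap_dp_all_ends(w, mo, cfg)
  n <- length(w)
  list(alignment_score = dp$score[n],
       percent_match = 100 * dp$matches[n] / dp$columns[n],
       matches = dp$matches[n], columns = dp$columns[n])
}

find_seeds <- function(ch, k) {
  n <- length(ch)
  if (n < 2L * k) return(integer(0))
  idx <- seq_len(n - 2L * k + 1L)
  ok <- rep(TRUE, length(idx))
  for (o in 0:(k - 1L)) {
    a <- ch[idx + o]; b <- ch[idx + k + o]
    ok <- ok & a == b & a != "N"
  }
  idx[ok]
}

merge_intervals <- function(starts, ends, gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me + gap) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  out
}

#' Find microsatellite repeats in a sequence
#'
#' Scans for di- to penta-nucleotide tandem repeats, scores candidate
#' tracts against the perfect repeat array of their motif with
#' [score_repeat_candidate()]'s wraparound DP, and returns maximal
#' non-overlapping hits passing both strict filters (percent match and the
#' motif-length-specific score threshold). Overlaps between motif classes
#' at one locus are resolved by keeping the highest score, ties broken by
#' shorter motif, then leftmost start, then shorter tract. `N` bases never
#' match.
#'
#' @param sequence Nucleotide string over `ACGTN`.
#' @param cfg A `mining_config`.
#' @param seq_id Sequence identifier for the output.
#' @return Data frame of hits sorted by start: `seq_id`, `start`, `end`
#'   (0-based half-open), `motif` (canonical), `copy_number`,
#'   `percent_match`, `alignment_score`.
#' @export
find_tandem_repeats <- function(sequence, cfg = mining_config(),
                                seq_id = "seq") {
  ch <- strsplit(toupper(sequence), "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N")))
    stop_pgtsma("sequence must be over ACGTN", "pgtsma_input_error")
  n <- length(ch)
  cand <- list()
  for (k in 2:5) {
    seeds <- find_seeds(ch, k)
    if (length(seeds) == 0L) next
    units <- vapply(seeds, function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
                    character(1))
    keep <- !vapply(units, is_power_of_shorter, logical(1))
    seeds <- seeds[keep]; units <- units[keep]
    if (length(seeds) == 0L) next
    rot <- vapply(units, rotation_class, character(1))
    for (cls in unique(rot)) {
      sel <- rot == cls
      regions <- merge_intervals(seeds[sel], seeds[sel] + 2L * k - 1L,
                                 cfg$region_gap)
      motif_ch <- strsplit(cls, "")[[1]]
      canon <- canonical_motif_or_na(cls)
      thr <- cfg$min_score_by_motif_len[[as.character(k)]]
      for (rg in regions) {
        rs <- max(1L, rg[1L] - cfg$region_margin)
        re <- min(n, rg[2L] + cfg$region_margin)
        for (start in rs:(re - 2L * k + 1L)) {
          dp <- wrap_dp_all_ends(ch[start:re], motif_ch, cfg)
          lens <- seq_along(dp$score)
          ok <- lens >= 2L * k & dp$score > thr &
            (100 * dp$matches / dp$columns) > cfg$min_percent_match
          if (!any(ok)) next
          ends <- start + lens[ok] - 1L
          cand[[length(cand) + 1L]] <- data.frame(
            seq_id = seq_id, start = start - 1L, end = ends, motif = canon,
            motif_len = k,
            copy_number = (ends - start + 1L) / k,
            percent_match = 100 * dp$matches[ok] / dp$columns[ok],
            alignment_score = dp$score[ok])
        }
      }
    }
  }
  if (length(cand) == 0L)
    return(empty_hits())
  select_nonoverlapping_hits(do.call(rbind, cand))
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             motif = character(0), motif_len = integer(0),
             copy_number = numeric(0), percent_match = numeric(0),
             alignment_score = numeric(0))
}

#' Greedy selection of maximal non-overlapping hits
#'
#' Orders candidates by score (descending), then motif length (ascending),
#' then start, then tract length, and keeps each candidate that does not
#' overlap an already kept one.
#'
#' @param cand Candidate hit data frame.
#' @return Selected hits sorted by start.
#' @export
select_nonoverlapping_hits <- function(cand) {
  if (nrow(cand) == 0L) return(empty_hits())
  # exact duplicates can arise when the same tract is reached from two
  # seed regions; they are harmless to the greedy but dropped for tidiness
  cand <- unique(cand)
  o <- order(-cand$alignment_score, cand$motif_len, cand$start,
             cand$end - cand$start)
  cand <- cand[o, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- kept & cand$seq_id == cand$seq_id[i] &
      cand$start < cand$end[i] & cand$end > cand$start[i]
    if (!any(ov)) kept[i] <- TRUE
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select repeat hits flanking the duplicated region
#'
#' Keeps hits lying entirely within `window_bp` of the duplicon on either
#' side and labels them upstream/downstream; hits overlapping the duplicon
#' are excluded with reason `"duplicated region"`, others with
#' `"outside window"`.
#'
#' @param hits Hit data frame from [find_tandem_repeats()].
#' @param duplicon Numeric `c(start, end)`, 0-based half-open.
#' @param cfg A `mining_config` (uses `window_bp`).
#' @return The hits with added columns `side` (`"upstream"`,
#'   `"downstream"`, or `NA`), `kept`, and `reason` (`NA` when kept).
#' @export
select_flanking_candidates <- function(hits, duplicon, cfg = mining_config()) {
  ds <- duplicon[[1L]]; de <- duplicon[[2L]]
  stopifnot(de > ds)
  w <- cfg$window_bp
  in_dup <- hits$start < de & hits$end > ds
  upstream <- hits$start >= ds - w & hits$end <= ds
  downstream <- hits$start >= de & hits$end <= de + w
  hits$side <- ifelse(in_dup, NA_character_,
                      ifelse(upstream, "upstream",
                             ifelse(downstream, "downstream", NA_character_)))
  hits$kept <- !is.na(hits$side)
  hits$reason <- ifelse(hits$kept, NA_character_,
                        ifelse(in_dup, "duplicated region", "outside window"))
  hits
}

#' Mine microsatellites from a FASTA file
#'
#' @param path FASTA path (read with Biostrings).
#' @param cfg A `mining_config`.
#' @return Combined hit data frame over all sequences.
#' @export
mine_fasta <- function(path, cfg = mining_config()) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_pgtsma("Biostrings is required to read FASTA input",
                "pgtsma_config_error")
  seqs <- Biostrings::readDNAStringSet(path)
  hits <- lapply(seq_along(seqs), function(i) {
    find_tandem_repeats(as.character(seqs[[i]]), cfg,
                        seq_id = sub("\\s.*$", "", names(seqs)[i]))
  })
  do.call(rbind, hits)
}

#' Write mining results as BED6 plus a percent-match TSV
#'
#' @param hits Hit data frame.
#' @param bed_path BED6 output (`chrom`, `start`, `end`,
#'   `name = motif x copies`, `score = alignment_score`, `strand = +`).
#' @param tsv_path Full TSV output including `percent_match`.
#' @return Invisibly, the BED path.
#' @export
write_mining_results <- function(hits, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = hits$seq_id, start = hits$start, end = hits$end,
                    name = sprintf("%sx%.1f", hits$motif, hits$copy_number),
                    score = hits$alignment_score, strand = "+")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bed_path)
}
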