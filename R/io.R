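# Genotype/pedigree/minisequencing table readers and writers.
#
# The interchange format for genotypes is a tab-separated table with header
#   sample_id  role  marker  allele1  allele2
# and "." for a missing allele. Alleles are integer amplicon sizes in bp
# (or repeat-unit counts; the pipeline treats them as opaque labels). A
# locus observed with a single fragment peak is written as allele1 + ".".
# A locus with more than two observed alleles (possible contamination) is
# written as multiple rows for the same sample and marker; readers take the
# union.

MISSING_TOKEN <- "."

#' Construct a single-sample genotype
#'
#' @param sample_id Sample identifier.
#' @param alleles Named list, one element per marker, each an integer vector
#'   of observed alleles: length 0 = amplification failure/missing, length 1
#'   = single observed allele (homozygote or dropout), length 2 = both
#'   alleles of a genotype (a homozygote may be given as a repeated label),
#'   length > 2 = extra alleles (contamination).
#' @param role One of `"father"`, `"mother"`, `"affected"`, `"embryo"`,
#'   `"sample"`, `"cell"`.
#' @return A `sample_genotype` object.
#' @export
sample_genotype <- function(sample_id, alleles, role = "sample") {
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  alleles <- lapply(alleles, function(a) as.integer(a[!is.na(a)]))
  structure(list(sample_id = as.character(sample_id),
                 role = as.character(role),
                 alleles = alleles),
            class = "sample_genotype")
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat(sprintf("<sample_genotype> %s (%s), %d markers\n",
              x$sample_id, x$role, length(x$alleles)))
  invisible(x)
}

#' Observed alleles of one sample at one marker
#' @keywords internal
#' @noRd
gt_alleles <- function(gt, marker) {
  a <- gt$alleles[[marker]]
  if (is.null(a)) integer(0) else a
}

#' Read a genotype table
#'
#' @param path Path to a TSV genotype table (see package format note).
#' @param panel Optional `sma_panel`; when given, rows whose marker is not
#'   in the panel are rejected with the offending row number.
#' @return A data frame with columns `sample_id`, `role`, `marker`,
#'   `allele1`, `allele2` (integers, `NA` = missing).
#' @export
read_genotypes <- function(path, panel = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "role", "marker", "allele1", "allele2")
  if (!all(required %in% names(df)))
    stop_pgtsma(sprintf("genotype table %s must have columns: %s",
                        path, paste(required, collapse = ", ")),
                "pgtsma_io_error")
  df <- df[required]
  if (!is.null(panel)) {
    unknown <- !(df$marker %in% panel$name)
    if (any(unknown))
      stop_pgtsma(sprintf("unknown marker '%s' at row %d of %s",
                          df$marker[unknown][1L], which(unknown)[1L], path),
                  "pgtsma_io_error")
  }
  parse_allele <- function(x, col) {
    x[x == MISSING_TOKEN] <- NA_character_
    bad <- !is.na(x) & is.na(suppressWarnings(as.integer(x)))
    if (any(bad))
      stop_pgtsma(sprintf("non-integer allele '%s' in column %s, row %d of %s",
                          x[bad][1L], col, which(bad)[1L], path),
                  "pgtsma_io_error")
    as.integer(x)
  }
  df$allele1 <- parse_allele(df$allele1, "allele1")
  df$allele2 <- parse_allele(df$allele2, "allele2")
  df
}

#' Write a genotype table
#'
#' @param genotypes A genotype data frame (as returned by [read_genotypes()]
#'   or the simulators) or a list of `sample_genotype` objects.
#' @param path Output path.
#' @param panel Optional panel used to order markers when writing
#'   `sample_genotype` objects.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, panel = NULL) {
  if (!is.data.frame(genotypes))
    genotypes <- genotype_table(genotypes, panel = panel)
  out <- genotypes
  out$allele1 <- ifelse(is.na(out$allele1), MISSING_TOKEN, as.character(out$allele1))
  out$allele2 <- ifelse(is.na(out$allele2), MISSING_TOKEN, as.character(out$allele2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert sample genotypes to a long table
#'
#' @param samples A `sample_genotype` or list of them.
#' @param panel Optional panel fixing marker order.
#' @return Genotype data frame; loci with more than two alleles emit extra
#'   rows.
#' @export
genotype_table <- function(samples, panel = NULL) {
  if (inherits(samples, "sample_genotype")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    markers <- if (!is.null(panel)) panel$name else names(s$alleles)
    do.call(rbind, lapply(markers, function(m) {
      a <- gt_alleles(s, m)
      if (length(a) == 0L) {
        data.frame(sample_id = s$sample_id, role = s$role, marker = m,
                   allele1 = NA_integer_, allele2 = NA_integer_)
      } else {
        # pair up alleles two per row; an odd leftover allele gets NA
        idx <- seq(1L, length(a), by = 2L)
        data.frame(sample_id = s$sample_id, role = s$role, marker = m,
                   allele1 = a[idx],
                   allele2 = ifelse(idx + 1L <= length(a), a[idx + 1L],
                                    NA_integer_))
      }
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a genotype table to sample genotypes
#'
#' Rows sharing a sample and marker are merged (union of alleles); an
#' intentionally homozygous truth genotype should therefore be written as a
#' single row with `allele1 == allele2`.
#'
#' @param df Genotype data frame.
#' @param panel Optional panel; markers absent from a sample become
#'   zero-length (missing) loci.
#' @param keep_duplicates Keep repeated allele labels within a row (so a
#'   homozygote is a length-2 vector); default `TRUE` for single-row loci.
#' @return Named list of `sample_genotype` objects.
#' @export
as_sample_genotypes <- function(df, panel = NULL, keep_duplicates = TRUE) {
  out <- lapply(split(df, df$sample_id), function(d) {
    markers <- if (!is.null(panel)) panel$name else unique(d$marker)
    alleles <- lapply(markers, function(m) {
      rows <- d[d$marker == m, , drop = FALSE]
      a <- c(rbind(rows$allele1, rows$allele2))
      a <- a[!is.na(a)]
      if (nrow(rows) > 1L || !keep_duplicates) a <- unique(a)
      as.integer(a)
    })
    names(alleles) <- markers
    sample_genotype(d$sample_id[1L], alleles, role = d$role[1L])
  })
  out[unique(df$sample_id)]
}

#' Read a pedigree table
#'
#' @param path TSV with columns `sample_id`, `role` (`father`, `mother`,
#'   `affected`, or `embryo`).
#' @return Data frame.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(df)))
    stop_pgtsma("pedigree table must have columns sample_id, role",
                "pgtsma_io_error")
  ok <- c("father", "mother", "affected", "embryo")
  if (!all(df$role %in% ok))
    stop_pgtsma(sprintf("unknown pedigree role '%s'",
                        setdiff(df$role, ok)[1L]),
                "pgtsma_io_error")
  df
}

#' Read a minisequencing signal table
#'
#' @param path TSV with columns `embryo_id`, `amplicon` (`e7`, `i7`, `e8`),
#'   `smn1_detected`, `smn2_detected` (0/1 or TRUE/FALSE).
#' @return Named list of per-embryo signal data frames (columns `amplicon`,
#'   `smn1_detected`, `smn2_detected`).
#' @export
read_minisequencing <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("embryo_id", "amplicon", "smn1_detected", "smn2_detected")
  if (!all(required %in% names(df)))
    stop_pgtsma(sprintf("minisequencing table must have columns: %s",
                        paste(required, collapse = ", ")),
                "pgtsma_io_error")
  df$smn1_detected <- as.logical(as.integer(as.logical(df$smn1_detected)))
  df$smn2_detected <- as.logical(as.integer(as.logical(df$smn2_detected)))
  lapply(split(df[required[-1L]], df$embryo_id), function(d) {
    d <- d[match(c("e7", "i7", "e8"), d$amplicon), ]
    rownames(d) <- NULL
    d
  })
}

#' Write a minisequencing signal table
#'
#' @param signals Named list of per-embryo signal data frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minisequencing <- function(signals, path) {
  rows <- Map(function(sig, id) cbind(embryo_id = id, sig),
              signals, names(signals))
  out <- do.call(rbind, rows)
  out$smn1_detected <- as.integer(out$smn1_detected)
  out$smn2_detected <- as.integer(out$smn2_detected)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phased haplotypes
#' @param phased Phased-haplotype data frame from [phase_trio()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased <- function(phased, path) {
  utils::write.table(phased, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = MISSING_TOKEN)
  invisible(path)
}

#' Read phased haplotypes
#' @param path Path written by [write_phased()].
#' @return Phased-haplotype data frame.
#' @export
read_phased <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = MISSING_TOKEN)
  df$mutant_allele <- as.integer(df$mutant_allele)
  df$wild_allele <- as.integer(df$wild_allele)
  if (is.null(df$possible_ado)) df$possible_ado <- FALSE
  df$possible_ado <- as.logical(df$possible_ado)
  df
}
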