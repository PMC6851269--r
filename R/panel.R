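# Marker panel definition and genetic-map helpers.

#' Default tridecaplex SMA marker panel
#'
#' Returns the 13-marker panel flanking the ~1.7 Mb chromosome 5q13.2
#' duplicated region that contains *SMN1* and *SMN2*: six markers upstream
#' and seven downstream of the duplicon. Marker names, repeat motifs,
#' amplicon size ranges, and published expected/observed heterozygosities in
#' the Chinese and Caucasian populations are those of the tridecaplex assay;
#' the base-pair positions are synthetic placements consistent with the
#' published map (upstream markers within ~0.5 Mb of the duplicon start and
#' within 2 Mb of *SMN1*; downstream markers within ~1 Mb of *SMN1*, the
#' most distal, *D5S637*, lying slightly beyond the 0.5 Mb mining window).
#'
#' @return An object of class `sma_panel`: a data frame with one row per
#'   marker (columns `name`, `chrom`, `position_bp`, `side`, `motif`,
#'   `size_min`, `size_max`, `he_chinese`, `he_caucasian`, `ho_chinese`,
#'   `ho_caucasian`) and attributes `duplicon` (0-based half-open interval),
#'   `gene_position_bp` (*SMN1*), and `chrom`.
#' @examples
#' panel <- sma_panel()
#' table(panel$side)
#' @export
sma_panel <- function() {
  markers <- data.frame(
    name = c("D5S1417", "D5S1413", "SMA6863", "SMA6873", "D5S1370",
             "SMA6877", "D5S1408", "SMA7093", "D5S610", "SMA7115",
             "SMA7120", "D5S1999", "D5S637"),
    chrom = "chr5",
    position_bp = c(68520000L, 68600000L, 68700000L, 68790000L, 68870000L,
                    68960000L, 70730000L, 70800000L, 70880000L, 70960000L,
                    71050000L, 71130000L, 71210000L),
    side = c(rep("upstream", 6L), rep("downstream", 7L)),
    motif = c("TG", "GT", "GA", "AC", "TG", "TG", "AC", "TG", "TG", "AG",
              "AC", "GA", "CA"),
    size_min = c(206L, 143L, 348L, 295L, 177L, 271L, 246L, 178L, 143L,
                 281L, 307L, 319L, 235L),
    size_max = c(228L, 167L, 384L, 327L, 193L, 293L, 274L, 206L, 175L,
                 311L, 325L, 327L, 243L),
    he_chinese   = c(0.69, 0.62, 0.81, 0.82, 0.68, 0.81, 0.76, 0.57, 0.84,
                     0.81, 0.75, 0.62, 0.52),
    he_caucasian = c(0.75, 0.56, 0.71, 0.76, 0.52, 0.79, 0.72, 0.61, 0.80,
                     0.84, 0.79, 0.52, 0.74),
    ho_chinese   = c(0.63, 0.63, 0.84, 0.77, 0.68, 0.83, 0.79, 0.57, 0.80,
                     0.85, 0.75, 0.62, 0.54),
    ho_caucasian = c(0.70, 0.59, 0.69, 0.78, 0.57, 0.80, 0.70, 0.56, 0.80,
                     0.81, 0.75, 0.60, 0.86),
    stringsAsFactors = FALSE
  )
  new_panel(markers,
            duplicon = c(start = 69000000L, end = 70700000L),
            gene_position_bp = 70220000L,
            chrom = "chr5")
}

new_panel <- function(markers, duplicon, gene_position_bp, chrom) {
  panel <- structure(markers,
                     duplicon = duplicon,
                     gene_position_bp = gene_position_bp,
                     chrom = chrom,
                     class = c("sma_panel", "data.frame"))
  validate_panel(panel)
  panel
}

#' Validate a marker panel
#'
#' Checks the structural invariants of a panel: at least one marker, unique
#' names, positions strictly increasing, no marker inside the duplicon, and
#' each marker's `side` label consistent with its position relative to the
#' duplicated region.
#'
#' @param panel An `sma_panel` object.
#' @return The panel, invisibly, if valid; otherwise an error naming the
#'   offending marker.
#' @export
validate_panel <- function(panel) {
  dup <- attr(panel, "duplicon")
  if (is.null(dup) || dup[["end"]] <= dup[["start"]])
    stop_pgtsma("panel duplicon must be a non-empty half-open interval",
                "pgtsma_config_error")
  if (nrow(panel) == 0L)
    stop_pgtsma("panel has no markers", "pgtsma_config_error")
  if (anyDuplicated(panel$name))
    stop_pgtsma(sprintf("duplicate marker name: %s",
                        panel$name[duplicated(panel$name)][1L]),
                "pgtsma_config_error")
  if (is.unsorted(panel$position_bp, strictly = TRUE))
    stop_pgtsma("marker positions must be strictly increasing",
                "pgtsma_config_error")
  inside <- panel$position_bp >= dup[["start"]] & panel$position_bp < dup[["end"]]
  if (any(inside))
    stop_pgtsma(sprintf("marker inside the duplicated region: %s",
                        panel$name[inside][1L]),
                "pgtsma_config_error")
  expected_side <- ifelse(panel$position_bp < dup[["start"]],
                          "upstream", "downstream")
  bad <- panel$side != expected_side
  if (any(bad))
    stop_pgtsma(sprintf("side label inconsistent with position for marker %s",
                        panel$name[bad][1L]),
                "pgtsma_config_error")
  if (any(panel$size_max < panel$size_min))
    stop_pgtsma("empty amplicon size range", "pgtsma_config_error")
  invisible(panel)
}

#' Read a marker panel from JSON
#'
#' @param path Path to a JSON panel file with fields `chrom`, `duplicon`
#'   (`start`, `end`; 0-based half-open), `gene_position_bp`, and `markers`
#'   (array of objects with `name`, `position_bp`, `side`, `motif`,
#'   `size_min`, `size_max` and optional heterozygosity columns).
#' @return A validated `sma_panel`.
#' @export
read_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.data.frame(x$markers, stringsAsFactors = FALSE)
  m$position_bp <- as.integer(m$position_bp)
  m$size_min <- as.integer(m$size_min)
  m$size_max <- as.integer(m$size_max)
  if (is.null(m$chrom)) m$chrom <- x$chrom
  new_panel(m,
            duplicon = c(start = as.integer(x$duplicon$start),
                         end = as.integer(x$duplicon$end)),
            gene_position_bp = as.integer(x$gene_position_bp),
            chrom = x$chrom)
}

#' Write a marker panel to JSON
#'
#' @param panel An `sma_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  dup <- attr(panel, "duplicon")
  x <- list(chrom = attr(panel, "chrom"),
            duplicon = list(start = unname(dup[["start"]]),
                            end = unname(dup[["end"]])),
            gene_position_bp = attr(panel, "gene_position_bp"),
            markers = as.data.frame(panel))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Haldane map function
#'
#' Converts a physical distance into a recombination fraction under the
#' Haldane (no-interference) map function, `r = (1 - exp(-2d))/2` with `d`
#' in Morgans.
#'
#' @param distance_mb Physical distance in megabases.
#' @param cm_per_mb Genetic-to-physical rate in centimorgans per megabase.
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(2, 1)   # ~0.0198 for a marker 2 Mb from the gene
#' @export
haldane_r <- function(distance_mb, cm_per_mb = 1) {
  stopifnot(all(distance_mb >= 0), cm_per_mb >= 0)
  d_morgan <- distance_mb * cm_per_mb / 100
  (1 - exp(-2 * d_morgan)) / 2
}

#' Marker distances from the target gene
#'
#' @param panel An `sma_panel`.
#' @return Named numeric vector of distances (Mb) between each marker and
#'   the gene position stored in the panel.
#' @export
marker_distances_mb <- function(panel) {
  d <- abs(panel$position_bp - attr(panel, "gene_position_bp")) / 1e6
  names(d) <- panel$name
  d
}

#' Per-side marker names, most distal first within each side
#' @keywords internal
#' @noRd
markers_by_side <- function(panel) {
  d <- marker_distances_mb(panel)
  lapply(split(panel$name, panel$side), function(nm) nm[order(-d[nm])])
}
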