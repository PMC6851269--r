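# Command-line style pipeline entry point tying the stages together.
# A thin wrapper script is shipped at inst/scripts/pgtsma.R.

parse_cli_args <- function(args) {
  if (length(args) == 0L)
    stop_pgtsma("usage: pgtsma <simulate|mine|stats|phase|diagnose|qc> [--opt value ...]",
                "pgtsma_usage_error")
  command <- args[[1L]]
  args <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--"))
      stop_pgtsma(sprintf("unexpected argument '%s'", key),
                  "pgtsma_usage_error")
    key <- gsub("-", "_", substring(key, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE  # bare flag
      i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  list(command = command, opts = opts)
}

opt_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) return(default)
  as.numeric(opts[[key]])
}

opt_chr <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) return(default)
  as.character(opts[[key]])
}

require_opt <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop_pgtsma(sprintf("missing required option --%s", gsub("_", "-", key)),
                "pgtsma_usage_error")
  opts[[key]]
}

write_run_info <- function(out_dir, command, opts, seed) {
  cfg <- vapply(opts, function(x) paste(format(x), collapse = ","),
                character(1))
  tmp <- tempfile()
  writeLines(paste(names(cfg), cfg, sep = "="), tmp)
  info <- list(tool = "pgtsma",
               version = as.character(utils::packageVersion("pgtsma")),
               command = command,
               seed = seed,
               config_hash = unname(tools::md5sum(tmp)),
               options = as.list(cfg))
  unlink(tmp)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

load_panel_opt <- function(opts) {
  path <- opt_chr(opts, "panel")
  if (is.null(path)) sma_panel() else read_panel(path)
}

params_from_opts <- function(opts) {
  sim_params(p_ado = opt_num(opts, "p_ado", 0.2),
             p_locus_fail = opt_num(opts, "p_locus_fail", 0.05),
             p_cell_fail = opt_num(opts, "p_cell_fail", 0),
             p_contam = opt_num(opts, "p_contam", 0),
             cm_per_mb = opt_num(opts, "cm_per_mb", 1),
             smn_signal_dropout_base = opt_num(opts, "smn_dropout", 0.1))
}

pipeline_simulate <- function(opts) {
  panel <- load_panel_opt(opts)
  seed <- as.integer(opt_num(opts, "seed", 1))
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  population <- opt_chr(opts, "population", "chinese")
  freqs <- default_allele_frequencies(panel, population)
  params <- params_from_opts(opts)
  if (!is.null(opts$cohort)) {
    n <- as.integer(opt_num(opts, "cohort"))
    cohort <- simulate_population(panel, freqs, n, seed = seed)
    write_genotypes(cohort, file.path(out_dir, "cohort.tsv"))
  }
  if (isTRUE(opts$trio) || !is.null(opts$embryos)) {
    trio <- simulate_trio(panel, freqs, seed = seed + 1L)
    parents <- list(parental_genotype(trio$father, "father", "father"),
                    parental_genotype(trio$mother, "mother", "mother"),
                    trio$child)
    write_genotypes(parents, file.path(out_dir, "trio.tsv"), panel = panel)
    truth <- list(seed = seed, population = population)
    if (!is.null(opts$embryos)) {
      n_emb <- as.integer(opt_num(opts, "embryos"))
      embryos <- simulate_embryos(trio$father, trio$mother, panel, n_emb,
                                  params, seed = seed + 2L)
      observed <- lapply(seq_along(embryos), function(i)
        apply_wga_artifacts(embryos[[i]]$genotype, params,
                            seed = seed + 10L + i))
      write_genotypes(observed, file.path(out_dir, "embryos.tsv"),
                      panel = panel)
      signals <- lapply(seq_along(embryos), function(i)
        simulate_minisequencing_signals(embryos[[i]]$truth$smn1_copies,
                                        embryos[[i]]$truth$smn2_copies,
                                        params, seed = seed + 100L + i))
      names(signals) <- vapply(observed, function(x) x$sample_id,
                               character(1))
      write_minisequencing(signals, file.path(out_dir, "minisequencing.tsv"))
      truth$embryos <- lapply(embryos, function(e) e$truth)
      names(truth$embryos) <- names(signals)
      truth$father_mutant <- as.list(trio$father$mutant$alleles)
      truth$father_wild <- as.list(trio$father$wild$alleles)
      truth$mother_mutant <- as.list(trio$mother$mutant$alleles)
      truth$mother_wild <- as.list(trio$mother$wild$alleles)
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  write_run_info(out_dir, "simulate", opts, seed)
  invisible(0L)
}

pipeline_mine <- function(opts) {
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- mine_fasta(require_opt(opts, "fasta"), mining_config())
  if (!is.null(opts$duplicon)) {
    dup <- as.numeric(strsplit(opt_chr(opts, "duplicon"), ":")[[1L]])
    hits <- select_flanking_candidates(hits, dup)
  }
  write_mining_results(hits, file.path(out_dir, "repeats.bed"),
                       file.path(out_dir, "repeats.tsv"))
  write_run_info(out_dir, "mine", opts, NA)
  invisible(0L)
}

pipeline_stats <- function(opts) {
  panel <- load_panel_opt(opts)
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_genotypes(require_opt(opts, "genotypes"), panel)
  stats <- heterozygosity_stats(cohort, panel)
  utils::write.table(stats, file.path(out_dir, "heterozygosity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- informativeness_profile(cohort, panel)
  utils::write.table(prof$summary, file.path(out_dir, "informativeness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_info(out_dir, "stats", opts, NA)
  invisible(0L)
}

trio_from_table <- function(df, panel) {
  samples <- as_sample_genotypes(df, panel)
  roles <- vapply(samples, function(s) s$role, character(1))
  pick <- function(role) {
    idx <- which(roles == role)
    if (length(idx) != 1L)
      stop_pgtsma(sprintf("expected exactly one sample with role '%s'", role),
                  "pgtsma_io_error")
    samples[[idx]]
  }
  list(father = pick("father"), mother = pick("mother"),
       affected = if (any(roles == "affected")) pick("affected") else NULL,
       embryos = samples[roles == "embryo"])
}

pipeline_phase <- function(opts) {
  panel <- load_panel_opt(opts)
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- read_genotypes(require_opt(opts, "genotypes"), panel)
  if (!is.null(opts$pedigree)) {
    ped <- read_pedigree(opt_chr(opts, "pedigree"))
    df$role <- ped$role[match(df$sample_id, ped$sample_id)]
  }
  trio <- trio_from_table(df, panel)
  if (is.null(trio$affected))
    stop_pgtsma("phasing requires a sample with role 'affected'",
                "pgtsma_io_error")
  phased <- phase_trio(trio$father, trio$mother, trio$affected, panel)
  write_phased(phased, file.path(out_dir, "phased.tsv"))
  write_run_info(out_dir, "phase", opts, NA)
  invisible(0L)
}

pipeline_diagnose <- function(opts) {
  panel <- load_panel_opt(opts)
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- read_genotypes(require_opt(opts, "genotypes"), panel)
  trio <- trio_from_table(df, panel)
  phased <- if (!is.null(opts$phased)) {
    read_phased(opt_chr(opts, "phased"))
  } else {
    if (is.null(trio$affected))
      stop_pgtsma("diagnose needs --phased or an 'affected' reference sample",
                  "pgtsma_io_error")
    phase_trio(trio$father, trio$mother, trio$affected, panel)
  }
  signals <- if (!is.null(opts$minisequencing))
    read_minisequencing(opt_chr(opts, "minisequencing")) else list()
  policy <- opt_chr(opts, "policy", "indirect-primary")
  min_support <- as.integer(opt_num(opts, "min_support_per_side", 2))
  reports <- lapply(trio$embryos, function(e)
    diagnose_embryo(e, signals[[e$sample_id]], phased,
                    trio$father, trio$mother, panel,
                    min_support_per_side = min_support, policy = policy))
  jsonlite::write_json(
    lapply(reports, function(r)
      r[c("embryo_id", "final_status", "direct_call", "indirect_status",
          "concordance", "policy", "flags")]),
    file.path(out_dir, "reports.json"), auto_unbox = TRUE, pretty = TRUE,
    force = TRUE)
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(embryo_id = r$embryo_id, final_status = r$final_status,
               direct_call = r$direct_call,
               indirect_status = r$indirect_status,
               concordance = r$concordance %||% NA_character_)))
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_info(out_dir, "diagnose", opts, NA)
  invisible(0L)
}

pipeline_qc <- function(opts) {
  panel <- load_panel_opt(opts)
  out_dir <- require_opt(opts, "out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  observed <- as_sample_genotypes(
    read_genotypes(require_opt(opts, "observed"), panel), panel)
  truth <- as_sample_genotypes(
    read_genotypes(require_opt(opts, "truth"), panel), panel)
  ado <- estimate_ado_rates(observed, truth, panel)
  utils::write.table(ado, file.path(out_dir, "ado_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fail <- estimate_failure_rates(observed, panel)
  utils::write.table(fail$per_marker, file.path(out_dir, "failure_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_info(out_dir, "qc", opts, NA)
  invisible(0L)
}

#' Run a pipeline subcommand
#'
#' Dispatches `simulate`, `mine`, `stats`, `phase`, `diagnose`, or `qc`
#' with command-line style arguments (e.g.
#' `run_pipeline(c("simulate", "--trio", "--embryos", "5", "--seed", "7",
#' "--out", "outdir"))`). All outputs are deterministic given `--seed`;
#' each run writes a `run_info.json` with the tool version, seed, and a
#' configuration hash.
#'
#' @param args Character vector of arguments (subcommand first).
#' @return Invisibly, exit status 0; validation problems raise classed
#'   errors (the shipped `inst/scripts/pgtsma.R` wrapper converts them to
#'   a non-zero exit status).
#' @export
run_pipeline <- function(args) {
  parsed <- parse_cli_args(args)
  switch(parsed$command,
         simulate = pipeline_simulate(parsed$opts),
         mine = pipeline_mine(parsed$opts),
         stats = pipeline_stats(parsed$opts),
         phase = pipeline_phase(parsed$opts),
         diagnose = pipeline_diagnose(parsed$opts),
         qc = pipeline_qc(parsed$opts),
         stop_pgtsma(sprintf("unknown subcommand '%s'", parsed$command),
                     "pgtsma_usage_error"))
}
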