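# run configuration and the full ordered pipeline

.CONFIG_DEFAULTS <- list(
  min_count = 5L, min_samples = 3L,          # prevalence filter
  lfc_cut = 1, alpha = 0.05,                 # DE significance cutoffs
  intron_nt = 200L, exon_nt = 10L,           # biogenesis window
  across_bsj_w = 11L,                        # junction read-through span
  mirna_min_total = 6L, mirna_min_wc = 5L, mirna_max_wobble = 1L,
  mirna_min_mean = 10,                       # miRNA expression filter
  count_mode = "max",                        # cross-tool aggregation
  traits = NULL,                             # GWAS trait regex
  n_random = NULL,                           # background size (default: n filtered)
  seed = 1L
)

#' Validate and resolve a run configuration
#'
#' Reads a YAML configuration, injects documented defaults for absent keys,
#' resolves relative paths against the configuration file's directory, and
#' checks that every referenced file exists — all problems are reported in one
#' error.
#'
#' Required keys: `genome`, `gtf`, `design`, and a non-empty `tools` mapping of
#' tool name to `dialect` and `files` (sample -> path). Optional inputs:
#' `motif_db`, `mirna_fasta`, `mirna_expression`, `gwas`, `rmsk`, `chain`,
#' plus any threshold listed in the package defaults.
#'
#' @param path YAML configuration file, or a pre-parsed list (then `base_dir`
#'   must be given).
#' @param base_dir directory against which relative paths resolve.
#' @return a resolved configuration list of class `run_config`.
#' @export
validate_config <- function(path, base_dir = NULL) {
  if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- yaml::read_yaml(path)
    base_dir <- base_dir %||% dirname(normalizePath(path))
  } else {
    cfg <- path
    if (is.null(base_dir)) abort("base_dir required when passing a parsed config")
  }
  for (k in names(.CONFIG_DEFAULTS)) {
    if (is.null(cfg[[k]])) cfg[k] <- .CONFIG_DEFAULTS[k]
  }

  problems <- character()
  need <- function(key) {
    if (is.null(cfg[[key]])) problems <<- c(problems, sprintf("missing required key '%s'", key))
  }
  need("genome"); need("gtf"); need("design")
  if (is.null(cfg$tools) || length(cfg$tools) == 0) {
    problems <- c(problems, "missing required key 'tools' (at least one tool)")
  }
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    full <- if (startsWith(f, "/")) f else file.path(base_dir, f)
    if (!file.exists(full)) problems <<- c(problems, sprintf("file not found: %s", full))
    full
  }
  for (k in c("genome", "gtf", "design", "motif_db", "mirna_fasta",
              "mirna_expression", "gwas", "rmsk", "chain")) {
    cfg[[k]] <- resolve(cfg[[k]])
  }
  known <- default_dialects()
  for (tool in names(cfg$tools)) {
    tl <- cfg$tools[[tool]]
    dname <- tl$dialect %||% tool
    if (!dname %in% names(known)) {
      problems <- c(problems, sprintf("tool '%s': unknown dialect '%s'", tool, dname))
    }
    if (is.null(tl$files) || length(tl$files) == 0) {
      problems <- c(problems, sprintf("tool '%s': no files", tool))
    } else {
      cfg$tools[[tool]]$files <- lapply(tl$files, resolve)
    }
    cfg$tools[[tool]]$dialect <- dname
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n", paste(" -", problems, collapse = "\n")))
  }
  structure(cfg, class = "run_config")
}

#' Run the full circRNA analysis pipeline
#'
#' Executes, in order: import of every (tool, sample) prediction file, merging,
#' antisense flagging and exclusion, prevalence filtering, NB differential
#' expression (first two design conditions), annotation, coordinate lifting
#' (when a chain file is configured), random-BSJ background generation,
#' sequence extraction (internal, across-junction, biogenesis windows), motif
#' enrichment of the filtered windows vs the random background, miRNA seed-site
#' scanning, and SNP/repeat flank annotation. Every stage writes a TSV/FASTA
#' into `outdir`; a resolved-configuration echo is written for provenance.
#' Given the same configuration and seed, outputs are byte-identical.
#'
#' @param config path to a YAML configuration or a `run_config`.
#' @param outdir output directory.
#' @return named list of the main result tibbles, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(outdir, ...)
  echo <- unclass(cfg)
  echo$tools <- lapply(echo$tools, function(t) {
    t$files <- lapply(t$files, basename); t
  })
  for (k in c("genome", "gtf", "design", "motif_db", "mirna_fasta",
              "mirna_expression", "gwas", "rmsk", "chain")) {
    if (!is.null(echo[[k]])) echo[[k]] <- basename(echo[[k]])
  }
  yaml::write_yaml(echo, o("resolved_config.yml"))

  design <- read_experiment_design(cfg$design)
  model <- load_gtf(cfg$gtf)
  genome <- load_genome(cfg$genome)
  dialects <- default_dialects()

  parsed <- list()
  for (tool in names(cfg$tools)) {
    tl <- cfg$tools[[tool]]
    for (s in names(tl$files)) {
      parsed[[length(parsed) + 1]] <-
        parse_tool_output(tl$files[[s]], dialects[[tl$dialect]], s)
    }
  }
  merged <- merge_predictions(parsed)
  merged <- flag_antisense(merged, model)
  write_bsj_tsv(merged, o("merged.tsv"))

  sense <- merged |> filter(!.data$antisense)
  mat <- collapse_counts(sense, design, mode = cfg$count_mode)
  filtered <- filter_circs(mat, design, cfg$min_count, cfg$min_samples)
  readr::write_tsv(filtered, o("filtered_counts.tsv"))
  keep <- sense |> filter(.data$circ_id %in% filtered$circ_id)

  de <- nb_wald_test(filtered, design, lfc_cut = cfg$lfc_cut, alpha_cut = cfg$alpha)
  readr::write_tsv(tidy(de), o("de.tsv"))

  lift <- NULL
  if (!is.null(cfg$chain)) {
    chains <- parse_chain(cfg$chain)
    lift <- lift_bsj(keep, chains)
    readr::write_tsv(lift, o("liftover.tsv"))
  }

  ann <- suppressWarnings(annotate_circs(keep, model))
  write_annotation_tsv(ann, o("annotation.tsv"))
  readr::write_tsv(circs_per_gene(ann), o("circs_per_gene.tsv"))

  n_random <- cfg$n_random %||% nrow(keep)
  random <- generate_random_bsjs(model, n_random, exclude = merged$circ_id,
                                 seed = cfg$seed)
  write_bsj_tsv(random, o("random_bsjs.tsv"))
  random_ann <- annotate_circs(random, model)

  internal <- extract_internal(ann, genome)
  write_seq_fasta(internal, o("internal.fa"))
  across <- extract_across_bsj(internal, w = cfg$across_bsj_w)
  write_seq_fasta(across, o("across_bsj.fa"))
  windows <- suppressWarnings(
    extract_flanks(ann, genome, "window", cfg$intron_nt, cfg$exon_nt))
  write_seq_fasta(windows, o("windows.fa"))
  random_windows <- suppressWarnings(
    extract_flanks(random_ann, genome, "window", cfg$intron_nt, cfg$exon_nt))
  write_seq_fasta(random_windows, o("random_windows.fa"))

  enrich <- NULL
  if (!is.null(cfg$motif_db) && nrow(windows) > 0 && nrow(random_windows) > 0) {
    motifs <- read_motif_db(cfg$motif_db)
    enrich <- motif_enrichment(windows, random_windows, motifs)
    readr::write_tsv(as_tibble(enrich), o("motif_enrichment.tsv"))
  }

  sites <- NULL
  if (!is.null(cfg$mirna_fasta)) {
    mirnas <- read_mirna_fasta(cfg$mirna_fasta)
    if (!is.null(cfg$mirna_expression)) {
      expr <- readr::read_tsv(cfg$mirna_expression, show_col_types = FALSE)
      mirnas <- suppressWarnings(
        filter_mirnas(mirnas, expr, min_mean = cfg$mirna_min_mean))
    }
    sites <- find_sites(internal, mirnas, cfg$mirna_min_total,
                        cfg$mirna_min_wc, cfg$mirna_max_wobble)
    readr::write_tsv(sites, o("mirna_sites.tsv"))
  }

  flanks <- NULL
  if (!is.null(cfg$gwas) || !is.null(cfg$rmsk)) {
    features <- bind_rows(
      if (!is.null(cfg$gwas)) read_gwas_tsv(cfg$gwas, traits = cfg$traits),
      if (!is.null(cfg$rmsk)) read_rmsk_tsv(cfg$rmsk))
    flanks <- annotate_flanks(ann, features, region = "introns")
    readr::write_tsv(flanks, o("flank_features.tsv"))
    pairs <- complementary_pairs(flanks)
    readr::write_tsv(pairs$pairs, o("complementary_pairs.tsv"))
    readr::write_tsv(summarize_flanks(flanks, pairs), o("flank_summary.tsv"))
  }

  invisible(list(merged = merged, filtered = filtered, de = de, lift = lift,
                 annotation = ann, random = random, internal = internal,
                 windows = windows, enrichment = enrich, mirna_sites = sites,
                 flanks = flanks))
}
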