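## Orchestration: the two end-to-end workflows, driven by a plain config
## list (or YAML file). Every run with an output directory writes its
## resolved configuration next to the results for provenance.

#' Default pipeline configuration
#'
#' All tunable parameters of the two workflows with their documented
#' defaults. Paths are `NULL` until supplied; any field can be overridden
#' via `...` or a YAML file.
#'
#' @param ... overrides (name = value).
#' @return config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome = NULL, tss = NULL, matrices = NULL, de_table = NULL,
    ncounter_counts = NULL, ncounter_roles = NULL, ncounter_meta = NULL,
    window = c(-600L, 100L), upstream_depth = 20000L,
    min_mss = 0.85, min_core = 0.99,
    min_fold = 2, max_p = 0.01, direction = "both",
    min_enrichment = 1, max_p_adj = 0.005, min_genes = 5L, min_pct = 25,
    background_n = 1000L, include_truncated = TRUE,
    n_references = 7L, repression_threshold = 0.20,
    treated = NULL, mock = NULL,
    seed = 1L, outdir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML path; keys override [pipeline_config()] defaults.
#' @return config list.
#' @export
read_pipeline_config <- function(file) {
  do.call(pipeline_config, yaml::read_yaml(file))
}

.write_resolved_config <- function(cfg, outdir) {
  keep <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(keep, file.path(outdir, "resolved_config.yaml"))
}

.require_paths <- function(cfg, fields) {
  for (f in fields) {
    if (is.null(cfg[[f]]))
      stop("config field '", f, "' is required")
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "': file not found: ", cfg[[f]])
  }
}

#' Run the promoter enrichment workflow
#'
#' Extract promoters, deduplicate, select regulated genes from the
#' differential table, sample the random background, scan all matrices,
#' test per-matrix enrichment with BH correction and pass criteria, and
#' collapse redundant matrices. With `outdir` set, writes the enrichment
#' table, hit table and resolved configuration as TSV/YAML.
#'
#' Config fields used: `genome` (FASTA path or named character), `tss`
#' (BED6 path or data.frame), `matrices` (TRANSFAC path or list of
#' [pwm]s), `de_table` (TSV path or data.frame), plus the thresholds and
#' window fields of [pipeline_config()].
#'
#' @param cfg config list from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return list with `enrichment` (collapsed [motif_enrichment_table()]),
#'   `enrichment_full` (uncollapsed), `hits`, `foreground`, `background`,
#'   `promoters`.
#' @export
run_enrichment <- function(cfg) {
  for (f in c("genome", "tss", "matrices", "de_table"))
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
  for (f in c("genome", "tss", "matrices", "de_table"))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "': file not found: ", cfg[[f]])

  genome <- if (is.character(cfg$genome) && length(cfg$genome) == 1L &&
                file.exists(cfg$genome))
    read_genome_fasta(cfg$genome) else cfg$genome
  tss <- if (is.character(cfg$tss)) read_tss_bed(cfg$tss) else cfg$tss
  pwms <- if (is.character(cfg$matrices)) parse_transfac(cfg$matrices)
          else cfg$matrices
  de <- if (is.character(cfg$de_table))
    utils::read.table(cfg$de_table, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else cfg$de_table

  prom <- extract_promoters(genome, tss, cfg$window)
  prom <- deduplicate_promoters(prom)
  if (!cfg$include_truncated)
    prom <- prom[!prom$truncated, , drop = FALSE]

  fg <- intersect(
    select_regulated(de, cfg$min_fold, cfg$max_p, cfg$direction),
    prom$gene_id)
  if (length(fg) < 2L)
    stop("fewer than 2 regulated genes with promoters; nothing to test")
  bg <- sample_background(prom$gene_id, fg,
                          min(cfg$background_n,
                              length(setdiff(prom$gene_id, fg))),
                          seed = cfg$seed)

  th <- scan_thresholds(cfg$min_mss, cfg$min_core)
  sub <- prom[prom$gene_id %in% c(fg, bg), , drop = FALSE]
  hits <- scan_promoters(pwms, sub, th)

  full <- motif_enrichment_table(hits, fg, bg, cfg$window,
                                 matrices = vapply(pwms, `[[`, "",
                                                   "matrix_id"),
                                 min_enrichment = cfg$min_enrichment,
                                 max_p_adj = cfg$max_p_adj,
                                 min_genes = cfg$min_genes,
                                 min_pct = cfg$min_pct)
  collapsed <- collapse_redundant(full)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(full),
                       file.path(cfg$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(collapsed),
                       file.path(cfg$outdir, "enrichment_collapsed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_hits(hits, file.path(cfg$outdir, "hits.tsv"))
    .write_resolved_config(cfg, cfg$outdir)
  }
  list(enrichment = collapsed, enrichment_full = full, hits = hits,
       foreground = fg, background = bg, promoters = prom)
}

#' Run the nCounter workflow
#'
#' Background-correct, select the most stable references, normalize to
#' their geometric mean and call repression between the treated and mock
#' samples. With `outdir` set, writes normalized counts, repression calls
#' and the resolved configuration.
#'
#' Config fields used: `ncounter_counts`, `ncounter_roles`,
#' `ncounter_meta` (TSV paths; or pass a ready [ncounter_run] as `run`),
#' `n_references`, `repression_threshold`, `treated`, `mock` (sample name
#' vectors; default: samples whose metadata `treatment` is not `"mock"`
#' vs those where it is).
#'
#' @param cfg config list.
#' @param run optional pre-built [ncounter_run] (overrides the paths).
#' @return list with `run` (processed), `calls` (named logical),
#'   `references`.
#' @export
run_ncounter <- function(cfg, run = NULL) {
  if (is.null(run)) {
    .require_paths(cfg, c("ncounter_counts", "ncounter_roles"))
    run <- read_ncounter_tsv(cfg$ncounter_counts, cfg$ncounter_roles,
                             cfg$ncounter_meta)
  }
  run <- normalize_ncounter(run, k = cfg$n_references)
  treated <- cfg$treated
  mock <- cfg$mock
  if (is.null(treated) || is.null(mock)) {
    if (is.null(run$meta))
      stop("supply 'treated' and 'mock' sample names or sample metadata")
    mock <- rownames(run$meta)[run$meta$treatment == "mock"]
    treated <- rownames(run$meta)[run$meta$treatment != "mock"]
  }
  calls <- call_repression(run, treated, mock,
                           threshold = cfg$repression_threshold)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_ncounter_tsv(run,
                       file.path(cfg$outdir, "ncounter_normalized.tsv"),
                       file.path(cfg$outdir, "repression_calls.tsv"),
                       calls)
    .write_resolved_config(cfg, cfg$outdir)
  }
  list(run = run, calls = calls, references = run$references)
}
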