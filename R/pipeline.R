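# End-to-end orchestration: simulate (or load) the cohort, run every stage,
# write every intermediate table, and record a manifest with checksums so a
# rerun at the same seed is verifiably identical.

#' Assemble a pipeline configuration
#'
#' Defaults reproduce the pipeline's reference thresholds: FDR 0.05 and the
#' 95th-percentile absolute effect-size gate, with at least 3 complete pairs
#' per probe. Either a simulation configuration or a table of per-study
#' input paths must be supplied.
#'
#' @param simulation A [simulation_config()], or `NULL` when reading files.
#' @param studies Data frame with columns `matrix`, `metadata`,
#'   `annotation`, and optionally `study_id`, `phenotype`; or `NULL` when
#'   simulating.
#' @param output_dir Directory for all stage outputs.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param effect_percentile Effect-size percentile (default 95).
#' @param min_pairs Minimum complete pairs per probe statistic (default 3).
#' @param min_pairs_study Studies with fewer pairs draw a validation
#'   warning (default 10, matching the reference cohort's inclusion rule);
#'   they are still analyzed.
#' @param stratify_sex Run male/female stratified analyses when sex labels
#'   are present (default `TRUE`).
#' @param seed Seed recorded in the manifest (and forwarded to the
#'   simulator when `simulation` carries none).
#' @return List of class `twindiff_config`.
#' @export
pipeline_config <- function(simulation = NULL, studies = NULL,
                            output_dir = tempfile("twindiff_run"),
                            fdr_alpha = 0.05, effect_percentile = 95,
                            min_pairs = 3L, min_pairs_study = 10L,
                            stratify_sex = TRUE, seed = 1L) {
  if (is.null(simulation) && is.null(studies))
    stop("supply either a simulation config or study input paths",
         call. = FALSE)
  structure(list(simulation = simulation, studies = studies,
                 output_dir = output_dir, fdr_alpha = fdr_alpha,
                 effect_percentile = effect_percentile,
                 min_pairs = as.integer(min_pairs),
                 min_pairs_study = as.integer(min_pairs_study),
                 stratify_sex = isTRUE(stratify_sex),
                 seed = as.integer(seed)),
            class = "twindiff_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s fields; a `simulation:` block
#' mirrors [simulation_config()]'s fields.
#'
#' @param path YAML file.
#' @return A `twindiff_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  studies <- if (!is.null(y$studies))
    do.call(rbind, lapply(y$studies, as.data.frame))
  args <- y[setdiff(names(y), c("simulation", "studies"))]
  do.call(pipeline_config, c(list(simulation = sim, studies = studies), args))
}

#' Run the full discordant-twin pipeline
#'
#' Stages, in order: cohort acquisition (simulation or file loading),
#' per-study probe statistics, gene-level summarization, per-study
#' significance selection, pairwise overlap and Spearman tables, per-gene
#' DerSimonian-Laird meta-analysis with overall selection, optional
#' sex-stratified re-analysis. Every stage's table is written to
#' `output_dir` and listed with its MD5 checksum in `manifest.tsv`;
#' identical configuration and seed give identical checksums.
#'
#' @param config A `twindiff_config` (or path to its YAML).
#' @return List of class `twindiff_run`: `config`, `studies`, `probe_tables`,
#'   `gene_tables`, `significance`, `overlaps`, `spearman`, `meta`,
#'   `overall`, `stratified` (or `NULL`), `manifest`, `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "twindiff_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  files <- character()

  # stage 1: cohort
  truth <- NULL
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    truth <- cohort$truth
    studies <- cohort$studies
  } else {
    s <- config$studies
    studies <- lapply(seq_len(nrow(s)), function(i)
      read_expression(s$matrix[i], s$metadata[i], s$annotation[i],
                      study_id = s$study_id[i], phenotype = s$phenotype[i]))
  }
  small <- vapply(studies, function(st) nrow(st$pairs), 0L) <
    config$min_pairs_study
  if (any(small))
    warning(sprintf("study with fewer than %d twin pairs: %s",
                    config$min_pairs_study,
                    paste(vapply(studies[small], `[[`, "", "study_id"),
                          collapse = ", ")), call. = FALSE)

  # stage 2-3: probe statistics and gene-level summaries
  probe_tables <- list(); gene_tables <- list()
  for (st in studies) {
    pt <- study_probe_table(st, min_pairs = config$min_pairs)
    probe_tables[[st$study_id]] <- pt
    f <- out(sprintf("probes_%s.tsv", st$study_id))
    write_results(pt, f); files <- c(files, f)
    gt <- summarize_study(pt, st$annotation, st$study_id)
    gene_tables[[st$study_id]] <- gt
    f <- out(sprintf("genes_%s.tsv", st$study_id))
    write_results(gt, f); files <- c(files, f)
  }

  # stage 4: per-study significance
  significance <- lapply(gene_tables, select_significant,
                         alpha = config$fdr_alpha,
                         percentile = config$effect_percentile)
  sig_df <- do.call(rbind, c(lapply(significance, function(r)
    data.frame(study_id = r$study_id, threshold_95 = r$threshold_95,
               n_tested = r$n_tested,
               n_significant = length(r$significant_genes),
               significant_genes = paste(r$significant_genes,
                                         collapse = ","),
               stringsAsFactors = FALSE)), make.row.names = FALSE))
  f <- out("significant.tsv"); write_results(sig_df, f)
  files <- c(files, f)

  # stage 5: pairwise integration
  overlaps <- NULL; spear <- NULL
  if (length(studies) >= 2L) {
    overlaps <- overlap_table(significance)
    f <- out("pairwise_overlap.tsv"); write_results(overlaps, f)
    files <- c(files, f)
    spear <- spearman_table(gene_tables)
    f <- out("pairwise_spearman.tsv"); write_results(spear, f)
    files <- c(files, f)
  }

  # stage 6: per-gene meta-analysis and overall selection
  meta <- meta_analyze(gene_tables)
  f <- out("meta_genes.tsv"); write_results(meta, f)
  files <- c(files, f)
  overall <- overall_selection(meta, alpha = config$fdr_alpha,
                               percentile = config$effect_percentile)
  i2 <- sort(meta$I2)
  ecdf_df <- data.frame(I2 = i2, ecdf = seq_along(i2) / length(i2))
  f <- out("ecdf_i2.tsv"); write_results(ecdf_df, f)
  files <- c(files, f)

  # stage 7: sex-stratified runs
  stratified <- NULL
  if (config$stratify_sex &&
      any(vapply(studies, function(st) !is.null(st$sex), TRUE))) {
    stratified <- list()
    for (sx in c("male", "female")) {
      run <- tryCatch(
        stratified_analysis(studies, sx, alpha = config$fdr_alpha,
                            percentile = config$effect_percentile,
                            min_pairs = config$min_pairs),
        error = function(e) NULL)
      if (is.null(run)) next
      stratified[[sx]] <- run
      f <- out(sprintf("meta_genes_%s.tsv", sx))
      write_results(run$meta, f); files <- c(files, f)
    }
    if (length(stratified) == 2L)
      stratified$overlap <- cross_sex_overlap(stratified$male,
                                              stratified$female)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = config$seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    n_studies = length(studies),
    per_study_significant = vapply(significance, function(r)
      length(r$significant_genes), 0L),
    n_overall_significant = length(overall$selected),
    n_heterogeneous = length(overall$heterogeneous),
    n_genes_universe = nrow(meta))

  structure(list(config = config, studies = studies, truth = truth,
                 probe_tables = probe_tables, gene_tables = gene_tables,
                 significance = significance, overlaps = overlaps,
                 spearman = spear, meta = meta, overall = overall,
                 stratified = stratified, manifest = manifest,
                 summary = summary),
            class = "twindiff_run")
}

#' @export
print.twindiff_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("twindiff run: %d studies, %d genes in meta universe\n",
              s$n_studies, s$n_genes_universe))
  cat("  per-study significant:",
      paste(sprintf("%s=%d", names(s$per_study_significant),
                    s$per_study_significant), collapse = " "), "\n")
  cat(sprintf("  overall significant: %d; heterogeneous (QEp FDR<%g): %d\n",
              s$n_overall_significant, x$config$fdr_alpha,
              s$n_heterogeneous))
  invisible(x)
}
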