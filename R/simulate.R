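#' Reference design of the seven-study twin cohort
#'
#' The multi-study discordant-twin compendium the pipeline targets: seven
#' phenotypes assayed on different microarray platforms, 10 to 44 pairs per
#' study (92 pairs in the five GEO studies), partially overlapping gene
#' panels, and sex labels available for three studies (CFS, MDD, OB).
#' The simulation defaults are drawn from this table.
#'
#' @return Data frame with one row per study: `study_id`, `phenotype`,
#'   `n_pairs`, `n_genes`, `platform`, `source`, `sex_labelled`.
#' @export
twin_cohort_design <- function() {
  data.frame(
    study_id = c("GSE22619", "GSE16059", "GSE20319", "GSE33476",
                 "GSE37146", "phs000486", "E-MEXP-1425"),
    phenotype = c("UC", "CFS", "PA", "IQ", "IAR_invitro", "MDD", "OB"),
    n_pairs = c(10L, 44L, 10L, 17L, 11L, 28L, 13L),
    n_genes = c(22836L, 22836L, 19429L, 18638L, 19580L, 19284L, 22836L),
    platform = c("GPL570", "GPL570", "GPL6884", "GPL6244", "GPL6102",
                 "GPL13667", "GPL570"),
    source = c("GEO", "GEO", "GEO", "GEO", "GEO", "dbGaP", "ArrayExpress"),
    sex_labelled = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic twin-cohort generator
#'
#' Defaults emulate the reference seven-study compendium
#' ([twin_cohort_design()]): its pair counts, a 25,000-gene universe with
#' 80% platform coverage (about 20,000 genes per study, 18.6k-22.8k in the
#' reference), 1-4 probes per gene, and sex labels in the three studies that
#' carry them. Effects are additive on the native intensity scale.
#'
#' @param n_studies Number of studies.
#' @param pairs_per_study Integer vector (recycled) of twin pairs per study;
#'   each entry must be at least 3.
#' @param n_genes_universe Size of the shared gene universe.
#' @param platform_coverage Probability that a universe gene is on a study's
#'   panel; panels are drawn independently per study.
#' @param probes_per_gene Integer vector of admissible probe counts per gene
#'   (sampled uniformly).
#' @param frac_affected_genes Fraction of universe genes with a nonzero
#'   phenotype effect.
#' @param effect_mean_sd SD of the per-gene mean effect `mu_g` (intensity
#'   units); affected genes draw `mu_g ~ N(0, effect_mean_sd^2)`.
#' @param tau Cross-study effect SD: study-level effects
#'   `delta_gs ~ N(mu_g, tau^2)` for affected genes, 0 for null genes.
#' @param noise_sd Residual SD per measurement; within-pair differences have
#'   variance `2 * noise_sd^2`.
#' @param pair_effect_sd SD of the shared pair-level random effect (cancels
#'   in within-pair differences).
#' @param probe_offset_sd SD of the additive per-probe offset (also cancels
#'   in differences, so all probes of a gene share one true effect).
#' @param baseline_mean,baseline_sd Per-gene baseline intensity distribution.
#' @param missing_rate Probability a single measurement is missing at random.
#' @param sex_labelled_studies Indices of studies that carry sex labels.
#' @param phenotypes Phenotype labels (recycled to `n_studies`).
#' @param seed Integer seed fixing every draw.
#'
#' @return A validated list of class `twin_sim_config`.
#' @export
simulation_config <- function(n_studies = 7L,
                              pairs_per_study = twin_cohort_design()$n_pairs,
                              n_genes_universe = 25000L,
                              platform_coverage = 0.8,
                              probes_per_gene = 1:4,
                              frac_affected_genes = 0.05,
                              effect_mean_sd = 1,
                              tau = 0.25,
                              noise_sd = 1,
                              pair_effect_sd = 1,
                              probe_offset_sd = 0.5,
                              baseline_mean = 100,
                              baseline_sd = 25,
                              missing_rate = 0,
                              sex_labelled_studies =
                                which(twin_cohort_design()$sex_labelled),
                              phenotypes = twin_cohort_design()$phenotype,
                              seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    pairs_per_study = rep_len(as.integer(pairs_per_study), n_studies),
    n_genes_universe = as.integer(n_genes_universe),
    platform_coverage = platform_coverage,
    probes_per_gene = as.integer(probes_per_gene),
    frac_affected_genes = frac_affected_genes,
    effect_mean_sd = effect_mean_sd,
    tau = tau,
    noise_sd = noise_sd,
    pair_effect_sd = pair_effect_sd,
    probe_offset_sd = probe_offset_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    missing_rate = missing_rate,
    sex_labelled_studies = intersect(as.integer(sex_labelled_studies),
                                     seq_len(n_studies)),
    phenotypes = rep_len(as.character(phenotypes), n_studies),
    seed = as.integer(seed))
  class(cfg) <- "twin_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "twin_sim_config"))
  if (cfg$n_studies < 1L) stop("n_studies must be >= 1", call. = FALSE)
  if (any(cfg$pairs_per_study < 3L))
    stop("each study needs at least 3 twin pairs", call. = FALSE)
  if (cfg$n_genes_universe < 1L)
    stop("n_genes_universe must be >= 1", call. = FALSE)
  if (cfg$platform_coverage <= 0 || cfg$platform_coverage > 1)
    stop("platform_coverage must be in (0, 1]", call. = FALSE)
  if (any(cfg$probes_per_gene < 1L))
    stop("probes_per_gene entries must be >= 1", call. = FALSE)
  if (cfg$frac_affected_genes < 0 || cfg$frac_affected_genes > 1)
    stop("frac_affected_genes must be in [0, 1]", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  sds <- c(cfg$effect_mean_sd, cfg$tau, cfg$noise_sd, cfg$pair_effect_sd,
           cfg$probe_offset_sd, cfg$baseline_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-study discordant-twin cohort with known ground truth
#'
#' Generative model, on the native intensity scale: for study *s*, gene *g*
#' on its panel, probe *k* of *g*, pair *i* and twin *t*,
#' `value = baseline_g + offset_k + pair_i + [t affected] * delta_gs + eps`,
#' with `eps ~ N(0, noise_sd^2)` and `delta_gs ~ N(mu_g, tau^2)` for affected
#' genes (0 for null genes). Pair effects and probe offsets cancel in
#' within-pair differences, so the within-pair difference for any probe of
#' gene *g* is `N(delta_gs, 2 * noise_sd^2)` — the sampling model the paired
#' t statistic assumes. All draws come from one generator seeded with
#' `config$seed`; the same configuration reproduces the cohort exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (list of `ExpressionStudy`) and `truth`, a
#'   list holding the per-gene affected flags and `mu_g`, the realized
#'   per-study effects `delta` (genes x studies, `NA` where unmeasured),
#'   and the `tau` used.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes_universe
  genes <- sprintf("G%05d", seq_len(G))
  n_aff <- round(config$frac_affected_genes * G)
  affected <- rep(FALSE, G)
  if (n_aff > 0) affected[sample.int(G, n_aff)] <- TRUE
  mu <- numeric(G)
  mu[affected] <- stats::rnorm(n_aff, 0, config$effect_mean_sd)
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)

  delta <- matrix(NA_real_, G, config$n_studies,
                  dimnames = list(genes, NULL))
  studies <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("SIM%02d", s)
    on_panel <- stats::runif(G) < config$platform_coverage
    panel <- which(on_panel)
    if (!length(panel)) stop("empty study panel; raise platform_coverage",
                             call. = FALSE)
    d <- numeric(length(panel))
    aff_panel <- affected[panel]
    d[aff_panel] <- stats::rnorm(sum(aff_panel), mu[panel][aff_panel],
                                 config$tau)
    delta[panel, s] <- d

    npp <- if (length(config$probes_per_gene) == 1L)
      rep(config$probes_per_gene, length(panel))
    else sample(config$probes_per_gene, length(panel), replace = TRUE)
    probe_gene <- rep(panel, npp)          # universe gene index per probe
    P <- length(probe_gene)
    probe_ids <- sprintf("%s_P%06d", sid, seq_len(P))
    offsets <- stats::rnorm(P, 0, config$probe_offset_sd)

    n <- config$pairs_per_study[s]
    pair_ids <- sprintf("%s_pair%02d", sid, seq_len(n))
    aff_ids <- paste0(pair_ids, "_A")
    una_ids <- paste0(pair_ids, "_U")
    pair_eff <- stats::rnorm(n, 0, config$pair_effect_sd)

    d_probe <- d[match(probe_gene, panel)]
    base_p <- baseline[probe_gene] + offsets
    vals <- matrix(stats::rnorm(P * 2L * n, 0, config$noise_sd), P, 2L * n)
    vals <- vals + base_p                       # recycles down columns
    vals <- sweep(vals, 2L, rep(pair_eff, each = 2L), "+")
    aff_cols <- seq(1L, 2L * n, by = 2L)
    vals[, aff_cols] <- vals[, aff_cols] + d_probe
    colnames(vals) <- c(rbind(aff_ids, una_ids))
    rownames(vals) <- probe_ids
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(vals)) < config$missing_rate
      vals[drop] <- NA_real_
    }

    sex <- NULL
    if (s %in% config$sex_labelled_studies) {
      sex <- stats::setNames(
        c("male", "female")[1L + (stats::runif(n) < 0.5)], pair_ids)
    }
    studies[[s]] <- expression_study(
      sid, config$phenotypes[s], vals,
      data.frame(pair_id = pair_ids, affected = aff_ids,
                 unaffected = una_ids, stringsAsFactors = FALSE),
      sex = sex,
      annotation = data.frame(probe_id = probe_ids,
                              gene_symbol = genes[probe_gene],
                              stringsAsFactors = FALSE))
  }
  colnames(delta) <- vapply(studies, `[[`, "", "study_id")
  list(studies = studies,
       truth = list(gene = genes, affected = affected, mu = mu,
                    delta = delta, tau = config$tau, seed = config$seed))
}

#' Write a simulated cohort to disk as TSV triples
#'
#' Emits one (matrix, metadata, annotation) TSV triple per study plus a
#' ground-truth table and a manifest listing every file with its MD5
#' checksum and the seed used.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param directory Output directory (created if absent).
#' @return The manifest data frame, invisibly; also written as
#'   `manifest.tsv`.
#' @export
emit_cohort_files <- function(cohort, directory) {
  if (!length(cohort$studies)) stop("empty cohort", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (st in cohort$studies) {
    stem <- file.path(directory, st$study_id)
    mp <- paste0(stem, "_matrix.tsv")
    mat <- data.frame(probe_id = rownames(st$values),
                      st$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(mat, mp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    md <- data.frame(
      sample_id = c(st$pairs$affected, st$pairs$unaffected),
      pair_id = rep(st$pairs$pair_id, 2L),
      status = rep(c("affected", "unaffected"), each = nrow(st$pairs)),
      stringsAsFactors = FALSE)
    if (!is.null(st$sex)) md$sex <- unname(st$sex[md$pair_id])
    dp <- paste0(stem, "_metadata.tsv")
    utils::write.table(md, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    ap <- paste0(stem, "_annotation.tsv")
    utils::write.table(st$annotation, ap, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files <- c(files, mp, dp, ap)
  }
  tp <- file.path(directory, "truth.tsv")
  tr <- cohort$truth
  truth_df <- data.frame(gene = tr$gene, affected = tr$affected,
                         mu = tr$mu, tr$delta, check.names = FALSE,
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  files <- c(files, tp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = tr$seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
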