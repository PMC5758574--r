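# Sex-stratified re-analysis. MZ twins share sex, so sex is a pair-level
# attribute; each labelled study is restricted to pairs of the requested
# sex and the identical per-study + meta-analytic pipeline is re-run,
# recomputing effect-size thresholds within the stratified run.

#' Run the full pipeline on one sex stratum
#'
#' Keeps the studies that carry sex labels and have at least `min_pairs`
#' pairs of the requested sex, restricts each to those pairs, and re-runs
#' paired statistics, gene-level summarization, per-study significance,
#' cross-study meta-analysis and overall selection.
#'
#' @param cohort List of `ExpressionStudy` objects.
#' @param sex `"male"` or `"female"`.
#' @param alpha FDR threshold, default 0.05.
#' @param percentile Effect-size percentile, default 95.
#' @param min_pairs Minimum same-sex pairs for a study to qualify
#'   (default 3).
#' @return List of class `StratifiedRun`: `sex`, `studies_used`,
#'   `gene_tables`, `significance` (per-study `SignificanceResult`s),
#'   `meta`, `overall` (see [overall_selection()]), and
#'   `overall_significant` (its `selected` set).
#' @export
stratified_analysis <- function(cohort, sex = c("male", "female"),
                                alpha = 0.05, percentile = 95,
                                min_pairs = 3L) {
  sex <- match.arg(sex)
  runs <- list()
  for (st in cohort) {
    if (is.null(st$sex)) next
    pid <- names(st$sex)[st$sex == sex]
    if (length(pid) < min_pairs) next
    runs[[st$study_id]] <- subset_pairs(st, pid)
  }
  if (!length(runs))
    stop(sprintf("no study qualifies for sex = '%s'", sex), call. = FALSE)
  gene_tables <- lapply(runs, function(st)
    summarize_study(study_probe_table(st, min_pairs = min_pairs),
                    st$annotation, st$study_id))
  gene_tables <- gene_tables[vapply(gene_tables, nrow, 0L) > 0L]
  significance <- lapply(gene_tables, select_significant,
                         alpha = alpha, percentile = percentile)
  meta <- meta_analyze(gene_tables)
  overall <- overall_selection(meta, alpha = alpha, percentile = percentile)
  structure(
    list(sex = sex, studies_used = names(gene_tables),
         gene_tables = gene_tables, significance = significance,
         meta = meta, overall = overall,
         overall_significant = overall$selected),
    class = "StratifiedRun")
}

#' Compare overall-significant sets between the sexes
#'
#' @param run_m,run_f `StratifiedRun` objects for the two sexes.
#' @return List: `n_male`, `n_female`, `n_shared`, `shared` (the
#'   intersection of the two overall-significant gene sets).
#' @export
cross_sex_overlap <- function(run_m, run_f) {
  shared <- intersect(run_m$overall_significant, run_f$overall_significant)
  list(n_male = length(run_m$overall_significant),
       n_female = length(run_f$overall_significant),
       n_shared = length(shared),
       shared = sort(shared))
}

#' @export
print.StratifiedRun <- function(x, ...) {
  cat(sprintf("StratifiedRun (%s): %d studies, %d overall-significant genes\n",
              x$sex, length(x$studies_used),
              length(x$overall_significant)))
  invisible(x)
}
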