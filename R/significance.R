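# Two-gate significance within each study: Benjamini-Hochberg FDR < 0.05
# AND absolute mean difference above the study's own 95th percentile. The
# effect-size gate keeps the per-study false positive rate low where pair
# counts are small.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j>=i} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Percentile effect-size threshold
#'
#' The 95th percentile (by default) of the absolute mean differences,
#' using linear interpolation between order statistics (quantile type 7).
#'
#' @param abs_diffs Non-empty vector of non-negative values.
#' @param percentile Percentile in (0, 100\], default 95.
#' @return The threshold (same units as the input).
#' @export
effect_threshold <- function(abs_diffs, percentile = 95) {
  if (!length(abs_diffs)) stop("empty effect-size list", call. = FALSE)
  if (any(abs_diffs < 0)) stop("absolute differences must be >= 0",
                               call. = FALSE)
  unname(stats::quantile(abs_diffs, percentile / 100, type = 7,
                         names = FALSE))
}

#' Select a study's significant genes
#'
#' Fills `q_value` by BH over all of the study's gene-level p-values and
#' selects genes with `q < alpha` AND `|mean_diff| >` the study's
#' `percentile`-th percentile of absolute mean differences (both gates
#' strict).
#'
#' @param gene_stats Data frame from [summarize_study()] — one study only.
#' @param alpha FDR threshold, default 0.05.
#' @param percentile Effect-size percentile, default 95.
#' @return List of class `SignificanceResult`: `study_id`, `threshold_95`,
#'   `significant_genes` (character vector), `n_tested`, `alpha_fdr`,
#'   `percentile`, and `gene_stats` with `q_value` filled.
#' @export
select_significant <- function(gene_stats, alpha = 0.05, percentile = 95) {
  if (!nrow(gene_stats)) stop("no genes to test", call. = FALSE)
  if (length(unique(gene_stats$study_id)) != 1L)
    stop("gene_stats mixes study IDs; select per study", call. = FALSE)
  gene_stats$q_value <- bh_fdr(gene_stats$p_value)
  thr <- effect_threshold(abs(gene_stats$mean_diff), percentile)
  sel <- gene_stats$q_value < alpha & abs(gene_stats$mean_diff) > thr
  structure(
    list(study_id = gene_stats$study_id[1L],
         threshold_95 = thr,
         significant_genes = sort(gene_stats$gene[sel]),
         n_tested = nrow(gene_stats),
         alpha_fdr = alpha,
         percentile = percentile,
         gene_stats = gene_stats),
    class = "SignificanceResult")
}

#' @export
print.SignificanceResult <- function(x, ...) {
  cat(sprintf(
    "SignificanceResult '%s': %d of %d genes (FDR < %g, |diff| > %.4g)\n",
    x$study_id, length(x$significant_genes), x$n_tested, x$alpha_fdr,
    x$threshold_95))
  invisible(x)
}
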