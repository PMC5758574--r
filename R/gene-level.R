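# Probe-to-gene summarization by inverse-variance fixed-effect pooling.
# Multiple probes of one gene interrogate the same samples with different
# binding affinities ("different measurement scales"); pooling their paired
# estimates gives one gene-level mean difference per study.

#' Inverse-variance fixed-effect pooling
#'
#' Pools k estimates with weights `w_j = 1/se_j^2`:
#' `pooled = sum(w m) / sum(w)`, `pooled_se = 1/sqrt(sum(w))`,
#' `z = pooled/pooled_se` with a two-sided standard-normal p-value.
#'
#' @param mean_diff Numeric vector of estimates.
#' @param se Positive standard errors, same length.
#' @return List with `pooled_mean`, `pooled_se`, `z`, `p_value`.
#' @export
fixed_effect_pool <- function(mean_diff, se) {
  if (!length(mean_diff)) stop("no estimates to pool", call. = FALSE)
  if (length(se) != length(mean_diff))
    stop("mean_diff and se lengths differ", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and > 0", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * mean_diff) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  list(pooled_mean = pooled, pooled_se = pse, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Summarize probe statistics to gene-level statistics for one study
#'
#' Joins `ok`-flagged probes to gene symbols (a probe annotated to several
#' genes contributes to each of them, marked `multi_mapped`), pools each
#' gene's probes with [fixed_effect_pool()], and ranks genes by descending
#' absolute mean difference (`abs_rank` 1 = largest; ties broken by gene
#' symbol, ascending). Genes whose probes are all flagged or unmapped are
#' omitted. Single-probe genes keep the probe's estimate and SE but receive
#' the same normal-reference p-value as pooled genes.
#'
#' @param probe_stats Data frame from [study_probe_table()].
#' @param annotation Data frame `probe_id`, `gene_symbol` (long form).
#' @param study_id Study label for the output.
#' @return Data frame with one row per gene: `gene`, `study_id`, `n_probes`,
#'   `multi_mapped`, `mean_diff`, `se`, `z_stat`, `p_value`, `q_value`
#'   (`NA` until [select_significant()] fills it), `abs_rank`; rows ordered
#'   by `abs_rank`.
#' @export
summarize_study <- function(probe_stats, annotation, study_id) {
  ok <- probe_stats[probe_stats$flag == "ok", , drop = FALSE]
  ann <- annotation[annotation$probe_id %in% ok$probe_id, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(gene = character(), study_id = character(),
                      n_probes = integer(), multi_mapped = logical(),
                      mean_diff = numeric(), se = numeric(),
                      z_stat = numeric(), p_value = numeric(),
                      q_value = numeric(), abs_rank = integer(),
                      stringsAsFactors = FALSE))
  idx <- match(ann$probe_id, ok$probe_id)
  m <- ok$mean_diff[idx]
  w <- 1 / ok$se[idx]^2
  multi <- ann$probe_id %in% ann$probe_id[duplicated(ann$probe_id)]

  g <- factor(ann$gene_symbol)
  sw <- rowsum(w, g)[, 1L]
  swm <- rowsum(w * m, g)[, 1L]
  n_probes <- as.integer(table(g))
  pooled <- swm / sw
  pse <- 1 / sqrt(sw)
  z <- pooled / pse
  multi_any <- rowsum(as.numeric(multi), g)[, 1L] > 0

  out <- data.frame(gene = levels(g), study_id = study_id,
                    n_probes = n_probes, multi_mapped = unname(multi_any),
                    mean_diff = unname(pooled), se = unname(pse),
                    z_stat = unname(z),
                    p_value = 2 * stats::pnorm(-abs(unname(z))),
                    q_value = NA_real_,
                    stringsAsFactors = FALSE)
  ord <- order(-abs(out$mean_diff), out$gene)
  out <- out[ord, , drop = FALSE]
  out$abs_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
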