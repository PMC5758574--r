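# Cross-phenotype integration: pairwise overlap of significant-gene sets,
# Spearman correlation of mean differences over co-measured genes, and a
# per-gene DerSimonian-Laird random-effects meta-analysis across studies
# with Cochran Q, tau^2, I^2 and the heterogeneity p-value (QEp).

#' DerSimonian-Laird random-effects meta-analysis for one gene
#'
#' Moment-based estimate of the between-study variance from Cochran's Q:
#' with fixed-effect weights `w_j = 1/se_j^2` and FE mean `mu_FE`,
#' `Q = sum w_j (m_j - mu_FE)^2` and
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`. Random-effects
#' weights `1/(se_j^2 + tau2)` give the pooled estimate and its SE, tested
#' with a Wald z. `I2 = max(0, (Q - (k-1))/Q) * 100` (0 when Q = 0) and
#' `QEp` is the upper chi-square tail of Q on k - 1 df. A single-study gene
#' (k = 1) returns its own estimate with `tau2 = 0`, `Q = 0`, `I2 = 0`,
#' `QEp = 1`.
#'
#' @param mean_diff Per-study estimates (length k >= 1).
#' @param se Positive per-study standard errors.
#' @return List: `k`, `re_estimate`, `re_se`, `z`, `p_value`, `tau2`, `Q`,
#'   `Q_df`, `QEp`, `I2`.
#' @export
dl_meta <- function(mean_diff, se) {
  if (!length(mean_diff)) stop("no estimates to meta-analyze", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and > 0", call. = FALSE)
  k <- length(mean_diff)
  w <- 1 / se^2
  mu_fe <- sum(w * mean_diff) / sum(w)
  Q <- sum(w * (mean_diff - mu_fe)^2)
  if (k == 1L) {
    Q <- 0; tau2 <- 0; I2 <- 0; QEp <- 1
  } else {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / denom)
    I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
    QEp <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  }
  ws <- 1 / (se^2 + tau2)
  est <- sum(ws * mean_diff) / sum(ws)
  rse <- 1 / sqrt(sum(ws))
  z <- est / rse
  list(k = k, re_estimate = est, re_se = rse, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       tau2 = tau2, Q = Q, Q_df = k - 1L, QEp = QEp, I2 = I2)
}

#' Per-gene random-effects meta-analysis across studies
#'
#' Stacks the per-study gene tables, runs [dl_meta()] for every gene over
#' the studies measuring it (vectorized), and fills two BH adjustments over
#' all genes: `q_value` on the pooled-estimate p-values and `QEp_fdr` on the
#' heterogeneity p-values.
#'
#' @param gene_tables List of per-study data frames from
#'   [summarize_study()].
#' @return Data frame, one row per gene in the union universe: `gene`, `k`,
#'   `re_estimate`, `re_se`, `z`, `p_value`, `q_value`, `tau2`, `Q`, `Q_df`,
#'   `QEp`, `QEp_fdr`, `I2`; sorted by gene symbol.
#' @export
meta_analyze <- function(gene_tables) {
  long <- do.call(rbind, gene_tables)
  if (is.null(long) || !nrow(long)) stop("no gene tables", call. = FALSE)
  g <- factor(long$gene)
  m <- long$mean_diff
  w <- 1 / long$se^2
  sw <- rowsum(w, g)[, 1L]
  swm <- rowsum(w * m, g)[, 1L]
  sw2 <- rowsum(w^2, g)[, 1L]
  swm2 <- rowsum(w * m^2, g)[, 1L]
  k <- as.integer(table(g))
  mu_fe <- swm / sw
  Q <- pmax(swm2 - swm^2 / sw, 0)
  denom <- sw - sw2 / sw
  tau2 <- ifelse(k > 1L, pmax(0, (Q - (k - 1)) / denom), 0)
  Q[k == 1L] <- 0
  I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q) * 100, 0)
  QEp <- ifelse(k > 1L,
                stats::pchisq(Q, df = pmax(k - 1L, 1L), lower.tail = FALSE),
                1)
  ws <- 1 / (long$se^2 + tau2[as.integer(g)])
  sws <- rowsum(ws, g)[, 1L]
  swsm <- rowsum(ws * m, g)[, 1L]
  est <- swsm / sws
  rse <- 1 / sqrt(sws)
  z <- est / rse
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene = levels(g), k = k,
                    re_estimate = unname(est), re_se = unname(rse),
                    z = unname(z), p_value = unname(p),
                    q_value = NA_real_,
                    tau2 = unname(tau2), Q = unname(Q), Q_df = k - 1L,
                    QEp = unname(QEp), QEp_fdr = NA_real_,
                    I2 = unname(I2), stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  out$QEp_fdr <- bh_fdr(out$QEp)
  rownames(out) <- NULL
  out
}

#' Overall-significant and heterogeneous gene sets
#'
#' A gene is overall significant when its BH-adjusted meta p-value is below
#' `alpha`, its absolute pooled estimate exceeds the `percentile`-th
#' percentile of absolute pooled estimates over all meta-analyzed genes, and
#' it was measured in more than one study. Genes with BH-adjusted QEp below
#' `alpha` form the heterogeneous set.
#'
#' @param meta Data frame from [meta_analyze()].
#' @param alpha FDR threshold, default 0.05.
#' @param percentile Effect-size percentile, default 95.
#' @return List: `selected` (character), `heterogeneous` (character),
#'   `threshold` (the effect-size cutoff), `alpha`, `percentile`.
#' @export
overall_selection <- function(meta, alpha = 0.05, percentile = 95) {
  thr <- effect_threshold(abs(meta$re_estimate), percentile)
  sel <- meta$q_value < alpha & abs(meta$re_estimate) > thr & meta$k > 1L
  het <- meta$QEp_fdr < alpha
  list(selected = sort(meta$gene[sel]),
       heterogeneous = sort(meta$gene[het]),
       threshold = thr, alpha = alpha, percentile = percentile)
}

#' Pairwise significant-gene overlap between phenotypes
#'
#' For every unordered study pair (including self-pairs), the number of
#' genes significant in both out of the genes measured in both, as a
#' percentage. The self-pair cell is the study's own significant fraction.
#'
#' @param results List of `SignificanceResult` objects.
#' @param gene_universes Optional named list of per-study measured-gene
#'   character vectors; defaults to the genes in each result's table.
#' @return Data frame: `phenotype_a`, `phenotype_b`, `n_measured_both`,
#'   `n_sig_both`, `overlap_pct` (rounded to 2 decimals; `NA` with a warning
#'   when no genes are co-measured).
#' @export
overlap_table <- function(results, gene_universes = NULL) {
  if (length(results) < 2L) stop("need at least two studies", call. = FALSE)
  ids <- vapply(results, `[[`, "", "study_id")
  if (is.null(gene_universes))
    gene_universes <- lapply(results, function(r) r$gene_stats$gene)
  names(gene_universes) <- ids
  sigs <- lapply(results, `[[`, "significant_genes")
  names(sigs) <- ids
  rows <- list()
  for (a in seq_along(ids)) for (b in a:length(ids)) {
    meas <- intersect(gene_universes[[a]], gene_universes[[b]])
    nsig <- length(intersect(intersect(sigs[[a]], sigs[[b]]), meas))
    pct <- if (length(meas)) round(100 * nsig / length(meas), 2) else {
      warning(sprintf("no co-measured genes for %s vs %s", ids[a], ids[b]),
              call. = FALSE)
      NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      phenotype_a = ids[a], phenotype_b = ids[b],
      n_measured_both = length(meas), n_sig_both = nsig,
      overlap_pct = pct, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Spearman correlation of mean differences between two studies
#'
#' Nonparametric correlation of the gene-level mean differences over the
#' genes measured in both studies, with average ranks for ties and a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param genes_a,genes_b Data frames from [summarize_study()].
#' @return List: `spearman_rho`, `spearman_p`, `n_shared`.
#' @export
diff_correlation <- function(genes_a, genes_b) {
  shared <- merge(genes_a[, c("gene", "mean_diff")],
                  genes_b[, c("gene", "mean_diff")], by = "gene")
  if (nrow(shared) < 3L)
    stop("fewer than 3 co-measured genes", call. = FALSE)
  ct <- stats::cor.test(shared$mean_diff.x, shared$mean_diff.y,
                        method = "spearman", exact = FALSE)
  list(spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       n_shared = nrow(shared))
}

#' Pairwise Spearman table across all studies
#'
#' [diff_correlation()] for every unordered pair of studies (self-pairs
#' report rho = 1).
#'
#' @param gene_tables Named list of per-study [summarize_study()] tables.
#' @return Data frame: `phenotype_a`, `phenotype_b`, `n_shared`,
#'   `spearman_rho`, `spearman_p`.
#' @export
spearman_table <- function(gene_tables) {
  ids <- names(gene_tables)
  if (is.null(ids)) ids <- vapply(gene_tables, function(t) t$study_id[1L], "")
  rows <- list()
  for (a in seq_along(ids)) for (b in a:length(ids)) {
    if (a == b) {
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype_a = ids[a], phenotype_b = ids[b],
        n_shared = nrow(gene_tables[[a]]), spearman_rho = 1,
        spearman_p = 0, stringsAsFactors = FALSE)
      next
    }
    dc <- diff_correlation(gene_tables[[a]], gene_tables[[b]])
    rows[[length(rows) + 1L]] <- data.frame(
      phenotype_a = ids[a], phenotype_b = ids[b],
      n_shared = dc$n_shared, spearman_rho = dc$spearman_rho,
      spearman_p = dc$spearman_p, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
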