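# Per-probe paired-difference statistics within one study. The within-pair
# difference is affected minus unaffected, so a positive mean difference
# means higher expression in the affected twin.

#' Per-probe paired t statistics for a whole study
#'
#' For every probe, forms the within-pair differences over pairs where both
#' twins were measured, then computes the mean difference, its standard
#' error (sample SD over sqrt(n)), the t statistic with n - 1 degrees of
#' freedom, and the two-sided p-value. Probes with fewer than `min_pairs`
#' complete pairs are flagged `insufficient_pairs`; probes whose differences
#' have zero sample SD are flagged `zero_variance`. Flagged probes carry no
#' t or p and are excluded from gene-level summarization.
#'
#' @param study An `ExpressionStudy`.
#' @param min_pairs Minimum complete pairs needed to emit a statistic
#'   (default 3).
#' @return Data frame with one row per probe, in the matrix's probe order:
#'   `probe_id`, `n_pairs`, `mean_diff`, `se`, `t_stat`, `df`, `p_value`,
#'   `flag`.
#' @export
study_probe_table <- function(study, min_pairs = 3L) {
  validate_expression_study(study)
  D <- study$values[, study$pairs$affected, drop = FALSE] -
    study$values[, study$pairs$unaffected, drop = FALSE]
  n <- rowSums(!is.na(D))
  m <- rowMeans(D, na.rm = TRUE)
  ss <- rowSums((D - m)^2, na.rm = TRUE)  # m recycles along columns
  sdv <- sqrt(ss / pmax(n - 1L, 1L))
  se <- sdv / sqrt(n)
  t_stat <- m / se
  df <- n - 1L
  p <- 2 * stats::pt(-abs(t_stat), df)

  flag <- rep("ok", nrow(D))
  flag[sdv == 0] <- "zero_variance"
  flag[n < min_pairs] <- "insufficient_pairs"
  bad <- flag != "ok"
  t_stat[bad] <- NA_real_
  p[bad] <- NA_real_
  se[flag == "zero_variance"] <- 0
  m[n == 0L] <- NA_real_

  data.frame(probe_id = rownames(study$values),
             n_pairs = n, mean_diff = m, se = se, t_stat = t_stat,
             df = df, p_value = p, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired t test for one probe
#'
#' Single-probe convenience wrapper around [study_probe_table()].
#'
#' @param study An `ExpressionStudy`.
#' @param probe_id Probe present in the study.
#' @param min_pairs Minimum complete pairs (default 3).
#' @return One-row data frame (see [study_probe_table()]).
#' @export
paired_ttest <- function(study, probe_id, min_pairs = 3L) {
  if (!probe_id %in% rownames(study$values))
    stop(sprintf("unknown probe '%s' in study '%s'", probe_id,
                 study$study_id), call. = FALSE)
  sub <- study
  sub$values <- study$values[probe_id, , drop = FALSE]
  sub$annotation <- study$annotation[
    study$annotation$probe_id == probe_id, , drop = FALSE]
  sub$unmapped <- intersect(sub$unmapped, probe_id)
  study_probe_table(sub, min_pairs = min_pairs)
}
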