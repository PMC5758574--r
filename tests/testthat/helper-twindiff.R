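# Builders for small in-code fixtures and brute-force oracles.

# Study whose within-pair differences are exactly the rows of `diffs`:
# unaffected twins read 0, affected twins read the difference.
make_diff_study <- function(diffs, study_id = "S1", phenotype = "PHE",
                            genes = NULL) {
  diffs <- rbind(diffs)
  n <- ncol(diffs)
  probes <- sprintf("p%03d", seq_len(nrow(diffs)))
  rownames(diffs) <- probes
  pair_ids <- sprintf("pr%02d", seq_len(n))
  aff <- paste0(pair_ids, "_A"); una <- paste0(pair_ids, "_U")
  vals <- matrix(0, nrow(diffs), 2L * n,
                 dimnames = list(probes, c(rbind(aff, una))))
  vals[, aff] <- diffs
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(diffs)))
  expression_study(study_id, phenotype, vals,
                   data.frame(pair_id = pair_ids, affected = aff,
                              unaffected = una, stringsAsFactors = FALSE),
                   annotation = data.frame(probe_id = probes,
                                           gene_symbol = genes,
                                           stringsAsFactors = FALSE))
}

# Study with per-pair sex labels and sex-specific gene effects.
# effect_by_sex: named list male/female of per-gene effect vectors.
make_sex_study <- function(n_pairs_per_sex, n_genes, effect_by_sex,
                           noise_sd = 1, study_id = "S1", seed = 1) {
  set.seed(seed)
  sexes <- rep(c("male", "female"), each = n_pairs_per_sex)
  n <- length(sexes)
  pair_ids <- sprintf("%s_pr%02d", study_id, seq_len(n))
  aff <- paste0(pair_ids, "_A"); una <- paste0(pair_ids, "_U")
  probes <- sprintf("%s_p%03d", study_id, seq_len(n_genes))
  vals <- matrix(stats::rnorm(n_genes * 2L * n, 0, noise_sd), n_genes, 2L * n,
                 dimnames = list(probes, c(rbind(aff, una))))
  for (i in seq_len(n))
    vals[, aff[i]] <- vals[, aff[i]] + effect_by_sex[[sexes[i]]]
  expression_study(study_id, study_id, vals,
                   data.frame(pair_id = pair_ids, affected = aff,
                              unaffected = una, stringsAsFactors = FALSE),
                   sex = stats::setNames(sexes, pair_ids),
                   annotation = data.frame(
                     probe_id = probes,
                     gene_symbol = sprintf("G%04d", seq_len(n_genes)),
                     stringsAsFactors = FALSE))
}

# Write a small TSV triple; returns the three paths.
write_study_fixture <- function(dir, matrix_df, metadata_df, annotation_df) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "metadata.tsv", "annotation.tsv"))
  utils::write.table(matrix_df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metadata_df, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(annotation_df, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

fixture_matrix <- function() {
  data.frame(probe_id = c("p1", "p2", "p3", "p4"),
             s1A = c(1.5, 2.0, 3.0, 4.0), s1U = c(1.0, 2.5, 3.5, 4.5),
             s2A = c(2.5, 3.0, 4.0, 5.0), s2U = c(2.0, 3.5, 4.5, 5.5),
             s3A = c(3.5, 4.0, 5.0, 6.0), s3U = c(3.0, 4.5, 5.5, 6.5),
             stringsAsFactors = FALSE)
}

fixture_metadata <- function() {
  data.frame(sample_id = c("s1A", "s1U", "s2A", "s2U", "s3A", "s3U"),
             pair_id = rep(c("P1", "P2", "P3"), each = 2),
             status = rep(c("affected", "unaffected"), 3),
             stringsAsFactors = FALSE)
}

fixture_annotation <- function() {
  data.frame(probe_id = c("p1", "p2", "p3"),
             gene_symbol = c("GENE1 /// GENE2", "GENE3", "GENE3"),
             stringsAsFactors = FALSE)
}

# Brute-force BH step-up: literal q_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Textbook paired-difference statistics for one vector of differences.
oracle_paired <- function(d) {
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- mean(d) / se
  list(mean_diff = mean(d), se = se, t = t,
       p = 2 * stats::pt(-abs(t), n - 1))
}
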