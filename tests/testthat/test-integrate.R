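test_that("DerSimonian-Laird arithmetic matches hand-computed cases", {
  r <- dl_meta(1.4, 0.6)
  expect_equal(r[c("re_estimate", "re_se", "tau2", "Q", "I2", "QEp")],
               list(re_estimate = 1.4, re_se = 0.6, tau2 = 0, Q = 0,
                    I2 = 0, QEp = 1))

  r <- dl_meta(c(2, 2, 2), c(1, 1, 1))
  expect_equal(r$Q, 0)
  expect_equal(r$tau2, 0)
  expect_equal(r$I2, 0)
  expect_equal(r$re_estimate, 2)
  expect_equal(r$re_se, 1 / sqrt(3), tolerance = 1e-12)

  r <- dl_meta(c(0, 2), c(1, 1))
  expect_equal(r$Q, 2, tolerance = 1e-12)
  expect_equal(r$tau2, 1, tolerance = 1e-12)
  expect_equal(r$I2, 50, tolerance = 1e-12)
  expect_equal(r$re_estimate, 1, tolerance = 1e-12)
  expect_equal(r$re_se, 1, tolerance = 1e-12)
  expect_equal(r$QEp, 0.1572992, tolerance = 1e-6)

  expect_error(dl_meta(numeric(), numeric()), "no estimates")
  expect_error(dl_meta(c(1, 2), c(1, -1)), "> 0")
})

test_that("DL estimates agree with metafor's rma.uni to 1e-10", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:9, 1)
    m <- rnorm(k, 0, 2); se <- runif(k, 0.3, 2)
    r <- dl_meta(m, se)
    ref <- metafor::rma.uni(yi = m, sei = se, method = "DL")
    expect_equal(r$re_estimate, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(r$re_se, ref$se, tolerance = 1e-10)
    expect_equal(r$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(r$Q, ref$QE, tolerance = 1e-10)
    expect_equal(r$QEp, ref$QEp, tolerance = 1e-10)
    expect_equal(r$I2, ref$I2, tolerance = 1e-8)
    expect_equal(r$p_value, ref$pval, tolerance = 1e-10)
  }
})

test_that("homogeneous inputs reduce DL to fixed-effect pooling", {
  set.seed(15)
  se <- runif(4, 0.5, 1)
  m <- rep(1.3, 4)                       # Q = 0 => tau2 = 0
  r <- dl_meta(m, se)
  fe <- fixed_effect_pool(m, se)
  expect_equal(r$re_estimate, fe$pooled_mean, tolerance = 1e-12)
  expect_equal(r$re_se, fe$pooled_se, tolerance = 1e-12)
  # Q is invariant under study permutation
  m2 <- rnorm(4); perm <- sample(4)
  expect_equal(dl_meta(m2[perm], se[perm])$Q, dl_meta(m2, se)$Q,
               tolerance = 1e-12)
})

test_that("the vectorized per-gene meta table equals gene-by-gene dl_meta", {
  set.seed(19)
  tabs <- lapply(sprintf("S%d", 1:5), function(s) {
    n <- 40
    keep <- sort(sample(60, n))
    data.frame(gene = sprintf("G%03d", keep), study_id = s, n_probes = 1L,
               multi_mapped = FALSE, mean_diff = rnorm(n), se = runif(n, .3, 2),
               z_stat = 0, p_value = runif(n), q_value = NA_real_,
               abs_rank = 1:n, stringsAsFactors = FALSE)
  })
  meta <- meta_analyze(tabs)
  long <- do.call(rbind, tabs)
  for (gname in sample(meta$gene, 12)) {
    rows <- long[long$gene == gname, ]
    ref <- dl_meta(rows$mean_diff, rows$se)
    row <- meta[meta$gene == gname, ]
    for (f in c("k", "re_estimate", "re_se", "tau2", "Q", "QEp", "I2",
                "p_value"))
      expect_equal(row[[f]], ref[[f]], tolerance = 1e-9)
  }
  expect_true(all(meta$I2 >= 0 & meta$I2 <= 100))
  expect_true(all(meta$tau2 >= 0))
  expect_equal(meta$q_value, bh_fdr(meta$p_value))
  expect_equal(meta$QEp_fdr, bh_fdr(meta$QEp))
  # single-study genes keep their estimate and carry the k = 1 conventions
  k1 <- meta[meta$k == 1, ]
  expect_true(all(k1$Q == 0 & k1$I2 == 0 & k1$QEp == 1 & k1$tau2 == 0))
})

test_that("DL recovers tau2 and flags no heterogeneity when absent", {
  set.seed(91)
  k <- 7; n_rep <- 500
  tau2_hat <- i2_null <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    theta <- rnorm(k, 0, 1)              # true tau2 = 1
    tau2_hat[r] <- dl_meta(theta + rnorm(k), rep(1, k))$tau2
    i2_null[r] <- dl_meta(rnorm(k), rep(1, k))$I2
  }
  expect_lt(abs(mean(tau2_hat) - 1), 0.15)
  expect_equal(median(i2_null), 0)
})

test_that("overlap percentages come from co-measured gene counts", {
  mk <- function(id, sig, genes) {
    structure(list(study_id = id, threshold_95 = 1,
                   significant_genes = sig, n_tested = length(genes),
                   alpha_fdr = 0.05, percentile = 95,
                   gene_stats = data.frame(gene = genes, study_id = id,
                                           stringsAsFactors = FALSE)),
              class = "SignificanceResult")
  }
  g <- sprintf("g%d", 1:4)
  a <- mk("A", c("g1", "g2"), g)
  b <- mk("B", c("g1", "g2"), g)
  tab <- overlap_table(list(a, b))
  ab <- tab[tab$phenotype_a == "A" & tab$phenotype_b == "B", ]
  expect_equal(ab$overlap_pct, 50.00)
  expect_equal(ab$n_measured_both, 4L)

  b2 <- mk("B", c("g3", "g4"), g)
  tab <- overlap_table(list(a, b2))
  expect_equal(tab$overlap_pct[tab$phenotype_a == "A" &
                                 tab$phenotype_b == "B"], 0)

  big <- mk("C", sprintf("g%d", 1:20), sprintf("g%d", 1:1000))
  tab <- overlap_table(list(big, a), gene_universes = list(
    C = sprintf("g%d", 1:1000), A = g))
  expect_equal(tab$overlap_pct[tab$phenotype_a == "C" &
                                 tab$phenotype_b == "C"], 2.00)

  disj <- mk("D", character(), c("x1", "x2"))
  expect_warning(tab <- overlap_table(list(a, disj)), "no co-measured")
  expect_true(is.na(tab$overlap_pct[tab$phenotype_a == "A" &
                                      tab$phenotype_b == "D"]))
  expect_error(overlap_table(list(a)), "at least two")
})

test_that("Spearman correlation of differences handles ties and transforms", {
  ga <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   mean_diff = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  gb <- ga
  expect_equal(diff_correlation(ga, gb)$spearman_rho, 1)
  gb$mean_diff <- rev(ga$mean_diff)
  expect_equal(diff_correlation(ga, gb)$spearman_rho, -1)
  gb$mean_diff <- c(1, 2, 2, 4)
  r <- diff_correlation(ga, gb)
  expect_equal(r$spearman_rho, 0.9486833, tolerance = 1e-6)
  expect_equal(r$spearman_p, 0.0513167, tolerance = 1e-6)
  # any strictly monotone transform preserves rho = 1 exactly
  gb$mean_diff <- exp(ga$mean_diff)
  expect_equal(diff_correlation(ga, gb)$spearman_rho, 1)
  expect_error(diff_correlation(ga[1:2, ], gb[1:2, ]), "fewer than 3")
})

test_that("overall selection applies FDR, effect-size and k > 1 gates", {
  meta <- data.frame(
    gene = c("gk1", "gbig", sprintf("gnull%02d", 1:58)),
    k = c(1L, 3L, rep(3L, 58)),
    re_estimate = c(12, 9, rep(0.1, 58)),
    p_value = c(1e-8, 1e-7, rep(0.9, 58)),
    QEp = c(1, 0.8, rep(0.9, 58)),
    stringsAsFactors = FALSE)
  meta$q_value <- bh_fdr(meta$p_value)
  meta$QEp_fdr <- bh_fdr(meta$QEp)
  sel <- overall_selection(meta)
  # both strong genes clear the effect-size cutoff, but the single-study
  # gene is barred by the measured-in-more-than-one-study requirement
  expect_equal(sel$selected, "gbig")
  expect_equal(sel$heterogeneous, character())
  expect_lt(sel$threshold, 9)
})

test_that("a gene spiked across all studies is recovered with low heterogeneity", {
  set.seed(321)
  n_genes <- 300; n_pairs <- 20
  tabs <- lapply(1:7, function(s) {
    d <- matrix(rnorm(n_genes * n_pairs, 0, sqrt(2)), n_genes, n_pairs)
    d[1, ] <- d[1, ] + 3                 # gene G001 carries effect 3 everywhere
    st <- make_diff_study(d, study_id = sprintf("S%d", s))
    summarize_study(study_probe_table(st), st$annotation, st$study_id)
  })
  meta <- meta_analyze(tabs)
  sel <- overall_selection(meta)
  expect_equal(sel$selected, "G001")
  spike_row <- meta[meta$gene == "G001", ]
  expect_lt(abs(spike_row$re_estimate - 3), 0.5)
  # homogeneous effect: heterogeneity stays below the I2 > 68 level that
  # flags heterogeneous genes, and most null genes estimate I2 = 0
  expect_lt(spike_row$I2, 68)
  expect_equal(median(meta$I2), 0)
  expect_equal(sel$heterogeneous, character())
})
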