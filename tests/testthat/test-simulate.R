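test_that("the noiseless limit reproduces the spiked effect exactly", {
  cfg <- simulation_config(n_studies = 2, pairs_per_study = 4,
                           n_genes_universe = 20, platform_coverage = 1,
                           probes_per_gene = 2, frac_affected_genes = 0.05,
                           effect_mean_sd = 2, tau = 0, noise_sd = 0,
                           pair_effect_sd = 0, probe_offset_sd = 0,
                           missing_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  spiked <- sim$truth$gene[sim$truth$affected]
  expect_length(spiked, 1L)
  expect_false(sim$truth$mu[sim$truth$affected] == 0)
  # with every noise source off, each within-pair difference equals the
  # study's realized effect delta_gs (mu_g for the spiked gene since
  # tau = 0, zero for null genes) up to the rounding of baseline + delta
  for (st in sim$studies) {
    D <- st$values[, st$pairs$affected] - st$values[, st$pairs$unaffected]
    d_true <- sim$truth$delta[st$annotation$gene_symbol[
      match(rownames(D), st$annotation$probe_id)], st$study_id]
    expect_equal(unname(D), matrix(d_true, nrow(D), ncol(D)),
                 tolerance = 1e-12)
    # null-gene probes difference out to exactly zero
    null_probe <- st$annotation$gene_symbol[
      match(rownames(D), st$annotation$probe_id)] %in%
      sim$truth$gene[!sim$truth$affected]
    expect_true(all(D[null_probe, ] == 0))
  }
  null_genes <- sim$truth$gene[!sim$truth$affected]
  expect_true(all(sim$truth$delta[null_genes, ] %in% c(0, NA)))
})

test_that("the same config and seed reproduce the cohort byte-for-byte", {
  cfg <- simulation_config(n_studies = 2, pairs_per_study = c(5, 6),
                           n_genes_universe = 50, missing_rate = 0.05,
                           seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$studies, `[[`, "values"),
                   lapply(b$studies, `[[`, "values"))
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- emit_cohort_files(a, d1)
  m2 <- emit_cohort_files(b, d2)
  expect_identical(m1$md5, m2$md5)
})

test_that("emitted files round-trip through read_expression", {
  cfg <- simulation_config(n_studies = 2, pairs_per_study = 4,
                           n_genes_universe = 30, seed = 5)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- emit_cohort_files(sim, dir)
  # 2 studies x 3 files + truth table
  expect_equal(nrow(manifest), 7L)
  st <- sim$studies[[1]]
  back <- read_expression(
    file.path(dir, paste0(st$study_id, "_matrix.tsv")),
    file.path(dir, paste0(st$study_id, "_metadata.tsv")),
    file.path(dir, paste0(st$study_id, "_annotation.tsv")),
    study_id = st$study_id, phenotype = st$phenotype)
  expect_equal(back$values, st$values, tolerance = 1e-12)
  expect_identical(back$pairs[order(back$pairs$pair_id), ],
                   st$pairs[order(st$pairs$pair_id), ])
  expect_setequal(
    paste(back$annotation$probe_id, back$annotation$gene_symbol),
    paste(st$annotation$probe_id, st$annotation$gene_symbol))
  expect_error(emit_cohort_files(list(studies = list()), dir), "empty")
})

test_that("panel coverage matches the configured platform_coverage", {
  cfg <- simulation_config(n_studies = 3, pairs_per_study = 3,
                           n_genes_universe = 2000,
                           platform_coverage = 0.6, probes_per_gene = 1,
                           seed = 21)
  sim <- simulate_cohort(cfg)
  for (st in sim$studies) {
    frac <- length(unique(st$annotation$gene_symbol)) / 2000
    expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
  }
})

test_that("pair effects cancel in within-pair differences", {
  base <- list(n_studies = 1, pairs_per_study = 40, n_genes_universe = 400,
               platform_coverage = 1, probes_per_gene = 1,
               frac_affected_genes = 0, noise_sd = 1, probe_offset_sd = 0,
               seed = 33)
  v <- function(pe_sd) {
    sim <- simulate_cohort(do.call(simulation_config,
                                   c(base, pair_effect_sd = pe_sd)))
    st <- sim$studies[[1]]
    D <- st$values[, st$pairs$affected] - st$values[, st$pairs$unaffected]
    mean(apply(D, 1, stats::var))
  }
  v0 <- v(0); vbig <- v(50)
  # both estimate 2 * noise_sd^2; a huge pair effect must not inflate it
  expect_lt(abs(vbig / v0 - 1), 0.1)
  expect_lt(abs(v0 / 2 - 1), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(pairs_per_study = 2), "at least 3")
  expect_error(simulation_config(platform_coverage = 0), "platform_coverage")
  expect_error(simulation_config(noise_sd = -1), "SDs")
  expect_error(simulation_config(frac_affected_genes = 1.2),
               "frac_affected_genes")
})
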