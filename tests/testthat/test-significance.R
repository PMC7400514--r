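# Folds, correlations, empirical p-values, corrections, pathway test.

test_that("folds are patient-grouped, stratified, balanced", {
  man <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 3),
                    cohort = "C1")
  f <- make_folds(man, 5L, seed = 1)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))

  # a patient's slides all inherit one fold (grouping is at patient level)
  expect_equal(nrow(f), 10L)  # deduplicated patients

  man2 <- data.frame(patient_id = sprintf("P%02d", 1:15),
                     cohort = rep(c("A", "B"), c(7, 8)))
  f2 <- make_folds(man2, 5L, seed = 2)
  counts <- table(f2$cohort, f2$fold)
  expect_true(all(counts >= 1 & counts <= 2))
  expect_error(make_folds(data.frame(patient_id = c("a", "b"),
                                     cohort = "X"), 5L),
               "smaller than n_folds")
})

test_that("per-gene correlation averages folds within cohorts", {
  pred <- matrix(c(1, 2, 3, 3, 2, 1), 6, 1,
                 dimnames = list(paste0("s", 1:6), "g"))
  truth <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1,
                  dimnames = list(paste0("s", 1:6), "g"))
  info <- data.frame(sample_id = paste0("s", 1:6), cohort = "C",
                     fold = rep(0:1, each = 3))
  out <- per_gene_correlation(pred, truth, info)
  expect_equal(out$R, 0)  # mean of +1 and -1

  # hand-computed Pearson example
  p2 <- matrix(c(1, 1, 2, 2), 4, 1, dimnames = list(paste0("t", 1:4), "g"))
  t2 <- matrix(c(0, 1, 1, 2), 4, 1, dimnames = list(paste0("t", 1:4), "g"))
  i2 <- data.frame(sample_id = paste0("t", 1:4), cohort = "C", fold = 0L)
  expect_equal(per_gene_correlation(p2, t2, i2)$R, sqrt(2) / 2,
               tolerance = 1e-6)

  # zero-variance fold skipped with warning
  p3 <- matrix(c(1, 1, 1, 2, 1, 3), 6, 1,
               dimnames = list(paste0("u", 1:6), "g"))
  expect_warning(
    out3 <- per_gene_correlation(
      p3, matrix(rnorm(6), 6, 1, dimnames = dimnames(p3)),
      data.frame(sample_id = paste0("u", 1:6), cohort = "C",
                 fold = rep(0:1, each = 3))),
    "zero variance")
  expect_equal(out3$n_folds_used, 1L)
})

test_that("empirical p-values follow the add-one convention", {
  null <- seq(-0.499, 0.499, by = 0.001)  # N = 999 values (sorted)
  expect_equal(empirical_pvalue(0.9, null), 1 / 1000)
  expect_equal(empirical_pvalue(-0.9, null), 1)
  med <- empirical_pvalue(stats::median(null), null)
  expect_gt(med, 0.45); expect_lt(med, 0.55)
  expect_true(all(empirical_pvalue(rnorm(20), null) > 0))
})

test_that("Holm-Sidak matches hand computation and is conservative", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  set.seed(6)
  p <- runif(30)
  expect_true(all(holm_sidak(p) >= p))
  # idempotent on already-adjusted monotone input
  adj <- holm_sidak(p)
  expect_true(all(holm_sidak(sort(adj)) >= sort(adj) - 1e-12))
  # order restored
  expect_equal(order(holm_sidak(p)[order(p)]), 1:30)
})

test_that("Benjamini-Hochberg matches p.adjust and dominates Holm-Sidak", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
    # BH never calls fewer than the FWER-controlling step-down at 0.05
    expect_gte(sum(benjamini_hochberg(p) < 0.05),
               sum(holm_sidak(p) < 0.05))
  }
})

test_that("untrained-model null is centered and tightens with n", {
  make_null_for <- function(n_pat, seed) {
    cfg <- synthetic_config(patients_per_cohort = n_pat,
                            slides_per_patient = 1L, tiles_per_slide = 16L,
                            feature_dim = 8L, n_signal_genes = 1L,
                            n_noise_genes = 9L, cv_folds = 2L, seed = seed)
    sim <- generate_cohorts(cfg)
    folds <- make_folds(sim$manifest, 2L, seed = seed)
    spec <- model_spec(8L, 10L, hidden = c(16L, 8L))
    build_null(sim$bags, sim$expression, folds, spec,
               n_replicates = 20L, seed = seed)
  }
  big <- make_null_for(40L, 11L)
  small <- make_null_for(10L, 12L)
  v_big <- big$values[[1]]
  v_small <- small$values[[1]]
  expect_lt(abs(mean(v_big)), 0.1)
  expect_lt(stats::sd(v_big), stats::sd(v_small))
})

test_that("null distribution is symmetric w.r.t. gene-column permutation", {
  # the untrained model has no preferred output unit, so permuting the gene
  # columns of the truth leaves the null's distribution (not individual
  # draws) unchanged
  cfg <- synthetic_config(patients_per_cohort = 12L,
                          slides_per_patient = 1L,
                          tiles_per_slide = 9L, feature_dim = 8L,
                          n_signal_genes = 2L, n_noise_genes = 8L,
                          cv_folds = 2L, seed = 21L)
  sim <- generate_cohorts(cfg)
  folds <- make_folds(sim$manifest, 2L, seed = 3)
  spec <- model_spec(8L, 10L, hidden = 8L)
  n1 <- build_null(sim$bags, sim$expression, folds, spec,
                   n_replicates = 25L, seed = 9)
  set.seed(5)
  perm <- sample(gene_ids(sim$expression))
  n2 <- build_null(sim$bags, subset_expression(sim$expression, genes = perm),
                   folds, spec, n_replicates = 25L, seed = 9)
  v1 <- n1$values[[1]]; v2 <- n2$values[[1]]
  expect_lt(abs(mean(v1) - mean(v2)), 0.1)
  expect_lt(abs(stats::sd(v1) - stats::sd(v2)), 0.1)
  expect_gt(suppressWarnings(stats::ks.test(v1, v2)$p.value), 0.01)
})

test_that("pathway test agrees with the exhaustive two-gene oracle", {
  signif <- data.frame(gene = paste0("g", 1:6), cohort = "C",
                       R = c(0.9, 0.8, 0.1, 0.1, 0.1, 0.1),
                       well_predicted = c(TRUE, TRUE, rep(FALSE, 4)))
  # oracle: all 15 two-gene lists, fraction with mean R >= R_p
  combos <- utils::combn(6, 2)
  means <- apply(combos, 2, function(ix) mean(signif$R[ix]))
  expect_equal(mean(means >= 0.85), 1 / 15)
  pt <- pathway_test(signif, c("g1", "g2"), n_random = 4000L, seed = 2)
  expect_equal(pt$R_p, 0.85)
  expect_lt(abs(pt$p_R - 1 / 15), 0.02)
  # 1/15 ~ 0.067 sits above the 0.05 line: not called significant
  expect_false(pt$significant_R)
  # extreme case: top genes give the floor p
  expect_equal(pathway_test(signif, c("g1", "g2"), n_random = 100L,
                            seed = 1)$p_R > 0, TRUE)
  expect_warning(pathway_test(signif, c("g1", "gX"), n_random = 10L,
                              seed = 1), "missing")
})

test_that("gene_significance wires p-values, calls and R_sign", {
  cor_tab <- data.frame(gene = paste0("g", 1:4), cohort = "C",
                        R = c(0.9, 0.5, 0.05, -0.2), n_folds_used = 5L)
  null <- structure(list(values = list(C = rnorm(2000, 0, 0.12)),
                         n_replicates = 100L, mode = "pooled"),
                    class = "null_distribution")
  tab <- gene_significance(cor_tab, null)
  expect_true(tab$well_predicted[1])
  expect_false(tab$well_predicted[4])
  expect_true(all(tab$p_holm_sidak >= tab$p_empirical - 1e-15))
  expect_equal(tab$R_sign[1], min(tab$R[tab$well_predicted]))
})
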