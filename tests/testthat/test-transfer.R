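# Transfer module: Wilcoxon against the sign-flip oracle, representation
# contracts, autoencoder behavior, leakage guard, classifier grouping.

test_that("Wilcoxon matches the exhaustive sign-flip oracle for n <= 8", {
  set.seed(23)
  for (n in 3:8) {
    for (rep in 1:6) {
      x <- rnorm(n)
      y <- x + rnorm(n, sd = 0.8)
      if (rep %% 2 == 0) y[1] <- x[1]  # inject zero differences
      if (rep %% 3 == 0) y[2] <- x[2] + (x[3] - y[3])  # tied |d|
      expect_equal(compare_auc_distributions(x, y)$p,
                   oracle_wilcoxon(x, y), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("Wilcoxon edge cases: identity, constant shift, large n", {
  x <- rnorm(12)
  expect_equal(compare_auc_distributions(x, x)$p, 1)
  # pairs (x, x+1) for n=10: the most extreme one-sided outcome
  x10 <- rnorm(10)
  expect_equal(compare_auc_distributions(x10 + 1, x10)$p, 2 / 1024)
  # agrees with stats::wilcox.test exact p when there are no ties/zeros
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15)
  ours <- compare_auc_distributions(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # beyond the exact range the normal approximation is used
  big <- compare_auc_distributions(rnorm(40) + 0.5, rnorm(40))
  expect_equal(big$method, "normal_approx")
  expect_lt(big$p, 1)
})

make_pooled_cohort <- function(seed = 31L, n_pat = 36L) {
  sim <- generate_cohorts(synthetic_config(
    patients_per_cohort = n_pat, slides_per_patient = 1L,
    tiles_per_slide = 49L, feature_dim = 16L, n_tile_types = 3L,
    n_signal_genes = 3L, n_noise_genes = 7L, cv_folds = 3L, seed = seed))
  pooled <- t(vapply(sim$bags, mean_pool_bag, numeric(16L)))
  rownames(pooled) <- names(sim$bags)
  list(sim = sim, pooled = pooled,
       patients = vapply(sim$bags, function(b) b$patient_id, character(1)),
       labels = stats::setNames(sim$labels$label, sim$labels$patient_id))
}

desk_transfer_config <- function(seed = 1L, n_bootstrap = 2L) {
  transfer_config(n_bootstrap = n_bootstrap, epochs = 30L,
                  repr_hidden = c(32L, 16L), clf_hidden = c(16L, 8L),
                  ae_hidden = c(32L, 16L, 32L), lr = 3e-3, seed = seed)
}

test_that("representation model honours width, determinism and firewall", {
  co <- make_pooled_cohort()
  # default architecture: 256-unit representation
  cfg_default <- transfer_config(epochs = 1L, seed = 2L)
  rm_ <- train_representation(co$pooled, co$sim$expression, co$patients,
                              cfg_default)
  expect_equal(rm_$repr_width, 256L)
  rep1 <- predict_representation(rm_, co$pooled[1:4, ])
  expect_equal(ncol(rep1), 256L)
  # identical inputs give identical representations
  expect_equal(rep1[1, ], predict_representation(rm_, co$pooled[1, ,
                                                                drop = FALSE])[1, ])
  # leakage guard
  expect_error(train_representation(co$pooled, co$sim$expression,
                                    co$patients, cfg_default,
                                    b_patients = co$patients[1]),
               "leakage")
  # determinism under the config seed
  cfg_d <- desk_transfer_config(seed = 5L)
  r1 <- train_representation(co$pooled, co$sim$expression, co$patients,
                             cfg_d)
  r2 <- train_representation(co$pooled, co$sim$expression, co$patients,
                             cfg_d)
  expect_identical(predict_representation(r1, co$pooled),
                   predict_representation(r2, co$pooled))
})

test_that("autoencoder learns, exposes its bottleneck, default width 256", {
  co <- make_pooled_cohort()
  expect_equal(transfer_config()$ae_hidden[2], 256L)
  ae <- train_autoencoder_baseline(co$pooled, desk_transfer_config(seed = 3L))
  expect_lt(mean(ae$loss[21:30]), ae$loss[1])
  expect_equal(ncol(ae$encode(co$pooled)), 16L)  # desk-scale bottleneck
})

test_that("classifiers are patient-grouped with one prediction per patient", {
  co <- make_pooled_cohort(seed = 37L)
  # duplicate every patient's slide so patients own 2 samples
  pooled2 <- rbind(co$pooled, co$pooled + rnorm(length(co$pooled), sd = 0.01))
  rownames(pooled2) <- c(rownames(co$pooled),
                         paste0(rownames(co$pooled), "-b"))
  patients2 <- c(co$patients, co$patients)
  y2 <- co$labels[patients2]
  out <- train_classifier_raw(pooled2, y2, patients2,
                              desk_transfer_config(seed = 6L))
  expect_length(out$patient_pred, length(unique(patients2)))
  expect_false(is.na(out$auc))
  # shuffled labels give chance-level AUC on average
  set.seed(8)
  null_aucs <- replicate(10, {
    sh <- stats::setNames(sample(co$labels), names(co$labels))
    train_classifier_raw(co$pooled, sh[co$patients], co$patients,
                         desk_transfer_config(seed = 7L))$auc
  })
  expect_gt(mean(null_aucs), 0.3)
  expect_lt(mean(null_aucs), 0.7)
})

test_that("harness produces the full method x bootstrap grid", {
  co <- make_pooled_cohort(seed = 41L)
  cfg <- desk_transfer_config(seed = 9L, n_bootstrap = 2L)
  res <- hospital_split_harness(co$pooled, co$sim$expression, co$patients,
                                co$labels, cfg)
  expect_equal(nrow(res), 2L * 4L)
  expect_setequal(unique(res$method),
                  c("raw", "transcriptome", "ae_A", "ae_B"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  # rejects fractions leaving B too small
  tiny <- transfer_config(b_fractions = 0.05, n_bootstrap = 1L)
  expect_error(hospital_split_harness(co$pooled, co$sim$expression,
                                      co$patients, co$labels, tiny),
               "fewer than")
})
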