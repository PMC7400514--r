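# The regression core: per-tile forward pass, top-k aggregation and its
# weighted-mean equivalence, training behavior, prediction bundles.

test_that("forward pass shares weights across tiles and is equivariant", {
  net <- mlp_init(c(2, 3, 2), c("relu", "linear"), seed = 1)
  X <- matrix(rnorm(10), 5, 2)
  X[2, ] <- X[4, ]
  out <- forward_tiles(X, net)
  expect_equal(out[2, ], out[4, ])
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(forward_tiles(X[perm, ], net), out[perm, ])
})

test_that("forward pass matches a hand-computed affine+rectifier stack", {
  net <- structure(list(
    W = list(matrix(c(1, 0, -1, 2), 2, 2), matrix(c(1, 1), 2, 1)),
    b = list(c(0.5, -0.5), 0.25),
    acts = c("relu", "linear"), sizes = c(2L, 2L, 1L)), class = "mlp")
  x <- c(2, 3)
  h <- pmax(c(2 * 1 + 3 * 0 + 0.5, 2 * -1 + 3 * 2 - 0.5), 0)  # (2.5, 3.5)
  expect_equal(as.vector(forward_tiles(matrix(x, 1, 2), net)),
               sum(h) + 0.25)
})

test_that("aggregate_train is the mean of the k largest scores per gene", {
  sc <- cbind(a = c(4, 2, 1, 1))
  expect_equal(unname(aggregate_train(sc, 2)), 3.0)
  expect_equal(unname(aggregate_train(sc, 4)), mean(sc))
  expect_equal(unname(aggregate_train(sc, 99)), mean(sc))  # capped
  expect_equal(unname(aggregate_train(matrix(7, 6, 1), 3)), 7)
  # multi-gene: each column handled independently
  sc2 <- cbind(c(1, 5, 3), c(-1, -5, -3))
  expect_equal(unname(aggregate_train(sc2, 2)), c(4, -2))
})

test_that("aggregate_inference matches hand computation and plain mean", {
  sc <- cbind(c(4, 2, 1, 1))
  agg <- aggregation_spec(L = c(1, 2, 4))
  expect_equal(unname(aggregate_inference(sc, agg)), 3.0)  # (4+3+2)/3
  expect_equal(unname(aggregate_inference(sc, aggregation_spec(L = 4))),
               mean(sc))
})

test_that("compute_tile_weights reproduces the hand expansion", {
  expect_equal(compute_tile_weights(4, c(1, 2, 4)),
               c(7 / 12, 1 / 4, 1 / 12, 1 / 12))
  for (n in c(3, 10, 40)) {
    w <- compute_tile_weights(n, c(1, 2, 5, 10, 20, 50, 100))
    expect_equal(sum(w), 1)
    expect_true(all(diff(w) <= 1e-15))
  }
})

test_that("weighted-mean equivalence holds exhaustively at small n", {
  # property over random L subsets and sizes; the top-k path must agree
  # with the rank-weight formulation to floating precision
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    L <- sort(sample(1:n, sample(1:min(n, 6), 1)))
    sc <- matrix(rnorm(n * 3), n, 3)
    agg <- aggregation_spec(L = L)
    w <- compute_tile_weights(n, L)
    manual <- apply(sc, 2, function(col) sum(w * sort(col, decreasing = TRUE)))
    expect_equal(unname(aggregate_inference(sc, agg)), manual,
                 tolerance = 1e-12)
    # and against the naive mean-of-top-k-means oracle
    naive <- rowMeans(vapply(L, function(k) {
      apply(sc, 2, function(col) mean(sort(col, decreasing = TRUE)[1:k]))
    }, numeric(3)))
    expect_equal(unname(aggregate_inference(sc, agg)), naive,
                 tolerance = 1e-12)
  }
})

test_that("aggregation is monotone and permutation invariant", {
  set.seed(5)
  sc <- matrix(rnorm(20), 20, 1)
  agg <- aggregation_spec(L = c(1, 3, 7, 20))
  base <- aggregate_inference(sc, agg)
  for (i in c(1, 8, 20)) {
    bumped <- sc; bumped[i, 1] <- bumped[i, 1] + 0.7
    expect_gte(aggregate_inference(bumped, agg)[1], base[1])
    for (k in c(1, 5, 20)) {
      expect_gte(aggregate_train(bumped, k)[1], aggregate_train(sc, k)[1])
    }
  }
  perm <- sample(20)
  expect_equal(aggregate_inference(sc[perm, , drop = FALSE], agg), base)
})

test_that("training learns a noise-free composition-linked cohort", {
  cfg <- synthetic_config(patients_per_cohort = 10L, slides_per_patient = 1L,
                          tiles_per_slide = 25L, feature_dim = 8L,
                          n_tile_types = 3L, n_signal_genes = 3L,
                          n_noise_genes = 0L, expression_noise_sd = 0,
                          feature_noise_sd = 0.1, cv_folds = 2L, seed = 8L)
  sim <- generate_cohorts(cfg)
  tcfg <- desk_train_config(seed = 2L, max_epochs = 150L)
  m <- train_tile_model(sim$bags, sim$expression,
                        agg = aggregation_spec(mode = "supertile"),
                        cfg = tcfg)
  Y <- log_values(sim$expression)
  baseline <- mean(sweep(Y, 2, colMeans(Y))^2)
  # learnability floor: converged training loss beats predict-the-mean
  expect_lt(min(m$history$loss), baseline)
  # determinism of the whole training path
  m2 <- train_tile_model(sim$bags, sim$expression,
                         agg = aggregation_spec(mode = "supertile"),
                         cfg = tcfg)
  expect_identical(m$net$W, m2$net$W)
  expect_identical(m$best_metric, m2$best_metric)
})

test_that("prediction bundles are internally consistent and deterministic", {
  sim <- tiny_sim()
  m <- train_tile_model(sim$bags, sim$expression,
                        cfg = desk_train_config(seed = 3L, max_epochs = 20L))
  bag <- sim$bags[[1]]
  p1 <- predict_slide(bag, m)
  p2 <- predict_slide(bag, m)
  expect_identical(p1$tile_scores, p2$tile_scores)
  expect_equal(p1$slide_prediction,
               stats::setNames(aggregate_inference(p1$tile_scores, m$agg),
                               m$genes))
  # duplicating every tile with doubled L leaves the prediction unchanged
  dup <- tile_bag("dup", bag$patient_id, bag$cohort,
                  rbind(bag$coords, bag$coords + 1000L),
                  rbind(bag$features, bag$features))
  L <- c(1L, 2L, 6L)
  pa <- aggregate_inference(p1$tile_scores, aggregation_spec(L = L))
  sc_dup <- forward_tiles(dup$features, m)
  pb <- aggregate_inference(sc_dup, aggregation_spec(L = 2L * L))
  expect_equal(unname(pa), unname(pb), tolerance = 1e-12)
})

test_that("fine-tuning guards widths and zero epochs is the identity", {
  sim <- tiny_sim()
  m <- train_tile_model(sim$bags, sim$expression,
                        cfg = desk_train_config(seed = 4L, max_epochs = 10L))
  cfg0 <- m$cfg; cfg0$max_epochs <- 0L
  same <- finetune_full_scale(m, sim$bags, sim$expression, cfg = cfg0)
  expect_identical(same$net$W, m$net$W)
  expect_identical(same$agg$mode, "full")
  wrong <- lapply(sim$bags, function(b) {
    tile_bag(b$slide_id, b$patient_id, b$cohort, b$coords,
             cbind(b$features, 0))
  })
  expect_error(finetune_full_scale(m, wrong, sim$expression), "width")
})

test_that("slides without expression rows are rejected", {
  sim <- tiny_sim()
  em <- subset_expression(sim$expression,
                          samples = sample_ids(sim$expression)[-1])
  expect_error(train_tile_model(sim$bags, em, cfg = desk_train_config()),
               "without expression")
})
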