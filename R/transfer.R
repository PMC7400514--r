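# Two-hospital transfer experiment: learn a transcriptomic representation at
# hospital A by mean-pooled expression regression, transfer it to hospital B
# for small-cohort binary classification (MSI-style), against raw-feature
# and autoencoder baselines, with a bootstrap split harness and a paired
# Wilcoxon comparison of AUC distributions.

#' Transfer experiment configuration
#'
#' Defaults follow the conventional protocol: 50 bootstrap A/B splits,
#' 3-fold cross-validation at each hospital, 50 training epochs without
#' hyperparameter tuning. Architecture widths default to the full-size
#' models (encoder 1024/256 sigmoid, raw classifier 256/128 sigmoid,
#' autoencoder 1024/256/1024 ReLU); pass smaller widths for desk-scale runs.
#'
#' @param b_fractions fractions of patients assigned to hospital B, one
#'   experiment per value.
#' @param n_bootstrap bootstrap splits per fraction.
#' @param cv_folds folds for the hospital-A regression and the hospital-B
#'   classifier (both patient-grouped).
#' @param epochs training epochs for every network.
#' @param repr_hidden encoder hidden widths; the last entry is the
#'   representation width (256 by default).
#' @param clf_hidden raw-classifier hidden widths; the representation
#'   classifier uses the same minus the first layer.
#' @param ae_hidden autoencoder hidden widths (bottleneck in the middle).
#' @param lr learning rate; batch_size minibatch size.
#' @param batch_size minibatch size.
#' @param seed RNG seed.
#' @return an object of class `transfer_config`.
#' @export
transfer_config <- function(b_fractions = 0.25, n_bootstrap = 50L,
                            cv_folds = 3L, epochs = 50L,
                            repr_hidden = c(1024L, 256L),
                            clf_hidden = c(256L, 128L),
                            ae_hidden = c(1024L, 256L, 1024L),
                            lr = 3e-4, batch_size = 16L, seed = 1L) {
  if (any(b_fractions <= 0) || any(b_fractions >= 1)) {
    stop_config("b_fractions must lie in (0, 1)")
  }
  if (!is_count(n_bootstrap)) stop_config("n_bootstrap must be >= 1")
  if (length(ae_hidden) %% 2L != 1L) {
    stop_config("ae_hidden needs an odd number of layers (bottleneck in the middle)")
  }
  structure(list(b_fractions = b_fractions,
                 n_bootstrap = as.integer(n_bootstrap),
                 cv_folds = as.integer(cv_folds),
                 epochs = as.integer(epochs),
                 repr_hidden = as.integer(repr_hidden),
                 clf_hidden = as.integer(clf_hidden),
                 ae_hidden = as.integer(ae_hidden),
                 lr = lr, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "transfer_config")
}

# simple patient-grouped fold ids for a patient vector
grouped_folds <- function(patients, n_folds, seed = NULL, labels = NULL) {
  upat <- unique(patients)
  with_seed(seed, {
    if (is.null(labels)) {
      upat <- sample(upat)
      fold <- stats::setNames((seq_along(upat) - 1L) %% n_folds, upat)
    } else {
      # stratified by patient label so each fold sees both classes
      lab <- labels[upat]
      fold <- stats::setNames(integer(length(upat)), upat)
      for (cl in unique(lab)) {
        grp <- sample(upat[lab == cl])
        fold[grp] <- (seq_along(grp) - 1L) %% n_folds
      }
    }
    fold[patients]
  })
}

#' Learn the transcriptomic representation at hospital A
#'
#' Trains the "one supertile" regression: a dense encoder (sigmoid hidden
#' layers, 256-unit representation by default) plus a linear head predicting
#' all genes' log expression from the mean-pooled bag vector, for
#' `cfg$epochs` epochs under MSE, in a `cfg$cv_folds`-fold patient-grouped
#' cross-validation over hospital A. Labels are never accessed. The
#' representation of an outside sample is the average of the fold models'
#' encoder outputs.
#'
#' @param pooled_a samples x d matrix of mean-pooled features (hospital A).
#' @param expr_a raw [expression_matrix()] for the same samples.
#' @param patients_a patient id per row of `pooled_a`.
#' @param cfg a [transfer_config()].
#' @param b_patients optional patient ids of hospital B; any overlap with
#'   hospital A aborts (leakage guard).
#' @return object of class `representation_model` with the fold networks.
#' @export
train_representation <- function(pooled_a, expr_a, patients_a,
                                 cfg = transfer_config(),
                                 b_patients = NULL) {
  pooled_a <- as.matrix(pooled_a)
  stopifnot(nrow(pooled_a) == length(patients_a))
  if (!is.null(b_patients) && length(intersect(patients_a, b_patients))) {
    stop_data("patient overlap between hospitals A and B: leakage")
  }
  Y <- log_values(expr_a)[rownames(pooled_a), , drop = FALSE]
  d <- ncol(pooled_a)
  sizes <- c(d, cfg$repr_hidden, ncol(Y))
  acts <- c(rep("sigmoid", length(cfg$repr_hidden)), "linear")
  folds <- grouped_folds(patients_a, cfg$cv_folds,
                         seed = child_seed(cfg$seed, 101L))
  nets <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    net <- mlp_init(sizes, acts, seed = child_seed(cfg$seed, 200L + f))
    fit <- mlp_fit(net, pooled_a[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                   loss = "mse", epochs = cfg$epochs,
                   batch_size = cfg$batch_size, lr = cfg$lr,
                   seed = child_seed(cfg$seed, 300L + f))
    nets[[as.character(f)]] <- fit$net
  }
  structure(list(nets = nets, repr_layer = length(cfg$repr_hidden),
                 repr_width = cfg$repr_hidden[length(cfg$repr_hidden)],
                 input_dim = d),
            class = "representation_model")
}

#' Transcriptomic representation of pooled vectors
#'
#' @param model a `representation_model`.
#' @param pooled samples x d matrix.
#' @return samples x repr_width matrix (mean over the fold models).
#' @export
predict_representation <- function(model, pooled) {
  pooled <- as.matrix(pooled)
  acc <- 0
  for (net in model$nets) {
    acc <- acc + mlp_activations(net, pooled, model$repr_layer)
  }
  out <- acc / length(model$nets)
  rownames(out) <- rownames(pooled)
  out
}

# Shared classifier CV: X rows = samples, y/patients aligned. Returns
# patient-level AUC from out-of-fold predictions averaged per patient.
classifier_cv <- function(X, y, patients, hidden, cfg, seed_offset,
                          max_redraws = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  sizes <- c(ncol(X), hidden, 1L)
  acts <- rep("sigmoid", length(hidden) + 1L)
  lab_of <- tapply(y, patients, function(v) v[1L])
  pred <- rep(NA_real_, length(y))
  for (redraw in seq_len(max_redraws)) {
    folds <- grouped_folds(patients, cfg$cv_folds,
                           seed = child_seed(cfg$seed,
                                             seed_offset + 17L * redraw),
                           labels = lab_of)
    ok <- all(vapply(sort(unique(folds)), function(f) {
      length(unique(y[folds != f])) == 2L
    }, logical(1)))
    if (ok) break
    if (redraw == max_redraws) stop_data("could not draw two-class folds")
  }
  for (f in sort(unique(folds))) {
    tr <- folds != f
    # z-score features on the training fold; representations can otherwise
    # sit on arbitrarily compressed scales a fixed-budget classifier
    # cannot exploit
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- pmax(apply(X[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    net <- mlp_init(sizes, acts,
                    seed = child_seed(cfg$seed, seed_offset + 500L + f))
    fit <- mlp_fit(net, Xs[tr, , drop = FALSE],
                   matrix(y[tr], ncol = 1L), loss = "bce",
                   epochs = cfg$epochs, batch_size = cfg$batch_size,
                   lr = cfg$lr,
                   seed = child_seed(cfg$seed, seed_offset + 900L + f))
    pred[!tr] <- mlp_forward(fit$net, Xs[!tr, , drop = FALSE])$out
  }
  pp <- tapply(pred, patients, mean)       # one prediction per patient
  list(auc = rank_auc(pp[names(lab_of)], lab_of == 1),
       patient_pred = pp, folds = folds)
}

#' Raw-feature classifier at hospital B
#'
#' Sigmoid MLP (hidden 256/128 by default, one sigmoid output) on the
#' mean-pooled bag vectors, trained with binary cross-entropy in a
#' patient-grouped `cfg$cv_folds`-fold CV; predictions are averaged over a
#' patient's samples before computing the patient-level AUC. A fold whose
#' training side is single-class triggers a redraw of the folds.
#'
#' @param pooled_b samples x d matrix (hospital B).
#' @param labels_b 0/1 label per sample (constant within patient).
#' @param patients_b patient id per sample.
#' @param cfg a [transfer_config()].
#' @return list `auc` (patient-level), `patient_pred`.
#' @export
train_classifier_raw <- function(pooled_b, labels_b, patients_b,
                                 cfg = transfer_config()) {
  classifier_cv(pooled_b, labels_b, patients_b, cfg$clf_hidden, cfg,
                seed_offset = 1000L)
}

#' Representation classifier at hospital B
#'
#' Same protocol as [train_classifier_raw()] but on the 256-dimensional
#' transcriptomic (or autoencoder) representation, with the classifier's
#' first hidden layer removed.
#'
#' @param repr_b samples x repr_width matrix.
#' @param labels_b,patients_b,cfg as in [train_classifier_raw()].
#' @param seed_offset internal stream separator.
#' @return list `auc`, `patient_pred`.
#' @export
train_classifier_repr <- function(repr_b, labels_b, patients_b,
                                  cfg = transfer_config(),
                                  seed_offset = 2000L) {
  hidden <- cfg$clf_hidden[-1L]
  if (!length(hidden)) hidden <- integer()
  classifier_cv(repr_b, labels_b, patients_b, hidden, cfg,
                seed_offset = seed_offset)
}

#' Autoencoder baseline representation
#'
#' Mirror-architecture autoencoder (hidden 1024/256/1024 ReLU, linear
#' output) trained on pooled vectors of one hospital with reconstruction
#' MSE; the bottleneck activations are the baseline representation.
#'
#' @param pooled samples x d matrix (unlabeled).
#' @param cfg a [transfer_config()].
#' @param seed_offset internal stream separator.
#' @return list `encode` (function mapping pooled vectors to bottleneck
#'   activations), `net`, `loss` (per-epoch), `bottleneck`.
#' @export
train_autoencoder_baseline <- function(pooled, cfg = transfer_config(),
                                       seed_offset = 3000L) {
  pooled <- as.matrix(pooled)
  d <- ncol(pooled)
  sizes <- c(d, cfg$ae_hidden, d)
  acts <- c(rep("relu", length(cfg$ae_hidden)), "linear")
  net <- mlp_init(sizes, acts, seed = child_seed(cfg$seed, seed_offset))
  fit <- mlp_fit(net, pooled, pooled, loss = "mse", epochs = cfg$epochs,
                 batch_size = cfg$batch_size, lr = cfg$lr,
                 seed = child_seed(cfg$seed, seed_offset + 1L))
  bott <- (length(cfg$ae_hidden) + 1L) %/% 2L
  list(encode = function(X) mlp_activations(fit$net, as.matrix(X), bott),
       net = fit$net, loss = fit$loss,
       bottleneck = cfg$ae_hidden[bott])
}

#' Bootstrapped two-hospital split harness
#'
#' For each B-fraction and bootstrap replicate: split patients (stratified
#' by label so small B subsets keep both classes) into hospitals A and B,
#' learn the transcriptomic representation at A, train the four classifiers
#' at B — raw pooled features, transcriptomic representation, autoencoder-A
#' representation, autoencoder-B representation — and record patient-level
#' AUCs.
#'
#' @param pooled samples x d matrix of mean-pooled features, all patients.
#' @param expr raw [expression_matrix()] over the same samples.
#' @param patients patient id per sample.
#' @param labels per-patient 0/1 labels (named by patient id).
#' @param cfg a [transfer_config()].
#' @return long data frame `fraction`, `bootstrap`, `method`, `auc` with
#'   methods `raw`, `transcriptome`, `ae_A`, `ae_B`.
#' @export
hospital_split_harness <- function(pooled, expr, patients, labels,
                                   cfg = transfer_config()) {
  pooled <- as.matrix(pooled)
  stopifnot(nrow(pooled) == length(patients))
  upat <- unique(patients)
  lab <- labels[upat]
  if (anyNA(lab)) stop_data("patients without labels")
  out <- list()
  for (frac in cfg$b_fractions) {
    n_b <- round(frac * length(upat))
    if (n_b < cfg$cv_folds * 2L) {
      stop_config("fraction ", frac, " leaves hospital B with fewer than ",
                  cfg$cv_folds * 2L, " labeled patients")
    }
    for (boot in seq_len(cfg$n_bootstrap)) {
      sd_b <- child_seed(cfg$seed, round(1e4 * frac) + 131L * boot)
      b_pat <- with_seed(sd_b, {
        # stratified draw of hospital B patients
        unlist(lapply(unique(lab), function(cl) {
          grp <- upat[lab == cl]
          sample(grp, max(1L, round(frac * length(grp))))
        }))
      })
      a_pat <- setdiff(upat, b_pat)
      in_b <- patients %in% b_pat
      cfg_i <- cfg
      cfg_i$seed <- sd_b
      repr_model <- train_representation(
        pooled[!in_b, , drop = FALSE],
        subset_expression(expr, samples = rownames(pooled)[!in_b]),
        patients[!in_b], cfg_i, b_patients = b_pat)
      repr_b <- predict_representation(repr_model,
                                       pooled[in_b, , drop = FALSE])
      ae_a <- train_autoencoder_baseline(pooled[!in_b, , drop = FALSE],
                                         cfg_i, seed_offset = 3000L)
      ae_b <- train_autoencoder_baseline(pooled[in_b, , drop = FALSE],
                                         cfg_i, seed_offset = 4000L)
      y_b <- labels[patients[in_b]]
      p_b <- patients[in_b]
      aucs <- c(
        raw = train_classifier_raw(pooled[in_b, , drop = FALSE], y_b, p_b,
                                   cfg_i)$auc,
        transcriptome = train_classifier_repr(repr_b, y_b, p_b, cfg_i,
                                              seed_offset = 2000L)$auc,
        ae_A = train_classifier_repr(ae_a$encode(pooled[in_b, , drop = FALSE]),
                                     y_b, p_b, cfg_i,
                                     seed_offset = 5000L)$auc,
        ae_B = train_classifier_repr(ae_b$encode(pooled[in_b, , drop = FALSE]),
                                     y_b, p_b, cfg_i,
                                     seed_offset = 6000L)$auc)
      out[[length(out) + 1L]] <- data.frame(fraction = frac,
                                            bootstrap = boot,
                                            method = names(aucs),
                                            auc = unname(aucs))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-tailed Wilcoxon signed-rank test for paired AUC distributions
#'
#' Paired per bootstrap split. Zero differences are dropped; midranks handle
#' ties among absolute differences. The null distribution is exact (computed
#' by sign-flip convolution over the observed midranks) for up to 25 nonzero
#' pairs, and a normal approximation with continuity and tie correction
#' beyond that.
#'
#' @param aucs_x,aucs_y paired numeric vectors.
#' @return list `p`, `statistic` (signed-rank sum W of positive
#'   differences), `n_nonzero`, `method`.
#' @export
compare_auc_distributions <- function(aucs_x, aucs_y) {
  stopifnot(length(aucs_x) == length(aucs_y))
  d <- aucs_x - aucs_y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(list(p = 1, statistic = 0, n_nonzero = 0L,
                           method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact sign-flip distribution over doubled midranks (integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    probs <- numeric(total + 1L)  # index = W2 value + 1
    probs[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(total + 1L - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(p = p, statistic = W, n_nonzero = n, method = method)
}
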