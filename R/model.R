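# The regression core: a per-tile MLP shared across tiles, trained
# multi-task on all genes with stochastic top-k aggregation and evaluated
# with a deterministic multi-k average.

#' Model architecture specification
#'
#' The per-tile network is an MLP applied independently to every tile
#' (equivalently, 1D convolutions of kernel size 1): rectified-linear hidden
#' layers with dropout in between, linear output of width `n_genes`.
#' Hidden sizes default to 1024 then 256 (sized for 2048-dimensional CNN
#' features; scale them down with the feature dimension).
#'
#' @param input_dim tile feature width d.
#' @param n_genes number of output genes.
#' @param hidden integer vector of hidden-layer widths.
#' @param dropout dropout probability in `[0, 1)` between consecutive layers.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(input_dim, n_genes, hidden = c(1024L, 256L),
                       dropout = 0.25) {
  stopifnot(is_count(input_dim), is_count(n_genes),
            all(vapply(hidden, is_count, logical(1))))
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 n_genes = as.integer(n_genes),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "model_spec")
}

#' Top-k aggregation specification
#'
#' The list L of k values: during training one k is drawn uniformly from L at
#' each optimizer step; at inference the slide prediction averages S(k) over
#' all k in L. Any k exceeding a slide's tile count is capped at the tile
#' count.
#'
#' @param L strictly increasing positive integers.
#' @param mode `"supertile"` or `"full"`; selects the conventional default L
#'   when `L` is `NULL`: (1, 2, 5, 10, 20, 50, 100) for supertile bags,
#'   (10, 20, 50, 100, 200, 500, 1000, 2000, 5000) for full-scale bags.
#' @return an object of class `aggregation_spec`.
#' @export
aggregation_spec <- function(L = NULL, mode = c("supertile", "full")) {
  mode <- match.arg(mode)
  if (is.null(L)) {
    L <- if (mode == "supertile") c(1L, 2L, 5L, 10L, 20L, 50L, 100L)
         else c(10L, 20L, 50L, 100L, 200L, 500L, 1000L, 2000L, 5000L)
  }
  L <- as.integer(L)
  if (length(L) < 1L || any(L < 1L) || is.unsorted(L, strictly = TRUE)) {
    stop_config("L must be a strictly increasing list of positive integers")
  }
  structure(list(L = L, mode = mode), class = "aggregation_spec")
}

#' Training configuration
#'
#' Conventional settings: Adam with learning rate 3e-4, minibatch 16 for
#' supertile bags (4 for full-scale), at most 200 epochs with early stopping
#' once the validation metric has not improved for 50 consecutive epochs,
#' a 10% patient-grouped validation split, mean squared error on
#' log-transformed expression.
#'
#' @param learning_rate Adam step size.
#' @param batch_size slides per optimizer step.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation improvement before stopping;
#'   must be below `max_epochs`.
#' @param val_fraction fraction of training slides held out (patient-grouped)
#'   for the early-stopping metric.
#' @param val_smooth width (in epochs) of the trailing mean applied to the
#'   validation metric before the improvement test. 1 (default) disables
#'   smoothing. On small cohorts the per-epoch metric is noisy enough that
#'   restore-best otherwise locks onto a chance peak; a window of 10-20
#'   epochs makes model selection track the trend instead.
#' @param restore_best restore the weights of the best validation epoch
#'   (default) rather than keeping the final weights.
#' @param metric_order `"cohort_then_gene"` (default: mean over cohorts of
#'   per-cohort gene means) or `"gene_then_cohort"` for the early-stopping
#'   metric.
#' @param seed RNG seed covering initialization, shuffling, k draws, dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 16L,
                         max_epochs = 200L, patience = 50L,
                         val_fraction = 0.10, val_smooth = 1L,
                         restore_best = TRUE,
                         metric_order = c("cohort_then_gene",
                                          "gene_then_cohort"),
                         seed = 1L) {
  metric_order <- match.arg(metric_order)
  if (!(val_fraction > 0 && val_fraction < 1)) {
    stop_config("val_fraction must be in (0, 1)")
  }
  if (patience >= max_epochs) stop_config("patience must be < max_epochs")
  if (!is_count(val_smooth)) stop_config("val_smooth must be a count >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 val_smooth = as.integer(val_smooth),
                 restore_best = isTRUE(restore_best),
                 metric_order = metric_order,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Per-tile forward pass
#'
#' Applies the shared MLP independently to each tile (row); output row order
#' matches tile order, so permuting tiles permutes scores identically.
#'
#' @param features n_tiles x d matrix.
#' @param model a trained `tile_model` (or a raw `mlp` of matching width).
#' @return n_tiles x n_genes score matrix.
#' @export
forward_tiles <- function(features, model) {
  net <- if (inherits(model, "tile_model")) model$net else model
  mlp_forward(net, features)$out
}

#' Training aggregation: mean of the k highest tile scores
#'
#' For each gene independently, sorts that gene's tile scores in decreasing
#' order and returns the mean of the top k: `S(k) = sum_{i=1}^k s_i / k`.
#' `k` is capped at the tile count; ties are broken by tile index.
#'
#' @param tile_scores n_tiles x n_genes matrix.
#' @param k number of tiles to average.
#' @return numeric vector of length n_genes.
#' @export
aggregate_train <- function(tile_scores, k) {
  stopifnot(is_count(k))
  tile_scores <- as.matrix(tile_scores)
  k <- min(k, nrow(tile_scores))
  out <- .cpp_topk(tile_scores, as.integer(k))$means
  names(out) <- colnames(tile_scores)
  out
}

#' Inference aggregation: average of S(k) over k in L
#'
#' Deterministic slide-level prediction `S = sum_{k in L} S(k) / |L|`, each k
#' capped at the tile count. Equivalent to a fixed weighted mean over
#' rank-ordered tile scores; see [compute_tile_weights()].
#'
#' @param tile_scores n_tiles x n_genes matrix.
#' @param agg an [aggregation_spec()].
#' @return numeric vector of length n_genes.
#' @export
aggregate_inference <- function(tile_scores, agg) {
  stopifnot(inherits(agg, "aggregation_spec"))
  tile_scores <- as.matrix(tile_scores)
  n <- nrow(tile_scores)
  w <- compute_tile_weights(n, agg$L)
  out <- as.vector(crossprod(.cpp_sort_desc_cols(tile_scores), w))
  names(out) <- colnames(tile_scores)
  out
}

#' Rank weights implied by the inference aggregation
#'
#' The multi-k average is a weighted mean of rank-ordered tile scores with
#' weight `w_i = (1/|L|) * sum_{k in L} 1/min(k, n) * [i <= min(k, n)]` on
#' the i-th largest score. Weights sum to 1 and are non-increasing in rank.
#'
#' @param n_tiles tile count.
#' @param L aggregation list (vector of k values).
#' @return numeric vector of length `n_tiles`.
#' @export
compute_tile_weights <- function(n_tiles, L) {
  stopifnot(is_count(n_tiles), length(L) >= 1L)
  kc <- pmin(as.integer(L), n_tiles)
  w <- numeric(n_tiles)
  for (k in kc) w[seq_len(k)] <- w[seq_len(k)] + 1 / k
  w / length(L)
}

# ---- training ---------------------------------------------------------

# Stack a list of bags into one matrix with row offsets, forward once.
stack_features <- function(bags) {
  feats <- lapply(bags, function(b) b$features)
  nt <- vapply(feats, nrow, integer(1))
  list(X = do.call(rbind, feats), n = nt,
       end = cumsum(nt), start = cumsum(nt) - nt + 1L)
}

# Validation metric: per-gene Pearson R per cohort on slide predictions,
# then averaged in the configured order.
validation_metric <- function(pred, truth, cohorts, order_mode,
                              warn_small = TRUE) {
  by_cohort <- split(seq_len(nrow(pred)), cohorts)
  gene_means <- c()
  all_r <- list()
  for (co in names(by_cohort)) {
    rows <- by_cohort[[co]]
    if (length(rows) < 2L) {
      if (warn_small) warning("cohort ", co,
                              " has <2 validation samples; excluded")
      next
    }
    r <- colwise_pearson(pred[rows, , drop = FALSE],
                         truth[rows, , drop = FALSE])
    all_r[[co]] <- r
    gene_means <- c(gene_means, mean(r, na.rm = TRUE))
  }
  if (!length(all_r)) return(NA_real_)
  if (order_mode == "cohort_then_gene") {
    mean(gene_means, na.rm = TRUE)
  } else {
    rmat <- do.call(rbind, all_r)
    mean(colMeans(rmat, na.rm = TRUE), na.rm = TRUE)
  }
}

#' Train the per-tile regression model
#'
#' Multi-task training on all genes at once. Each optimizer step draws one k
#' uniformly from L (shared across genes and the slides of the minibatch),
#' aggregates tile scores with [aggregate_train()], and minimizes mean
#' squared error against log-transformed expression, averaged over genes and
#' slides. A patient-grouped validation split (fraction
#' `cfg$val_fraction`) drives early stopping on the mean per-gene, per-cohort
#' validation correlation; the best weights are restored.
#'
#' @param bags list of `tile_bag` / `supertile_bag` objects.
#' @param expr an [expression_matrix()] with one row per slide (raw values;
#'   the log transform is applied internally).
#' @param spec a [model_spec()]; `NULL` derives one from the data with
#'   hidden sizes scaled to the feature width.
#' @param agg an [aggregation_spec()].
#' @param cfg a [train_config()].
#' @param init optional `mlp` to warm-start from (used by
#'   [finetune_full_scale()]).
#' @return an object of class `tile_model`: the network, specs, training
#'   history (epoch, loss, validation metric) and the best epoch.
#' @export
train_tile_model <- function(bags, expr, spec = NULL,
                             agg = aggregation_spec(mode = "supertile"),
                             cfg = train_config(), init = NULL) {
  stopifnot(length(bags) >= 2L, inherits(expr, "expression_matrix"))
  ids <- vapply(bags, function(b) b$slide_id, character(1))
  names(bags) <- ids
  missing <- setdiff(ids, sample_ids(expr))
  if (length(missing)) {
    stop_data("slides without expression rows: ",
              paste(utils::head(missing, 3), collapse = ", "))
  }
  Y <- log_values(expr)[ids, , drop = FALSE]
  d <- ncol(bags[[1L]]$features)
  if (is.null(spec)) {
    spec <- model_spec(d, ncol(Y), hidden = pmax(8L, c(2L, 1L) * d),
                       dropout = 0.25)
  }
  if (spec$input_dim != d) {
    stop_data("feature width ", d, " does not match model input width ",
              spec$input_dim)
  }
  if (spec$n_genes != ncol(Y)) {
    stop_data("model output width ", spec$n_genes, " does not match ",
              ncol(Y), " genes")
  }
  patients <- vapply(bags, function(b) b$patient_id, character(1))
  cohorts <- vapply(bags, function(b) b$cohort, character(1))

  with_seed(cfg$seed, {
    # patient-grouped validation split
    upat <- unique(patients)
    n_val_pat <- max(1L, round(cfg$val_fraction * length(upat)))
    val_pat <- sample(upat, n_val_pat)
    val_ids <- ids[patients %in% val_pat]
    tr_ids <- setdiff(ids, val_ids)
    if (length(tr_ids) < 1L) stop_data("no training slides left after split")

    sizes <- c(spec$input_dim, spec$hidden, spec$n_genes)
    acts <- c(rep("relu", length(spec$hidden)), "linear")
    net <- if (is.null(init)) mlp_init(sizes, acts) else init
    state <- adam_init(net)

    best <- list(metric = -Inf, net = net, epoch = 0L)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_metric = numeric())
    stall <- 0L
    warned_small <- FALSE
    use_loss_metric <- FALSE

    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_ids)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        k_draw <- agg$L[sample.int(length(agg$L), 1L)]
        st <- stack_features(bags[batch])
        fwd <- mlp_forward(net, st$X, dropout = spec$dropout,
                           training = TRUE, cache = TRUE)
        S <- fwd$out
        dOut <- matrix(0, nrow(S), ncol(S))
        lval <- 0
        G <- ncol(S)
        for (j in seq_along(batch)) {
          rows <- st$start[j]:st$end[j]
          sc <- S[rows, , drop = FALSE]
          k <- min(k_draw, length(rows))
          y <- Y[batch[j], ]
          # top-k indices per gene in one compiled pass; rows are disjoint
          # across slides so direct assignment into dOut is safe
          tk <- .cpp_topk(sc, as.integer(k))
          idx <- tk$idx
          gcol <- rep(seq_len(G), each = k)
          resid <- tk$means - y
          lval <- lval + sum(resid^2)
          dOut[cbind(rows[as.vector(idx)], gcol)] <-
            rep(2 * resid / (k * G * length(batch)), each = k)
        }
        lval <- lval / (ncol(S) * length(batch))
        if (!is.finite(lval)) {
          stop_data("non-finite loss at epoch ", ep, ", batch starting ",
                    start, "; check inputs for extreme values")
        }
        grads <- mlp_backward(net, fwd, dOut = dOut)
        stp <- adam_step(net, grads, state, lr = cfg$learning_rate)
        net <- stp$net; state <- stp$state
        ep_loss <- ep_loss + lval; nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb

      # validation metric (dropout off)
      vp <- matrix(NA_real_, length(val_ids), spec$n_genes)
      for (j in seq_along(val_ids)) {
        sc <- forward_tiles(bags[[val_ids[j]]]$features, net)
        vp[j, ] <- aggregate_inference(sc, agg)
      }
      vm <- validation_metric(vp, Y[val_ids, , drop = FALSE],
                              cohorts[match(val_ids, ids)],
                              cfg$metric_order,
                              warn_small = !warned_small)
      warned_small <- TRUE
      if (is.na(vm)) {
        if (!use_loss_metric) {
          warning("validation metric undefined; early stopping on training ",
                  "loss instead")
          use_loss_metric <- TRUE
        }
        vm_eff <- -ep_loss
      } else vm_eff <- vm
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                     val_metric = vm))
      if (cfg$val_smooth > 1L) {
        recent <- if (use_loss_metric) -hist$loss else hist$val_metric
        vm_eff <- mean(utils::tail(recent, cfg$val_smooth))
      }
      if (vm_eff > best$metric + 1e-12) {
        best <- list(metric = vm_eff, net = net, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }

    final_net <- if (isTRUE(cfg$restore_best)) best$net else net
    structure(list(net = final_net, spec = spec, agg = agg, cfg = cfg,
                   genes = colnames(Y), history = hist,
                   best_epoch = best$epoch, best_metric = best$metric,
                   val_slides = val_ids),
              class = "tile_model")
  })
}

#' @export
print.tile_model <- function(x, ...) {
  cat(sprintf(paste0("<tile_model> d=%d -> [%s] -> %d genes; best epoch %d",
                     " (val metric %.3f)\n"),
              x$spec$input_dim, paste(x$spec$hidden, collapse = ","),
              x$spec$n_genes, x$best_epoch, x$best_metric))
  invisible(x)
}

#' Fine-tune a supertile-trained model on full-scale bags
#'
#' Resumes optimization from trained weights on per-tile (non-clustered)
#' bags, with the full-scale aggregation list and a smaller batch size.
#' Zero epochs returns the model unchanged apart from the updated specs.
#'
#' @param model a trained `tile_model`.
#' @param bags full-scale `tile_bag`s of the same feature width.
#' @param expr expression matrix covering the bags.
#' @param agg full-scale [aggregation_spec()].
#' @param cfg a [train_config()]; conventional fine-tuning uses
#'   `max_epochs = 100`, `batch_size = 4`.
#' @return the fine-tuned `tile_model`.
#' @export
finetune_full_scale <- function(model, bags, expr,
                                agg = aggregation_spec(mode = "full"),
                                cfg = NULL) {
  stopifnot(inherits(model, "tile_model"))
  d <- ncol(bags[[1L]]$features)
  if (d != model$spec$input_dim) {
    stop_data("feature width ", d, " does not match model input width ",
              model$spec$input_dim)
  }
  if (is.null(cfg)) {
    cfg <- model$cfg
    cfg$max_epochs <- 100L
    cfg$batch_size <- 4L
  }
  if (cfg$max_epochs == 0L) {
    model$agg <- agg
    return(model)
  }
  out <- train_tile_model(bags, expr, spec = model$spec, agg = agg,
                          cfg = cfg, init = model$net)
  out
}

#' Predict one slide
#'
#' Runs the shared MLP over every tile with dropout disabled and aggregates
#' with the deterministic multi-k average. The per-tile scores are the
#' virtual spatialization input; the slide prediction is always reproducible
#' from them via [aggregate_inference()].
#'
#' @param bag a `tile_bag` (full-scale or supertile).
#' @param model a trained `tile_model`.
#' @param agg aggregation spec; defaults to the model's.
#' @return a `prediction_bundle`: `slide_id`, `tile_scores`
#'   (n_tiles x n_genes), `slide_prediction` (length n_genes), `coords`.
#' @export
predict_slide <- function(bag, model, agg = NULL) {
  stopifnot(inherits(model, "tile_model"))
  if (is.null(agg)) agg <- model$agg
  sc <- forward_tiles(bag$features, model)
  colnames(sc) <- model$genes
  structure(list(slide_id = bag$slide_id,
                 tile_scores = sc,
                 slide_prediction = stats::setNames(
                   aggregate_inference(sc, agg), model$genes),
                 coords = bag$coords),
            class = "prediction_bundle")
}

#' Cross-validated training and held-out prediction
#'
#' Trains one model per fold on the remaining folds and predicts the held-out
#' slides, so every slide gets an out-of-fold prediction. Gene filtering
#' (nonzero median) is fit on the training folds only and the frozen gene
#' list applied to the held-out fold; predictions for genes a fold did not
#' retain are `NA`.
#'
#' @param bags list of bags (training representation, e.g. supertiles).
#' @param expr raw [expression_matrix()] over all slides.
#' @param folds a fold assignment from [make_folds()].
#' @param spec,agg,cfg model, aggregation and training configuration
#'   (`spec = NULL` derives the architecture per fold).
#' @param filter_genes fit the nonzero-median filter inside each fold?
#' @param predict_bags optional list of bags to predict on instead of
#'   `bags` (e.g. full-scale bags for tile-level maps).
#' @return list: `predictions` (slides x genes matrix of out-of-fold slide
#'   predictions), `sample_info` (slide, patient, cohort, fold), `models`
#'   (one per fold), `gene_lists` (retained genes per fold).
#' @export
cross_validate <- function(bags, expr, folds, spec = NULL,
                           agg = aggregation_spec(mode = "supertile"),
                           cfg = train_config(), filter_genes = TRUE,
                           predict_bags = NULL) {
  ids <- vapply(bags, function(b) b$slide_id, character(1))
  names(bags) <- ids
  if (!is.null(predict_bags)) {
    names(predict_bags) <- vapply(predict_bags, function(b) b$slide_id,
                                  character(1))
  }
  patients <- vapply(bags, function(b) b$patient_id, character(1))
  cohorts <- vapply(bags, function(b) b$cohort, character(1))
  fold_of_patient <- stats::setNames(folds$fold, folds$patient_id)
  fold_of_slide <- fold_of_patient[patients]
  if (anyNA(fold_of_slide)) stop_data("slides with patients missing from folds")

  all_genes <- gene_ids(expr)
  pred <- matrix(NA_real_, length(ids), length(all_genes),
                 dimnames = list(ids, all_genes))
  models <- list()
  gene_lists <- list()
  for (f in sort(unique(folds$fold))) {
    tr <- ids[fold_of_slide != f]
    te <- ids[fold_of_slide == f]
    if (!length(te)) next
    ex_tr <- subset_expression(expr, samples = tr)
    if (filter_genes) ex_tr <- filter_genes_nonzero_median(ex_tr)
    genes_f <- gene_ids(ex_tr)
    if (!length(genes_f)) stop_data("fold ", f, ": no genes retained")
    cfg_f <- cfg
    cfg_f$seed <- child_seed(cfg$seed, f)
    m <- train_tile_model(bags[tr], ex_tr, spec = spec, agg = agg,
                          cfg = cfg_f)
    models[[as.character(f)]] <- m
    gene_lists[[as.character(f)]] <- genes_f
    for (sid in te) {
      b <- if (is.null(predict_bags)) bags[[sid]] else predict_bags[[sid]]
      pred[sid, genes_f] <- predict_slide(b, m)$slide_prediction
    }
  }
  list(predictions = pred,
       sample_info = data.frame(sample_id = ids, patient_id = patients,
                                cohort = cohorts,
                                fold = as.integer(fold_of_slide)),
       models = models, gene_lists = gene_lists)
}
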