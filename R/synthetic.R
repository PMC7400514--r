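# Synthetic cohorts: slide bags with latent tile types laid out as spatially
# coherent fields, expression tied to tile-type composition, patient/sample
# hierarchy, multi-cohort structure, and a composition-linked binary label.
# This is the package's stand-in for a paired WSI + RNA-Seq resource and is
# first-class, tested code.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale cohort: one cancer-type cohort of 20
#' patients with 2 slides each (40 slides), 144 tiles per slide on a 12 x 12
#' grid, 32 tile features (a scaled stand-in for the 2048-dimensional CNN
#' features of real pipelines), 4 latent tile types, 5 signal genes whose
#' expression tracks tile-type composition and 50 noise genes that do not.
#'
#' `slide_noise_sd` (default 0, i.e. off) optionally adds one random offset
#' vector per slide in the non-prototype feature directions, emulating
#' slide-level technical variation (staining, scanner batch) that does not
#' average out under pooling. It is an experiment knob, not part of the
#' default generative story: with few slides such an offset acts as a
#' per-slide fingerprint that any flexible model can memorize.
#'
#' @param n_cohorts number of cohorts (cancer types).
#' @param patients_per_cohort patients per cohort.
#' @param slides_per_patient slides per patient; scalar or `c(min, max)`.
#' @param tiles_per_slide tiles per slide; scalar or `c(min, max)`; each
#'   slide is laid out on the smallest square grid holding them.
#' @param feature_dim tile feature dimension (>= `n_tile_types`).
#' @param n_tile_types number of latent tile types.
#' @param n_signal_genes genes linked to one tile type each.
#' @param n_noise_genes genes independent of composition.
#' @param signal_strength scale of the expression-composition link (raw
#'   FPKM-UQ-like units).
#' @param feature_noise_sd isotropic noise around the tile-type prototype.
#' @param slide_noise_sd slide-level feature offset scale (see above).
#' @param expression_noise_sd log-scale multiplicative noise on signal genes.
#' @param label_weights logit weights over tile types for the per-patient
#'   binary label; default contrasts the first two types.
#' @param cv_folds number of CV folds the cohorts must support downstream.
#' @param seed integer seed; everything is reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cohorts = 1L,
                             patients_per_cohort = 20L,
                             slides_per_patient = 2L,
                             tiles_per_slide = 144L,
                             feature_dim = 32L,
                             n_tile_types = 4L,
                             n_signal_genes = 5L,
                             n_noise_genes = 50L,
                             signal_strength = 100,
                             feature_noise_sd = 0.3,
                             slide_noise_sd = 0,
                             expression_noise_sd = 0.1,
                             label_weights = NULL,
                             cv_folds = 5L,
                             seed = 1L) {
  if (is.null(label_weights)) {
    label_weights <- c(8, -8, rep(0, max(0L, n_tile_types - 2L)))
  }
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              patients_per_cohort = as.integer(patients_per_cohort),
              slides_per_patient = as.integer(slides_per_patient),
              tiles_per_slide = as.integer(tiles_per_slide),
              feature_dim = as.integer(feature_dim),
              n_tile_types = as.integer(n_tile_types),
              n_signal_genes = as.integer(n_signal_genes),
              n_noise_genes = as.integer(n_noise_genes),
              signal_strength = signal_strength,
              feature_noise_sd = feature_noise_sd,
              slide_noise_sd = slide_noise_sd,
              expression_noise_sd = expression_noise_sd,
              label_weights = label_weights,
              cv_folds = as.integer(cv_folds),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_cohorts", "patients_per_cohort", "n_tile_types",
              "feature_dim", "n_signal_genes")
  for (f in counts) {
    if (!is_count(cfg[[f]])) stop_config(f, " must be a count >= 1")
  }
  if (!is_count(cfg$n_noise_genes, min = 0L)) {
    stop_config("n_noise_genes must be a count >= 0")
  }
  for (f in c("slides_per_patient", "tiles_per_slide")) {
    v <- cfg[[f]]
    if (!(length(v) %in% 1:2) || any(v < 1) || any(v != floor(v))) {
      stop_config(f, " must be a count or a c(min, max) range")
    }
    if (length(v) == 2L && v[1] > v[2]) stop_config(f, " range inverted")
  }
  if (cfg$feature_dim < cfg$n_tile_types) {
    stop_config("feature_dim must be >= n_tile_types")
  }
  for (f in c("feature_noise_sd", "slide_noise_sd", "expression_noise_sd")) {
    if (cfg[[f]] < 0) stop_config(f, " must be >= 0")
  }
  if (cfg$signal_strength <= 0) stop_config("signal_strength must be > 0")
  if (length(cfg$label_weights) != cfg$n_tile_types) {
    stop_config("label_weights must have one entry per tile type")
  }
  if (cfg$patients_per_cohort < cfg$cv_folds) {
    stop_config("each cohort needs at least cv_folds (", cfg$cv_folds,
                ") patients; got ", cfg$patients_per_cohort)
  }
  invisible(cfg)
}

draw_count <- function(v) {
  if (length(v) == 1L) v else sample(v[1]:v[2], 1L)
}

# Smooth a grid of white noise with a separable box filter; cheap stand-in
# for a Gaussian random field giving spatially coherent tile types.
smooth_field <- function(mat, passes = 2L) {
  for (p in seq_len(passes)) {
    mat <- (mat +
              rbind(mat[1, , drop = FALSE], mat[-nrow(mat), , drop = FALSE]) +
              rbind(mat[-1, , drop = FALSE], mat[nrow(mat), , drop = FALSE]) +
              cbind(mat[, 1, drop = FALSE], mat[, -ncol(mat), drop = FALSE]) +
              cbind(mat[, -1, drop = FALSE], mat[, ncol(mat), drop = FALSE])) / 5
  }
  mat
}

#' Generate synthetic cohorts
#'
#' Produces slide bags, a sample x gene expression matrix, per-tile ground
#' truth and per-patient binary labels with the statistical structure the
#' model assumes:
#' \itemize{
#'   \item tile types form smoothed random fields on each slide's grid, so
#'     spatial clustering (supertiles) sees coherent structure;
#'   \item tile features are orthogonal unit-vector prototypes plus isotropic
#'     noise plus a per-slide offset (technical variation);
#'   \item each signal gene g linked to type t has raw expression
#'     `signal_strength * coef_g * fraction_t(slide) * exp(eps)` with
#'     `eps ~ N(0, expression_noise_sd)`; noise genes are log-normal and
#'     independent of composition;
#'   \item the per-patient label is Bernoulli(logistic(label_weights .
#'     patient mean composition, centered)).
#' }
#'
#' @param cfg a [synthetic_config()].
#' @return list with `bags` (list of [tile_bag()]), `expression`
#'   (an [expression_matrix()] of raw values, one row per slide), `truth`
#'   (tile types per slide, gene links, label weights, per-patient labels,
#'   per-slide compositions), `labels` (patient label table) and `manifest`
#'   (slide_id, patient_id, cohort).
#' @export
generate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    T <- cfg$n_tile_types
    d <- cfg$feature_dim
    protos <- diag(1, T, d)  # orthogonal unit prototypes embedded in d dims

    genes <- c(if (cfg$n_signal_genes > 0)
                 sprintf("SIG%02d", seq_len(cfg$n_signal_genes)),
               if (cfg$n_noise_genes > 0)
                 sprintf("NOISE%03d", seq_len(cfg$n_noise_genes)))
    gene_links <- if (cfg$n_signal_genes > 0) {
      data.frame(gene = sprintf("SIG%02d", seq_len(cfg$n_signal_genes)),
                 tile_type = ((seq_len(cfg$n_signal_genes) - 1L) %% T) + 1L,
                 coefficient = stats::runif(cfg$n_signal_genes, 0.5, 1.5))
    } else {
      data.frame(gene = character(), tile_type = integer(),
                 coefficient = numeric())
    }
    noise_meanlog <- stats::rnorm(cfg$n_noise_genes, log(50), 1)

    bags <- list()
    manifest <- list()
    tile_types <- list()
    comp_rows <- list()
    expr_rows <- list()
    patient_ids <- character()
    patient_cohort <- character()
    patient_comp <- list()

    for (co in seq_len(cfg$n_cohorts)) {
      cohort <- sprintf("COHORT%d", co)
      for (p in seq_len(cfg$patients_per_cohort)) {
        pid <- sprintf("%s-P%03d", cohort, p)
        patient_ids <- c(patient_ids, pid)
        patient_cohort <- c(patient_cohort, cohort)
        n_slides <- draw_count(cfg$slides_per_patient)
        # patient-level type bias: slides of one patient share composition
        patient_bias <- stats::rnorm(T, 0, 0.8)
        comps <- matrix(0, n_slides, T)
        for (s in seq_len(n_slides)) {
          sid <- sprintf("%s-S%d", pid, s)
          nt <- draw_count(cfg$tiles_per_slide)
          side <- ceiling(sqrt(nt))
          cells <- seq_len(nt) - 1L
          coords <- cbind(x = cells %% side, y = cells %/% side)
          # per-type smoothed random field + patient bias; type = argmax
          fields <- vapply(seq_len(T), function(t) {
            f <- smooth_field(matrix(stats::rnorm(side * side), side, side))
            patient_bias[t] + stats::rnorm(1, 0, 0.4) +
              2.5 * as.vector(f)[cells + 1L]
          }, numeric(nt))
          types <- max.col(fields, ties.method = "first")
          feats <- protos[types, , drop = FALSE] +
            matrix(stats::rnorm(nt * d, 0, cfg$feature_noise_sd), nt, d)
          if (cfg$slide_noise_sd > 0 && d > T) {
            # technical variation is confined to the non-prototype
            # directions: nuisance that survives pooling without erasing
            # the composition signal itself
            offset <- c(numeric(T),
                        stats::rnorm(d - T, 0, cfg$slide_noise_sd))
            feats <- feats + rep(offset, each = nt)
          }
          bag <- tile_bag(sid, pid, cohort, coords, feats)
          bags[[sid]] <- bag
          tile_types[[sid]] <- types
          frac <- tabulate(types, nbins = T) / nt
          comps[s, ] <- frac
          comp_rows[[sid]] <- frac

          sig <- if (cfg$n_signal_genes > 0) {
            eps <- stats::rnorm(cfg$n_signal_genes, 0,
                                cfg$expression_noise_sd)
            cfg$signal_strength * gene_links$coefficient *
              frac[gene_links$tile_type] * exp(eps)
          } else numeric()
          noi <- if (cfg$n_noise_genes > 0) {
            exp(noise_meanlog + stats::rnorm(cfg$n_noise_genes, 0, 0.5))
          } else numeric()
          expr_rows[[sid]] <- c(sig, noi)
          manifest[[sid]] <- data.frame(slide_id = sid, patient_id = pid,
                                        cohort = cohort)
        }
        patient_comp[[pid]] <- colMeans(comps)
      }
    }

    expr <- do.call(rbind, expr_rows)
    dimnames(expr) <- list(names(expr_rows), genes)

    w <- cfg$label_weights
    comp_mat <- do.call(rbind, patient_comp)
    logits <- as.vector(comp_mat %*% w) - sum(w) / T
    labels <- stats::rbinom(length(patient_ids), 1L, stats::plogis(logits))
    label_tab <- data.frame(patient_id = patient_ids,
                            cohort = patient_cohort, label = labels)

    truth <- structure(list(tile_types = tile_types,
                            gene_links = gene_links,
                            label_logit_weights = w,
                            true_label = stats::setNames(labels, patient_ids),
                            composition = do.call(rbind, comp_rows),
                            prototypes = protos),
                       class = "ground_truth")
    list(bags = bags,
         expression = expression_matrix(expr),
         truth = truth,
         labels = label_tab,
         manifest = do.call(rbind, unname(manifest)))
  })
}
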