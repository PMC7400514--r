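# Per-gene evaluation and statistical machinery: patient-grouped stratified
# folds, empirical null from untrained models, multiple-testing corrections,
# well-predicted gene calls, and the pathway-vs-random-lists test.

#' Patient-grouped, cohort-stratified fold assignment
#'
#' Every sample of a patient lands in the same fold and each cohort's
#' patients are spread as evenly as possible across folds (per-cohort fold
#' counts differ by at most one).
#'
#' @param manifest data frame with `patient_id` and `cohort` columns (one
#'   row per slide is fine; patients are deduplicated).
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return data frame `patient_id`, `cohort`, `fold` (0-based fold ids).
#' @export
make_folds <- function(manifest, n_folds = 5L, seed = NULL) {
  stopifnot(is_count(n_folds, min = 2L))
  pats <- unique(manifest[, c("patient_id", "cohort")])
  counts <- table(pats$cohort)
  small <- names(counts)[counts < n_folds]
  if (length(small)) {
    stop_data("cohorts smaller than n_folds: ", paste(small, collapse = ", "))
  }
  with_seed(seed, {
    out <- lapply(split(pats, pats$cohort), function(df) {
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      df$fold <- (seq_len(nrow(df)) - 1L) %% n_folds
      df
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Per-gene, per-cohort cross-validated Pearson correlation
#'
#' Pearson R between held-out predictions and true log expression, computed
#' within each (gene, cohort, fold) cell and averaged over folds. Cohorts are
#' always evaluated separately. Folds where either side has zero variance are
#' skipped with a warning.
#'
#' @param predictions slides x genes matrix of out-of-fold predictions
#'   (`NA` allowed for genes a fold did not retain).
#' @param truth slides x genes matrix of true log expression (same dimnames).
#' @param sample_info data frame `sample_id`, `cohort`, `fold` aligned with
#'   prediction rows.
#' @return data frame `gene`, `cohort`, `R` (fold-averaged), `n_folds_used`.
#' @export
per_gene_correlation <- function(predictions, truth, sample_info) {
  stopifnot(nrow(predictions) == nrow(sample_info))
  truth <- truth[rownames(predictions), colnames(predictions), drop = FALSE]
  res <- list()
  skipped <- 0L
  for (co in unique(sample_info$cohort)) {
    acc <- matrix(NA_real_, 0L, ncol(predictions))
    for (f in sort(unique(sample_info$fold))) {
      rows <- which(sample_info$cohort == co & sample_info$fold == f)
      if (length(rows) < 2L) next
      r <- colwise_pearson(predictions[rows, , drop = FALSE],
                           truth[rows, , drop = FALSE])
      skipped <- skipped + sum(is.na(r) &
                                 !is.na(colSums(predictions[rows, , drop = FALSE])))
      acc <- rbind(acc, r)
    }
    res[[co]] <- data.frame(gene = colnames(predictions), cohort = co,
                            R = colMeans(acc, na.rm = TRUE),
                            n_folds_used = colSums(!is.na(acc)))
  }
  if (skipped > 0L) {
    warning(skipped, " (gene, fold) cells had zero variance and were skipped")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Empirical null from untrained models
#'
#' For each replicate, draws fresh random initial weights for the same
#' architecture and runs the identical inference and correlation path with no
#' training, pooling the resulting per-gene R values within each cohort (or
#' keeping them per gene). This is the null distribution of "correlations a
#' model of this shape achieves by chance".
#'
#' @param bags list of bags (the representation the trained model used).
#' @param expr raw [expression_matrix()].
#' @param folds fold assignment from [make_folds()].
#' @param spec a [model_spec()] matching the trained architecture.
#' @param agg an [aggregation_spec()].
#' @param n_replicates untrained replicates (default 100).
#' @param mode `"pooled"` (per-cohort pool across genes, default) or
#'   `"per_gene"`.
#' @param seed RNG seed.
#' @return object of class `null_distribution`: list of numeric vectors per
#'   cohort (pooled) or matrices genes x replicates (per_gene), plus
#'   `n_replicates` and `mode`.
#' @export
build_null <- function(bags, expr, folds, spec,
                       agg = aggregation_spec(mode = "supertile"),
                       n_replicates = 100L, mode = c("pooled", "per_gene"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "model_spec"))
  ids <- vapply(bags, function(b) b$slide_id, character(1))
  names(bags) <- ids
  patients <- vapply(bags, function(b) b$patient_id, character(1))
  cohorts <- vapply(bags, function(b) b$cohort, character(1))
  fold_of <- stats::setNames(folds$fold, folds$patient_id)[patients]
  Y <- log_values(expr)[ids, , drop = FALSE]
  sizes <- c(spec$input_dim, spec$hidden, spec$n_genes)
  acts <- c(rep("relu", length(spec$hidden)), "linear")
  info <- data.frame(sample_id = ids, cohort = cohorts,
                     fold = as.integer(fold_of))
  vals <- list()
  for (rep_i in seq_len(n_replicates)) {
    net <- mlp_init(sizes, acts, seed = child_seed(seed, rep_i))
    pred <- matrix(NA_real_, length(ids), spec$n_genes,
                   dimnames = list(ids, colnames(Y)))
    for (sid in ids) {
      sc <- mlp_forward(net, bags[[sid]]$features)$out
      pred[sid, ] <- aggregate_inference(sc, agg)
    }
    tab <- suppressWarnings(per_gene_correlation(pred, Y, info))
    vals[[rep_i]] <- tab
  }
  all_tab <- do.call(rbind, vals)
  out <- if (mode == "pooled") {
    lapply(split(all_tab$R, all_tab$cohort), function(v) v[!is.na(v)])
  } else {
    lapply(split(all_tab, all_tab$cohort), function(df) {
      m <- matrix(df$R, ncol = n_replicates)
      rownames(m) <- df$gene[seq_len(nrow(m))]
      m
    })
  }
  structure(list(values = out, n_replicates = n_replicates, mode = mode),
            class = "null_distribution")
}

#' One-sided empirical p-value with the add-one convention
#'
#' `p = (1 + #(null >= observed)) / (1 + N)`; larger observed correlations
#' are more significant, and p can never be exactly zero.
#'
#' @param observed numeric vector of observed statistics.
#' @param null_values numeric vector of null draws.
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  if (!length(null_values)) stop_data("empty null distribution")
  n <- length(null_values)
  vapply(observed, function(o) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(null_values >= o)) / (1 + n)
  }, numeric(1))
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts p-values ascending, applies `1 - (1 - p_(i))^(m - i + 1)`, enforces
#' the running maximum, and restores input order. Controls the family-wise
#' error rate; applied separately per cohort by the callers.
#'
#' @param pvals numeric vector in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same order.
#' @export
holm_sidak <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  if (m == 0L) return(pvals)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  res <- rep(NA_real_, length(pvals))
  res[ok] <- out
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR adjustment `m * p_(i) / i` with a running minimum from the
#' largest rank down.
#'
#' @param pvals numeric vector in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same order.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  if (m == 0L) return(pvals)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, m / (m:1) * p[o])
  adj <- cummin(adj)
  out <- numeric(m)
  out[o] <- adj
  res <- rep(NA_real_, length(pvals))
  res[ok] <- out
  res
}

#' Gene significance table
#'
#' Combines fold-averaged correlations with the untrained-model null into
#' per-gene empirical p-values, Holm-Sidak and Benjamini-Hochberg corrected
#' p-values (each within cohort), the well-predicted call (corrected p <
#' alpha under the chosen method) and the cohort's minimum significant R.
#'
#' @param cor_tab output of [per_gene_correlation()].
#' @param null a `null_distribution` from [build_null()].
#' @param alpha significance level (default 0.05).
#' @param method correction driving the `well_predicted` call:
#'   `"holm_sidak"` (default) or `"benjamini_hochberg"`.
#' @return data frame `gene`, `cohort`, `R`, `p_empirical`, `p_holm_sidak`,
#'   `p_benjamini_hochberg`, `well_predicted`, `R_sign`.
#' @export
gene_significance <- function(cor_tab, null, alpha = 0.05,
                              method = c("holm_sidak",
                                         "benjamini_hochberg")) {
  method <- match.arg(method)
  stopifnot(inherits(null, "null_distribution"))
  out <- lapply(split(cor_tab, cor_tab$cohort), function(df) {
    co <- df$cohort[1L]
    nv <- null$values[[co]]
    if (is.null(nv)) stop_data("no null distribution for cohort ", co)
    if (null$mode == "pooled") {
      df$p_empirical <- empirical_pvalue(df$R, nv)
    } else {
      df$p_empirical <- vapply(seq_len(nrow(df)), function(i) {
        empirical_pvalue(df$R[i], nv[df$gene[i], ])
      }, numeric(1))
    }
    df$p_holm_sidak <- holm_sidak(df$p_empirical)
    df$p_benjamini_hochberg <- benjamini_hochberg(df$p_empirical)
    padj <- if (method == "holm_sidak") df$p_holm_sidak
            else df$p_benjamini_hochberg
    df$well_predicted <- !is.na(padj) & padj < alpha
    df$R_sign <- if (any(df$well_predicted)) min(df$R[df$well_predicted])
                 else NA_real_
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pathway versus random gene lists
#'
#' Compares the mean correlation over a pathway's genes (`R_p`) and its
#' fraction of well-predicted genes (`f_p`) against `n_random` random gene
#' lists of the same length drawn without replacement from the evaluated gene
#' universe. One-sided add-one empirical p-values; significance is called at
#' p < 0.05.
#'
#' @param signif one cohort's rows of a [gene_significance()] table.
#' @param pathway_genes character vector of gene ids.
#' @param n_random number of random lists (default 10000).
#' @param seed RNG seed.
#' @return object of class `pathway_result`: `R_p`, `R_0` (mean of random
#'   means), `p_R`, `f_p`, `f_0_mean`, `p_f`, `n_used`, `dropped`,
#'   `n_random`, and the raw random draws `R_r`, `f_r`.
#' @export
pathway_test <- function(signif, pathway_genes, n_random = 10000L,
                         seed = NULL) {
  if (length(unique(signif$cohort)) != 1L) {
    stop_data("pathway_test expects a single cohort's significance table")
  }
  universe <- signif$gene
  present <- intersect(pathway_genes, universe)
  dropped <- setdiff(pathway_genes, universe)
  if (length(dropped)) {
    warning("pathway genes missing from universe, dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  if (!length(present)) stop_data("no pathway gene present in the universe")
  R <- stats::setNames(signif$R, signif$gene)
  wp <- stats::setNames(signif$well_predicted, signif$gene)
  R_p <- mean(R[present], na.rm = TRUE)
  f_p <- mean(wp[present], na.rm = TRUE)
  len <- length(present)
  with_seed(seed, {
    R_r <- numeric(n_random)
    f_r <- numeric(n_random)
    n_u <- length(universe)
    for (i in seq_len(n_random)) {
      pick <- sample.int(n_u, len)
      R_r[i] <- mean(R[pick], na.rm = TRUE)
      f_r[i] <- mean(wp[pick], na.rm = TRUE)
    }
    structure(list(pathway_size = len, n_used = len,
                   dropped = dropped, n_random = as.integer(n_random),
                   R_p = R_p, R_0 = mean(R_r),
                   p_R = (1 + sum(R_r >= R_p)) / (1 + n_random),
                   f_p = f_p, f_0_mean = mean(f_r),
                   p_f = (1 + sum(f_r >= f_p)) / (1 + n_random),
                   R_r = R_r, f_r = f_r,
                   significant_R = (1 + sum(R_r >= R_p)) /
                                   (1 + n_random) < 0.05),
              class = "pathway_result")
  })
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf(paste0("<pathway_result> %d genes: R_p=%.3f vs R_0=%.3f ",
                     "(p=%.4g); f_p=%.3f vs f_0=%.3f (p=%.4g)\n"),
              x$pathway_size, x$R_p, x$R_0, x$p_R, x$f_p, x$f_0_mean, x$p_f))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: tab-separated `name`, `description`, genes...
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_data("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  out
}
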