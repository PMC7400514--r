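# Virtual spatialization: per-tile score maps and their validation against
# tile-level ground truth (tile correlation, threshold AUCs, top-tile
# summaries, per-slide region-overlap AUC), plus heatmap rendering.

#' Rank-based (Mann-Whitney) AUC with midrank tie handling
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @return AUC in `[0, 1]`; `NA` when only one class is present (degenerate,
#'   deliberately not reported as 0.5).
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-tile score map over a gene set
#'
#' Skips the slide-level aggregation and interprets each tile's score as the
#' predicted expression at that tile, averaged over the requested genes
#' (e.g. the genes encoding a marker of interest). Scores stay on the log
#' scale the model was trained on.
#'
#' @param bundle a `prediction_bundle` from [predict_slide()].
#' @param genes character vector of gene ids present in the bundle.
#' @return object of class `tile_score_map`: `slide_id`, `genes`, `coords`,
#'   `score` (one per tile).
#' @export
score_map <- function(bundle, genes) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  if (!length(genes)) stop_data("empty gene set for score map")
  missing <- setdiff(genes, colnames(bundle$tile_scores))
  if (length(missing)) {
    stop_data("genes absent from bundle: ", paste(missing, collapse = ", "))
  }
  structure(list(slide_id = bundle$slide_id, genes = genes,
                 coords = bundle$coords,
                 score = rowMeans(bundle$tile_scores[, genes,
                                                     drop = FALSE])),
            class = "tile_score_map")
}

#' Correlation between tile scores and tile-level counts
#'
#' Pearson R over tiles with a two-tailed p-value from
#' `t = R * sqrt((n - 2) / (1 - R^2))` on n - 2 degrees of freedom.
#'
#' @param map a `tile_score_map`.
#' @param counts numeric vector aligned 1:1 with the map's tiles.
#' @return list `R`, `p`, `n`.
#' @export
tile_count_correlation <- function(map, counts) {
  s <- map$score
  stopifnot(length(s) == length(counts))
  n <- length(s)
  if (n < 3L) stop_data("need at least 3 tiles for a correlation test")
  if (stats::sd(s) == 0 || stats::sd(counts) == 0) {
    stop_data("zero variance in scores or counts")
  }
  R <- stats::cor(s, counts)
  tt <- R * sqrt((n - 2) / max(1 - R^2, .Machine$double.eps))
  list(R = R, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' AUC for exceeding count thresholds
#'
#' Binarizes the ground-truth counts at percentile-derived thresholds
#' (defaults: 75th, 90th, 95th, 99th) and reports the rank-based AUC of the
#' score map against each binary label. A degenerate labeling (single class)
#' yields `NA`, not 0.5.
#'
#' @param map a `tile_score_map`.
#' @param counts tile-level counts aligned with the map.
#' @param percentiles percentile thresholds in (0, 100).
#' @return data frame `percentile`, `threshold`, `n_positive`, `auc`.
#' @export
tile_threshold_auc <- function(map, counts,
                               percentiles = c(75, 90, 95, 99)) {
  stopifnot(length(map$score) == length(counts))
  thr <- stats::quantile(counts, percentiles / 100, names = FALSE, type = 7)
  data.frame(percentile = percentiles, threshold = thr,
             n_positive = vapply(thr, function(t) sum(counts > t),
                                 integer(1)),
             auc = vapply(thr, function(t) rank_auc(map$score, counts > t),
                          numeric(1)))
}

#' Top-scoring tiles versus the slide at large
#'
#' Returns the k highest-scoring tiles (ties broken by tile index) with the
#' median ground truth among them next to the global median — the "are the
#' hot tiles actually enriched" summary.
#'
#' @param map a `tile_score_map`.
#' @param truth tile-level ground truth values aligned with the map.
#' @param k number of top tiles (default 100).
#' @return list `top_idx`, `median_top`, `median_all`, `k`.
#' @export
top_tiles_report <- function(map, truth, k = 100L) {
  stopifnot(length(map$score) == length(truth), is_count(k),
            k <= length(truth))
  top <- order(map$score, decreasing = TRUE, method = "radix")[seq_len(k)]
  list(top_idx = top, k = as.integer(k),
       median_top = stats::median(truth[top]),
       median_all = stats::median(truth))
}

#' Tumor/healthy region-overlap AUC per slide
#'
#' For every slide, the AUC for distinguishing tiles in the flagged region
#' from the rest, plus cohort mean/median and a slide-level aggregated score
#' usable for downstream slide classification. Slides with a single class
#' are excluded with a warning.
#'
#' @param maps named list of `tile_score_map`s (one per slide).
#' @param flags named list of logical vectors (`TRUE` = tumor), aligned with
#'   each map's tiles.
#' @return list `per_slide` (data frame slide_id, auc, n_tumor, n_healthy,
#'   slide_score), `mean_auc`, `median_auc`, `excluded`.
#' @export
region_overlap_auc <- function(maps, flags) {
  ids <- vapply(maps, function(m) m$slide_id, character(1))
  names(maps) <- ids
  rows <- list(); excluded <- character()
  for (sid in ids) {
    fl <- as.logical(flags[[sid]])
    m <- maps[[sid]]
    stopifnot(length(fl) == length(m$score))
    if (length(unique(fl)) < 2L) {
      excluded <- c(excluded, sid)
      next
    }
    rows[[sid]] <- data.frame(slide_id = sid,
                              auc = rank_auc(m$score, fl),
                              n_tumor = sum(fl), n_healthy = sum(!fl),
                              slide_score = mean(m$score))
  }
  if (length(excluded)) {
    warning("slides with a single region class excluded: ",
            paste(excluded, collapse = ", "))
  }
  per_slide <- if (length(rows)) do.call(rbind, rows)
               else data.frame(slide_id = character(), auc = numeric(),
                               n_tumor = integer(), n_healthy = integer(),
                               slide_score = numeric())
  rownames(per_slide) <- NULL
  list(per_slide = per_slide,
       mean_auc = mean(per_slide$auc),
       median_auc = stats::median(per_slide$auc),
       excluded = excluded)
}

#' Raster matrix for a score map
#'
#' Lays tile scores onto their grid with per-slide min-max normalization
#' (rendering only; raw scores are preserved in the TSV output). Cells with
#' no tile are `NA` (transparent background).
#'
#' @param map a `tile_score_map`.
#' @return numeric matrix (rows = y, cols = x) of normalized scores.
#' @export
heatmap_raster <- function(map) {
  xy <- map$coords
  if (anyDuplicated(paste(xy[, 1L], xy[, 2L]))) {
    stop_data("overlapping tile coordinates in score map")
  }
  nx <- max(xy[, 1L]) + 1L
  ny <- max(xy[, 2L]) + 1L
  rng <- range(map$score)
  norm <- if (diff(rng) == 0) rep(1, length(map$score))
          else (map$score - rng[1L]) / diff(rng)
  ras <- matrix(NA_real_, ny, nx)
  ras[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L)] <- norm
  ras
}

#' Render a score map to disk
#'
#' Writes a TSV (`x`, `y`, `score`; raw values) and a PNG raster in which
#' each tile is one pixel block, linear color scale normalized per slide,
#' background transparent.
#'
#' @param map a `tile_score_map`.
#' @param path output path without extension; `.tsv` and `.png` are
#'   appended.
#' @param block pixel block size per tile.
#' @return invisibly, the paths written.
#' @export
render_heatmap <- function(map, path, block = 8L) {
  ras <- heatmap_raster(map)
  tsv <- paste0(path, ".tsv")
  png_path <- paste0(path, ".png")
  data.table::fwrite(data.frame(x = map$coords[, 1L], y = map$coords[, 2L],
                                score = map$score),
                     tsv, sep = "\t")
  pal <- grDevices::hcl.colors(256, "viridis")
  col_idx <- 1L + round(ras * 255)
  rgba <- array(0, c(nrow(ras), ncol(ras), 4))
  rgb_vals <- grDevices::col2rgb(pal) / 255
  for (ch in 1:3) {
    m <- matrix(0, nrow(ras), ncol(ras))
    m[!is.na(ras)] <- rgb_vals[ch, col_idx[!is.na(ras)]]
    rgba[, , ch] <- m
  }
  rgba[, , 4] <- !is.na(ras)  # alpha: transparent background
  grDevices::png(png_path, width = ncol(ras) * block,
                 height = nrow(ras) * block)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgba), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(c(tsv = tsv, png = png_path))
}

#' Read a tile score map back from its TSV
#'
#' Inverse of the TSV side of [render_heatmap()].
#'
#' @param path TSV path.
#' @param slide_id identifier to attach.
#' @param genes gene set annotation to attach.
#' @return a `tile_score_map`.
#' @export
read_score_map <- function(path, slide_id = NA_character_,
                           genes = character()) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  structure(list(slide_id = slide_id, genes = genes,
                 coords = as.matrix(df[, c("x", "y")]),
                 score = df$score),
            class = "tile_score_map")
}
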