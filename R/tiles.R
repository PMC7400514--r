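# Tile bags and their preprocessing: tissue selection, subsampling,
# supertile construction by spatial k-means with feature averaging.
#
# Coordinates are 0-based tile-grid indices with a top-left origin (column
# x, row y); a tile is a fixed 112 x 112 um square so grid indices are the
# natural unit.

#' Construct a tile bag
#'
#' One slide represented as a bag of per-tile feature vectors plus the tile
#' grid coordinates, with patient and cohort identity attached.
#'
#' @param slide_id,patient_id,cohort identifiers.
#' @param coords integer-like n_tiles x 2 matrix of (x, y) grid positions,
#'   unique within the slide.
#' @param features numeric n_tiles x d matrix of tile features (d = 2048 for
#'   a standard ImageNet ResNet50 extractor; configurable).
#' @return an object of class `tile_bag`.
#' @export
tile_bag <- function(slide_id, patient_id, cohort, coords, features) {
  coords <- as.matrix(coords)
  features <- as.matrix(features)
  if (nrow(coords) != nrow(features)) {
    stop_data("coords and features disagree on tile count")
  }
  if (nrow(features) < 1L) stop_data("a tile bag needs at least one tile")
  if (ncol(coords) != 2L) stop_data("coords must be n_tiles x 2")
  if (anyDuplicated(paste(coords[, 1L], coords[, 2L]))) {
    stop_data("duplicate tile coordinates in slide ", slide_id)
  }
  if (any(!is.finite(features))) stop_data("non-finite tile features")
  structure(list(slide_id = as.character(slide_id),
                 patient_id = as.character(patient_id),
                 cohort = as.character(cohort),
                 coords = coords, features = features),
            class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> %s (patient %s, cohort %s): %d tiles x %d features\n",
              x$slide_id, x$patient_id, x$cohort,
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

n_tiles <- function(bag) nrow(bag$features)

#' Otsu threshold of an intensity sample
#'
#' Exhaustive search over 256 histogram bins for the threshold maximizing
#' between-class variance.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return the threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]
  mu_t <- mu[n_bins]
  w0 <- w[-n_bins]
  between <- (n * mu[-n_bins] - mu_t * w0)^2 / (w0 * (n - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

#' Select tissue tiles on a grayscale thumbnail
#'
#' Thresholds the tile-level mean intensity grid with Otsu's method and masks
#' out the background side. With a light background (hematoxylin-eosin on a
#' white field, the default) tissue is the darker class.
#'
#' @param thumbnail numeric matrix of tile mean intensities (grid layout).
#' @param background `"light"` (default) or `"dark"`: which side of the
#'   threshold is background.
#' @return logical matrix, `TRUE` where tissue is retained.
#' @export
select_tissue_tiles <- function(thumbnail, background = c("light", "dark")) {
  background <- match.arg(background)
  thumbnail <- as.matrix(thumbnail)
  if (length(unique(as.vector(thumbnail))) < 2L) {
    warning("constant thumbnail: keeping all tiles as foreground")
    return(matrix(TRUE, nrow(thumbnail), ncol(thumbnail)))
  }
  thr <- otsu_threshold(as.vector(thumbnail))
  if (background == "light") thumbnail < thr else thumbnail >= thr
}

#' Subsample a tile bag to a maximum size
#'
#' Uniform sampling without replacement, keeping coordinates and features
#' aligned; a bag already within the cap is returned unchanged. The paper's
#' pipeline caps slides at 8000 tiles.
#'
#' @param bag a `tile_bag`.
#' @param max_tiles maximum number of tiles to keep.
#' @param seed RNG seed.
#' @return a `tile_bag` with at most `max_tiles` tiles.
#' @export
subsample_tiles <- function(bag, max_tiles = 8000L, seed = NULL) {
  stopifnot(inherits(bag, "tile_bag"), is_count(max_tiles))
  n <- n_tiles(bag)
  if (n <= max_tiles) return(bag)
  keep <- with_seed(seed, sort(sample.int(n, max_tiles)))
  tile_bag(bag$slide_id, bag$patient_id, bag$cohort,
           bag$coords[keep, , drop = FALSE],
           bag$features[keep, , drop = FALSE])
}

#' Cluster tiles into supertiles
#'
#' k-means on tile coordinates only (never on features); each supertile's
#' feature vector is the unweighted mean of its member tiles' features. This
#' reduces a slide from `n_tiles x d` to `K x d` with
#' `K = min(n_clusters, n_tiles)`. k-means runs with a 300-iteration cap and
#' seeded center initialization so results are reproducible; an empty-cluster
#' failure is repaired by re-seeding the centers.
#'
#' @param bag a `tile_bag`.
#' @param n_clusters requested number of supertiles (paper default: 100).
#' @param seed RNG seed for center initialization.
#' @return an object of class `supertile_bag` with elements `features`
#'   (K x d means), `sizes`, `cluster_of_tile`, `coords` (cluster centroid
#'   positions) and the bag's identifiers.
#' @export
make_supertiles <- function(bag, n_clusters = 100L, seed = NULL) {
  stopifnot(inherits(bag, "tile_bag"), is_count(n_clusters))
  n <- n_tiles(bag)
  coords <- bag$coords
  uniq <- !duplicated(paste(coords[, 1L], coords[, 2L]))
  K <- min(n_clusters, n, sum(uniq))
  cl <- with_seed(seed, {
    if (K == n) {
      seq_len(n)
    } else {
      fit <- NULL
      for (attempt in 1:10) {
        centers <- coords[sample(which(uniq), K), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(coords, centers = centers,
                                         iter.max = 300L)),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) stop_data("k-means failed to find ", K,
                                  " nonempty clusters")
      fit$cluster
    }
  })
  feats <- matrix(0, K, ncol(bag$features))
  cent <- matrix(0, K, 2L)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    rows <- which(cl == k)
    sizes[k] <- length(rows)
    feats[k, ] <- colMeans(bag$features[rows, , drop = FALSE])
    cent[k, ] <- colMeans(bag$coords[rows, , drop = FALSE])
  }
  structure(list(slide_id = bag$slide_id, patient_id = bag$patient_id,
                 cohort = bag$cohort, features = feats, sizes = sizes,
                 cluster_of_tile = cl, coords = cent),
            class = c("supertile_bag", "tile_bag"))
}

#' Mean-pool a bag to a single feature vector
#'
#' Column-wise mean over tiles; identical to [make_supertiles()] with one
#' cluster. This is the "one supertile" input used for transcriptomic
#' representation learning.
#'
#' @param bag a `tile_bag`.
#' @return numeric vector of length d.
#' @export
mean_pool_bag <- function(bag) {
  stopifnot(inherits(bag, "tile_bag"))
  colMeans(bag$features)
}
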