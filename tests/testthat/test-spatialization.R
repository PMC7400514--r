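# Score maps, AUC metrics against the exhaustive pair oracle, top-tile
# summaries, region overlap, heatmap rendering.

make_bundle <- function(scores, coords = NULL, slide_id = "S1") {
  n <- nrow(scores)
  if (is.null(coords)) coords <- cbind(seq_len(n) - 1L, 0L)
  structure(list(slide_id = slide_id, tile_scores = scores,
                 slide_prediction = colMeans(scores), coords = coords),
            class = "prediction_bundle")
}

test_that("score_map averages the requested gene columns", {
  sc <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(-1, -2, -3))
  b <- make_bundle(sc)
  expect_equal(score_map(b, "A")$score, sc[, "A"])
  expect_equal(score_map(b, c("A", "B"))$score, sc[, "A"])
  expect_equal(score_map(b, c("A", "C"))$score, c(0, 0, 0))
  expect_error(score_map(b, character()), "empty")
  expect_error(score_map(b, "Z"), "absent")
})

test_that("rank_auc matches exhaustive pair counting for all small cases", {
  set.seed(17)
  for (n in 3:12) {
    scores <- sample(c(rnorm(n - 2), rnorm(1), rnorm(1)))  # with possible ties below
    scores[2] <- scores[1]  # force at least one tie
    for (rep in 1:8) {
      labels <- runif(n) < 0.5
      expect_identical(is.na(rank_auc(scores, labels)),
                       length(unique(labels)) == 1L)
      if (length(unique(labels)) == 2L) {
        expect_equal(rank_auc(scores, labels), oracle_auc(scores, labels),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(rank_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(rank_auc(1:10, 1:10 > 5), 1)
})

test_that("tile_count_correlation matches cor.test", {
  map <- structure(list(slide_id = "S", genes = "g",
                        coords = cbind(0:4, 0L),
                        score = c(0.3, 1.2, 0.8, 2.0, 1.4)),
                   class = "tile_score_map")
  counts <- c(1, 4, 2, 9, 5)
  out <- tile_count_correlation(map, counts)
  ref <- stats::cor.test(map$score, counts)
  expect_equal(out$R, unname(ref$estimate))
  expect_equal(out$p, ref$p.value, tolerance = 1e-12)
  map$score <- counts
  expect_equal(tile_count_correlation(map, counts)$R, 1)
  map$score <- rep(1, 5)
  expect_error(tile_count_correlation(map, counts), "zero variance")
})

test_that("threshold AUCs binarize at percentiles and respect degeneracy", {
  set.seed(3)
  counts <- c(rep(0, 80), rpois(20, 8))
  map <- structure(list(slide_id = "S", genes = "g",
                        coords = cbind(0:99, 0L), score = counts),
                   class = "tile_score_map")
  out <- tile_threshold_auc(map, counts)
  expect_equal(out$percentile, c(75, 90, 95, 99))
  expect_true(all(out$auc == 1, na.rm = TRUE))  # perfectly ordered map
  const <- map; const$score <- rep(2, 100)
  expect_true(all(tile_threshold_auc(const, counts)$auc == 0.5,
                  na.rm = TRUE))
  # all-one-class labeling reported as NA
  same <- map; same$score <- rnorm(100)
  expect_true(is.na(tile_threshold_auc(same, rep(5, 100))$auc[1]))
})

test_that("top_tiles_report returns order statistics honestly", {
  map <- structure(list(slide_id = "S", genes = "g",
                        coords = cbind(0:9, 0L), score = 10:1),
                   class = "tile_score_map")
  truth <- c(50, 40, 30, 20, 10, 1, 1, 1, 1, 1)
  rep3 <- top_tiles_report(map, truth, 3L)
  expect_equal(rep3$median_top, 40)
  expect_equal(rep3$median_all, stats::median(truth))
  expect_gte(rep3$median_top, rep3$median_all)
  all10 <- top_tiles_report(map, truth, 10L)
  expect_equal(all10$median_top, all10$median_all)
})

test_that("region_overlap_auc scores slides and excludes degenerates", {
  m1 <- structure(list(slide_id = "A", genes = "g", coords = cbind(0:5, 0L),
                       score = c(5, 5, 5, 1, 1, 1)),
                  class = "tile_score_map")
  m2 <- structure(list(slide_id = "B", genes = "g", coords = cbind(0:5, 0L),
                       score = c(0.9, 0.8, 0.1, 0.2, 0.7, 0.3)),
                  class = "tile_score_map")
  m3 <- structure(list(slide_id = "C", genes = "g", coords = cbind(0:2, 0L),
                       score = c(1, 2, 3)), class = "tile_score_map")
  flags <- list(A = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                B = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                C = c(TRUE, TRUE, TRUE))
  expect_warning(out <- region_overlap_auc(list(m1, m2, m3), flags),
                 "excluded")
  expect_equal(out$per_slide$auc[out$per_slide$slide_id == "A"], 1)
  expect_equal(out$per_slide$auc[out$per_slide$slide_id == "B"],
               oracle_auc(m2$score, flags$B))
  expect_equal(out$excluded, "C")
  # permutation null: shuffled labels give AUC near 0.5 on average
  set.seed(9)
  shuffled <- replicate(100, {
    fl <- list(B = sample(flags$B))
    suppressWarnings(region_overlap_auc(list(m2), fl)$per_slide$auc)
  })
  expect_lt(abs(mean(shuffled) - 0.5), 0.1)
})

test_that("heatmap raster is pixel-exact and the TSV round-trips", {
  # checkerboard scores on a 4x4 grid
  cells <- 0:15
  coords <- cbind(cells %% 4L, cells %/% 4L)
  score <- as.numeric((coords[, 1] + coords[, 2]) %% 2L)
  map <- structure(list(slide_id = "S", genes = "g", coords = coords,
                        score = score), class = "tile_score_map")
  ras <- heatmap_raster(map)
  expect_equal(dim(ras), c(4L, 4L))
  expect_equal(ras, outer(0:3, 0:3, function(y, x) (x + y) %% 2))

  tmp <- file.path(withr::local_tempdir(), "hm")
  paths <- render_heatmap(map, tmp)
  expect_true(file.exists(paths["tsv"]))
  expect_true(file.exists(paths["png"]))
  back <- read_score_map(paths["tsv"], slide_id = "S", genes = "g")
  expect_equal(back$score, map$score)
  expect_equal(back$coords, unname(map$coords), ignore_attr = TRUE)

  # single tile renders with maximal color and overlaps are rejected
  one <- structure(list(slide_id = "S", genes = "g",
                        coords = cbind(0L, 0L), score = 3),
                   class = "tile_score_map")
  expect_equal(heatmap_raster(one), matrix(1, 1, 1))
  dup <- map; dup$coords[2, ] <- dup$coords[1, ]
  expect_error(heatmap_raster(dup), "overlapping")
})
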