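# Shared fixtures, built in code at test time.

# Tiny cohort for fast structural tests.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohorts(synthetic_config(
        patients_per_cohort = 6L, slides_per_patient = 1L,
        tiles_per_slide = 36L, feature_dim = 8L, n_tile_types = 3L,
        n_signal_genes = 2L, n_noise_genes = 4L, cv_folds = 2L,
        seed = 42L))
    }
    cache
  }
})

# Random bag with reproducible contents.
random_bag <- function(n = 12L, d = 5L, seed = 1L, slide_id = "S1",
                       patient_id = "P1", cohort = "C1") {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  cells <- seq_len(n) - 1L
  tile_bag(slide_id, patient_id, cohort,
           coords = cbind(cells %% side, cells %/% side),
           features = matrix(rnorm(n * d), n, d))
}

# Exhaustive concordant-pair AUC oracle (midrank tie convention).
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive sign-flip Wilcoxon signed-rank oracle (two-tailed, zeros
# dropped, midranks for ties).
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(Ws <= W)
  p_ge <- mean(Ws >= W)
  min(1, 2 * min(p_le, p_ge))
}
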