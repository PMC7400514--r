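# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream. A `NULL` seed means "use the current
#' stream".
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483629)
}

stop_config <- function(...) {
  stop(structure(class = c("bagexpr_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("bagexpr_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

# Column-wise Pearson correlation between two matrices of equal shape.
# Returns a vector of length ncol; columns with zero variance give NA.
colwise_pearson <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  n <- nrow(A)
  if (n < 2L) return(rep(NA_real_, ncol(A)))
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(1, pmax(-1, r))
}
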