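#' @importFrom stats cor cor.test dist kmeans na.omit pnorm rbeta rbinom rnorm
#'   runif sd setNames var
#' @importFrom utils read.table
NULL

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed; stays below 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483587L
}

# Solve (A + ridge I) x = b for symmetric positive semidefinite A.
ridge_solve <- function(A, b, ridge = 1e-6) {
  solve(A + diag(ridge, nrow(A)), b)
}

# Canonical id of an unordered cross between two inbred parents.
cross_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' equal to 1 for identical partitions (up to label permutation) and close
#' to 0 for independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single numeric value in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
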