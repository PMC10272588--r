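# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and textbook formulas only.

# Rogers distance by the per-locus definition with within-line allele
# frequencies dosage/2, looped over every pair and locus.
brute_rogers <- function(dos) {
  n <- nrow(dos)
  D <- matrix(0, n, n, dimnames = list(rownames(dos), rownames(dos)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(ncol(dos))) {
      pi <- dos[i, l] / 2; pj <- dos[j, l] / 2
      acc <- acc + sqrt(0.5 * ((pi - pj)^2 + ((1 - pi) - (1 - pj))^2))
    }
    D[i, j] <- acc / ncol(dos)
  }
  D
}

# Kendall tau-b by explicit pair counting.
brute_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# REML log-likelihood for V = s2 * (lambda * G + I), profiled over s2.
profiled_logl <- function(lambda, y, X, G) {
  n <- length(y); p <- ncol(X)
  V0 <- lambda * G + diag(n)
  V0i <- solve(V0)
  XtVX <- t(X) %*% V0i %*% X
  P0 <- V0i - V0i %*% X %*% solve(XtVX) %*% t(X) %*% V0i
  s2 <- drop(t(y) %*% P0 %*% y) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(s2) + determinant(V0)$modulus +
                       determinant(XtVX)$modulus + (n - p)))
}

# Dense grid search over the variance ratio for a single-kernel model;
# returns the implied (sigma2_g, sigma2_e) at the grid optimum.
grid_reml_1k <- function(y, G, X = NULL,
                         grid = 10^seq(-4, 4, by = 0.002)) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  ll <- vapply(grid, function(l) profiled_logl(l, y, X, G), 0)
  lam <- grid[which.max(ll)]
  n <- length(y); p <- ncol(X)
  V0 <- lam * G + diag(n)
  V0i <- solve(V0)
  P0 <- V0i - V0i %*% X %*% solve(t(X) %*% V0i %*% X) %*% t(X) %*% V0i
  s2 <- drop(t(y) %*% P0 %*% y) / (n - p)
  list(sigma2_g = lam * s2, sigma2_e = s2, logl = max(ll), lambda = lam)
}

# Two-kernel grid search by iterative zoom over the two variance ratios.
grid_reml_2k <- function(y, G1, G2, X = NULL, rounds = 4) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  n <- length(y); p <- ncol(X)
  eval_ll <- function(l1, l2) {
    V0 <- l1 * G1 + l2 * G2 + diag(n)
    V0i <- solve(V0)
    XtVX <- t(X) %*% V0i %*% X
    P0 <- V0i - V0i %*% X %*% solve(XtVX) %*% t(X) %*% V0i
    s2 <- drop(t(y) %*% P0 %*% y) / (n - p)
    list(ll = as.numeric(-0.5 * ((n - p) * log(s2) +
                                   determinant(V0)$modulus +
                                   determinant(XtVX)$modulus + (n - p))),
         s2 = s2)
  }
  lo1 <- lo2 <- -3; hi1 <- hi2 <- 3
  best <- NULL
  for (r in seq_len(rounds)) {
    g1 <- 10^seq(lo1, hi1, length.out = 25)
    g2 <- 10^seq(lo2, hi2, length.out = 25)
    best <- list(ll = -Inf)
    for (a in g1) for (b in g2) {
      e <- eval_ll(a, b)
      if (e$ll > best$ll) best <- list(ll = e$ll, l1 = a, l2 = b, s2 = e$s2)
    }
    w1 <- diff(log10(range(g1)))[1] / 24; w2 <- diff(log10(range(g2)))[1] / 24
    lo1 <- log10(best$l1) - 2 * w1; hi1 <- log10(best$l1) + 2 * w1
    lo2 <- log10(best$l2) - 2 * w2; hi2 <- log10(best$l2) + 2 * w2
  }
  list(sigma2_1 = best$l1 * best$s2, sigma2_2 = best$l2 * best$s2,
       sigma2_e = best$s2, logl = best$ll)
}

# Direct mixed-model-equation solve at given variance components
# (single random term, kernel K, identity residual): returns beta and u.
mme_solve <- function(y, X, Z, K, s2_u, s2_e, ridge = 1e-10) {
  Kinv <- solve(K + diag(ridge, nrow(K)))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + (s2_e / s2_u) * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

# Small structured two-pool scenario reused across tests.
quick_sim <- function(seed, n_lines = 40, n_markers = 1000, n_pools = 2,
                      divergence = 0.3, cross_fraction = 0.6,
                      var_additive = 1, var_dominance = 0.5,
                      var_residual = 0.5, ...) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    n_pools = n_pools, divergence = divergence,
                    n_diallel_parents = n_lines,
                    cross_fraction = cross_fraction,
                    var_additive = var_additive,
                    var_dominance = var_dominance,
                    var_residual = var_residual, seed = seed, ...)
  sim <- simulate_parents(cfg)
  truth <- simulate_genetic_effects(sim$genotypes, cfg)
  list(cfg = cfg, G = sim$genotypes, pools = sim$truth$pool_labels,
       truth = truth)
}

# Toy genotype matrix from explicit dosage rows.
toy_gm <- function(..., chrom = NULL) {
  rows <- list(...)
  d <- do.call(rbind, rows)
  rownames(d) <- paste0("L", seq_len(nrow(d)))
  colnames(d) <- paste0("M", seq_len(ncol(d)))
  genotype_matrix(d, chrom = chrom)
}
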