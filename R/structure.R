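#' Rogers genetic distance between lines
#'
#' Computes the pairwise Rogers distance from allele dosages. Per locus the
#' distance between two individuals is
#' `sqrt(0.5 * sum_alleles (p_i - p_j)^2)` with within-individual allele
#' frequencies `dosage/2`; for a biallelic locus this reduces to
#' `|g_i - g_j| / 2`, and the distance is the average over loci, bounded in
#' `[0, 1]`.
#'
#' @param G a [genotype_matrix()] with no missing dosages (impute first).
#' @return A symmetric n x n matrix with zero diagonal and line ids as
#'   dimnames.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2, 2, 0, 2, 2, 0, 0), 2, byrow = TRUE,
#'                             dimnames = list(c("a", "b"), paste0("m", 1:4))))
#' rogers_distance(g)["a", "b"]  # per-locus |diff|/2 = (1,0,1,0) -> 0.5
#' @export
rogers_distance <- function(G) {
  d <- if (inherits(G, "GenotypeMatrix")) G$dosages else as.matrix(G)
  if (ncol(d) == 0) stop("no markers")
  if (anyNA(d)) stop("missing dosages; impute before computing distances")
  D <- as.matrix(dist(d, method = "manhattan")) / (2 * ncol(d))
  diag(D) <- 0
  D
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centred,
#' eigendecomposed, and the top-k eigenvectors scaled by the square roots
#' of their eigenvalues are returned as coordinates. Negative eigenvalues
#' (possible for non-Euclidean distances) are truncated to zero when
#' normalising explained-variance fractions.
#'
#' @param D symmetric distance matrix with ids as dimnames.
#' @param k number of coordinates to return.
#' @return List of class `pcoa_result` with `vectors` (n x k coordinates),
#'   `values` (all eigenvalues, non-increasing) and `explained`
#'   (fractions for the returned coordinates).
#' @export
pcoa <- function(D, k = 10) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stop("k cannot exceed the number of individuals")
  A <- -0.5 * D^2
  B <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eg$values
  pos <- pmax(vals, 0)
  kk <- min(k, sum(pos > 1e-12))
  vec <- eg$vectors[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(kk)]), kk)
  if (kk < k)  # pad degenerate dimensions with zeros
    vec <- cbind(vec, matrix(0, n, k - kk))
  rownames(vec) <- rownames(D)
  colnames(vec) <- paste0("PCo", seq_len(k))
  structure(list(vectors = vec, values = vals,
                 explained = pos[seq_len(k)] / sum(pos)),
            class = "pcoa_result")
}

#' K-means clustering with WSS-based choice of k
#'
#' Runs Lloyd-type k-means (100 random restarts by default) for every k in
#' `k_range`, records the total within-cluster sum of squares (WSS), and
#' picks k at the elbow of the WSS curve — the k with the largest second
#' difference of WSS — unless `k` is given explicitly.
#'
#' @param X numeric matrix of row-wise observations (e.g. the first
#'   principal coordinates, or rows of an SCA matrix).
#' @param k_range candidate cluster numbers for the elbow scan.
#' @param k optional fixed number of clusters, bypassing the elbow rule.
#' @param seed integer seed (restarts are stochastic).
#' @param nstart random restarts per k.
#' @return List of class `cluster_result`: `labels` (named), `k`, `wss`
#'   (named by k), `k_range`, `seed`.
#' @export
kmeans_partition <- function(X, k_range = 1:8, k = NULL, seed = 1,
                             nstart = 100) {
  X <- as.matrix(X)
  if (nrow(X) < max(k_range)) stop("more clusters requested than rows")
  if (nrow(unique(X)) == 1) stop("all rows identical; clustering undefined")
  with_seed(seed, {
    scan <- if (is.null(k)) k_range else unique(c(k_range, k))
    wss <- setNames(numeric(length(scan)), scan)
    fits <- vector("list", length(scan))
    for (i in seq_along(scan)) {
      kk <- scan[i]
      fits[[i]] <- if (kk == 1) {
        list(cluster = rep(1L, nrow(X)),
             tot.withinss = sum(scale(X, scale = FALSE)^2))
      } else {
        kmeans(X, centers = kk, nstart = nstart, iter.max = 50)
      }
      wss[i] <- fits[[i]]$tot.withinss
    }
    if (is.null(k)) {
      k <- choose_k_elbow(scan, wss)
    }
    labels <- fits[[match(k, scan)]]$cluster
    names(labels) <- rownames(X)
    structure(list(labels = labels, k = k, wss = wss, k_range = k_range,
                   seed = seed),
              class = "cluster_result")
  })
}

# Elbow rule: k maximising the second difference of the WSS curve
# (interior points only; falls back to the smallest candidate otherwise).
choose_k_elbow <- function(ks, wss) {
  if (length(ks) < 3) return(ks[which.min(wss)])
  d2 <- diff(diff(wss))
  ks[which.max(d2) + 1L]
}

#' Kendall coincidence of two partitions
#'
#' Measures agreement between two clusterings of the same lines. The second
#' partition's labels are first aligned to the first by the assignment that
#' maximises the contingency-table agreement (searched exhaustively over
#' label permutations, hence deterministic and order-invariant), then
#' Kendall's tau is computed between the aligned label vectors with the
#' usual large-sample normal p-value in the presence of ties.
#'
#' @param labels_a,labels_b cluster label vectors over the same lines (same
#'   order).
#' @param alpha significance level for the `significant` flag.
#' @return List: `tau`, `p`, `significant`, `aligned_b`.
#' @export
kendall_coincidence <- function(labels_a, labels_b, alpha = 0.01) {
  if (length(labels_a) != length(labels_b))
    stop("partitions cover different numbers of lines")
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  b <- align_labels(a, b)
  ct <- suppressWarnings(cor.test(a, b, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha, aligned_b = b)
}

# Relabel b to maximise sum of the diagonal of the a x b contingency table.
# Exhaustive over permutations of b's labels (fine for the small k used in
# heterotic-group work); greedy fallback beyond 7 groups.
align_labels <- function(a, b) {
  ka <- max(a); kb <- max(b)
  tab <- table(factor(a, levels = seq_len(max(ka, kb))),
               factor(b, levels = seq_len(max(ka, kb))))
  k <- max(ka, kb)
  if (k <= 7) {
    perms <- permutations_of(seq_len(k))
    best <- perms[[which.max(vapply(perms, function(p)
      sum(tab[cbind(p, seq_len(k))]), 0))]]
  } else {
    best <- integer(k); used <- logical(k)
    for (j in order(-apply(tab, 2, max))) {
      cand <- order(-tab[, j])
      pick <- cand[!used[cand]][1]
      best[j] <- pick; used[pick] <- TRUE
    }
  }
  best[b]
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles, with significance from
#' joint row/column permutations of the second matrix. The p-value uses the
#' add-one estimator `(1 + #{r_perm >= r_obs}) / (n_perm + 1)` (one-sided,
#' upper tail), so it can never be exactly zero and has resolution
#' `1/(n_perm + 1)`.
#'
#' @param D1,D2 distance matrices over the same ids in the same order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 1000, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!identical(dim(D1), dim(D2)))
    stop("distance matrices of different size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("distance matrices over different ids or orders")
  n <- nrow(D1)
  lt <- lower.tri(D1)
  x <- D1[lt]
  if (sd(x) == 0 || sd(D2[lt]) == 0)
    stop("constant distance matrix; Mantel correlation undefined")
  r_obs <- cor(x, D2[lt])
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(x, D2[p, p][lt])
    }, 0)
  })
  structure(list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mantel_result")
}

#' Cross-dataset eigenvector R-squared grid
#'
#' Squared Pearson correlations between the first `n` principal
#' coordinates of two analyses of the same lines — the standard display for
#' asking whether two marker platforms recover the same structure axes.
#'
#' @param P1,P2 `pcoa_result` objects over the same lines.
#' @param n number of eigenvectors from each side.
#' @return An n x n matrix; entry (i, j) is R^2 between eigenvector i of
#'   `P1` and eigenvector j of `P2`.
#' @export
eigenvector_r2 <- function(P1, P2, n = 10) {
  V1 <- P1$vectors; V2 <- P2$vectors
  if (!identical(rownames(V1), rownames(V2)))
    stop("analyses cover different lines")
  if (ncol(V1) < n || ncol(V2) < n) stop("fewer than n eigenvectors")
  R <- matrix(NA_real_, n, n,
              dimnames = list(paste0("P1.", 1:n), paste0("P2.", 1:n)))
  for (i in 1:n) for (j in 1:n) {
    v1 <- V1[, i]; v2 <- V2[, j]
    R[i, j] <- if (sd(v1) == 0 || sd(v2) == 0) 0 else cor(v1, v2)^2
  }
  R
}
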