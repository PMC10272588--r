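#' GCA/SCA genomic diallel model
#'
#' Fits the two-kernel mixed model `y = 1 mu + Z_P g_P + Z_H h + e` to the
#' adjusted means of the observed single crosses: `g_P` holds general
#' combining abilities of the parents with covariance `s2_P G_P`
#' (marker-derived parental kernel), `h` the specific combining abilities
#' of the crosses with covariance `s2_H H` (Kronecker-derived SCA kernel),
#' and `e ~ N(0, s2_e I)`. `Z_P` sums the two parental incidences of each
#' cross; `Z_H` is the identity on observed crosses.
#'
#' @param means an `adjusted_means` data frame (or a named numeric vector
#'   keyed by cross id).
#' @param design a [hybrid_design()]; only rows flagged `observed` and
#'   present in `means` are fitted.
#' @param Gp parental kernel from [gp_matrix()].
#' @param H optional SCA kernel over the observed crosses; computed with
#'   [sca_kernel()] when omitted.
#' @param ... passed to [reml_fit()].
#' @return Object of class `diallel_fit`: `gca` (named per parent), `sca`
#'   (named per observed cross), `varcomps` (`gca`, `sca`, `residual`),
#'   `mu`, `logl`, `fit` (the underlying `lmm_fit`), `design`.
#' @export
fit_diallel <- function(means, design, Gp, H = NULL, ...) {
  y <- as_means_vector(means)
  obs <- design[design$observed & design$cross %in% names(y), ]
  if (nrow(obs) < 3) stop("too few observed crosses")
  y <- y[obs$cross]
  parents <- rownames(Gp)
  used <- unique(c(obs$parent_a, obs$parent_b))
  if (!all(used %in% parents)) stop("cross parents missing from Gp")
  if (!all(parents %in% used))
    stop("parent appearing in no observed cross: ",
         paste(setdiff(parents, used), collapse = ", "))
  n <- nrow(obs)
  Zp <- matrix(0, n, length(parents), dimnames = list(obs$cross, parents))
  Zp[cbind(seq_len(n), match(obs$parent_a, parents))] <- 1
  Zp[cbind(seq_len(n), match(obs$parent_b, parents))] <-
    Zp[cbind(seq_len(n), match(obs$parent_b, parents))] + 1
  if (is.null(H)) H <- sca_kernel(Gp, obs)
  H <- H[obs$cross, obs$cross]
  fit <- reml_fit(y, random = list(gca = list(Z = Zp, K = unclass(Gp)),
                                   sca = list(K = unclass(H))), ...)
  names(fit$u$sca) <- obs$cross
  structure(list(gca = fit$u$gca, sca = fit$u$sca,
                 varcomps = setNames(fit$varcomps,
                                     c("gca", "sca", "residual")),
                 mu = unname(fit$beta[1]), logl = fit$logl, fit = fit,
                 design = obs),
            class = "diallel_fit")
}

as_means_vector <- function(means) {
  if (inherits(means, "adjusted_means") || is.data.frame(means))
    setNames(means$blue, means$entry)
  else means
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat(sprintf("diallel fit: %d parents, %d observed crosses\n",
              length(x$gca), length(x$sca)))
  cat("variance components:\n"); print(round(x$varcomps, 6))
  invisible(x)
}

#' Complete parent-by-parent SCA matrix
#'
#' Arranges SCA estimates as a symmetric parents x parents matrix, the
#' genetic-distance-like surface from which heterotic groups are read.
#' Observed crosses take their BLUPs; unobserved pairs are filled with
#' model-based predictions through the SCA kernel ([blup_predict()]); the
#' diagonal is 0 by convention (no self-crosses).
#'
#' @param fit a `diallel_fit`.
#' @param Gp the parental kernel used in the fit.
#' @param ridge ridge for the kernel inversion.
#' @return A symmetric matrix of class `sca_matrix`.
#' @export
complete_sca_matrix <- function(fit, Gp, ridge = 1e-6) {
  parents <- names(fit$gca)
  S <- matrix(0, length(parents), length(parents),
              dimnames = list(parents, parents))
  obs <- fit$design
  S[cbind(obs$parent_a, obs$parent_b)] <- fit$sca
  S[cbind(obs$parent_b, obs$parent_a)] <- fit$sca
  all_pairs <- diallel_design(parents)
  todo <- all_pairs[!all_pairs$cross %in% obs$cross, ]
  if (nrow(todo) > 0) {
    full <- rbind(obs[, c("parent_a", "parent_b", "cross", "observed")],
                  cbind(todo[, c("parent_a", "parent_b", "cross")],
                        observed = FALSE))
    class(full) <- c("hybrid_design", "data.frame")
    Hfull <- sca_kernel(Gp, full)
    pred <- blup_predict(fit$sca,
                         K_cross = Hfull[todo$cross, obs$cross, drop = FALSE],
                         K_train = Hfull[obs$cross, obs$cross],
                         ridge = ridge)
    S[cbind(todo$parent_a, todo$parent_b)] <- pred
    S[cbind(todo$parent_b, todo$parent_a)] <- pred
  }
  diag(S) <- 0
  class(S) <- c("sca_matrix", class(S))
  S
}

#' Heterotic groups from the SCA matrix
#'
#' Clusters parents by k-means on the rows of the completed SCA matrix.
#' Parents that combine similarly with the rest of the panel fall in the
#' same group; because high SCA indicates heterosis, the expected pattern
#' is low SCA within groups and high SCA between groups.
#'
#' @param S a complete `sca_matrix`.
#' @param k number of heterotic groups (2 for the classical two-pool
#'   scheme).
#' @param seed integer seed for the k-means restarts.
#' @return A data frame of class `heterotic_partition` (`parent`, `group`,
#'   `is_tester`), testers unset until [choose_testers()].
#' @export
heterotic_partition <- function(S, k = 2, seed = 1) {
  if (k > nrow(S)) stop("more groups than parents")
  cl <- kmeans_partition(unclass(S), k = k, k_range = k, seed = seed)
  out <- data.frame(parent = rownames(S), group = unname(cl$labels),
                    is_tester = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("heterotic_partition", "data.frame")
  out
}

#' Elect a tester per heterotic group
#'
#' The tester of a group is the line with the best average predicted
#' performance when crossed to the opposite group. Under the default
#' `rule = "mean_cross"` the score of line i in group g is the mean over
#' lines j outside g of `gca_i + gca_j + sca_ij`; `rule = "gca"` ranks by
#' GCA alone. Ties break towards the lexicographically first parent id.
#'
#' @param partition a `heterotic_partition`.
#' @param fit the `diallel_fit` providing GCA estimates.
#' @param S the complete `sca_matrix`.
#' @param rule `"mean_cross"` (default) or `"gca"`.
#' @return The partition with `is_tester` set (exactly one per group) and
#'   per-parent `tester_score` attached.
#' @export
choose_testers <- function(partition, fit, S, rule = c("mean_cross", "gca")) {
  rule <- match.arg(rule)
  stopifnot(identical(sort(partition$parent), sort(names(fit$gca))))
  gca <- fit$gca[partition$parent]
  score <- numeric(nrow(partition))
  for (i in seq_len(nrow(partition))) {
    other <- partition$parent[partition$group != partition$group[i]]
    if (length(other) == 0) stop("empty complementary group")
    score[i] <- if (rule == "gca") gca[i]
    else gca[i] + mean(gca[other] + S[partition$parent[i], other])
  }
  partition$tester_score <- score
  partition$is_tester <- FALSE
  for (g in unique(partition$group)) {
    ig <- which(partition$group == g)
    best <- ig[order(-score[ig], partition$parent[ig])][1]
    partition$is_tester[best] <- TRUE
  }
  partition
}

#' Enumerate North Carolina II crosses between two heterotic groups
#'
#' All between-group parent pairs of a two-group partition — the
#' inter-population factorial a breeder would make after defining pools —
#' with no within-group pair. Observed flags are carried over from a
#' reference design when given.
#'
#' @param partition a two-group `heterotic_partition`.
#' @param observed_design optional [hybrid_design()] whose `observed` flags
#'   mark which NCII crosses already have data.
#' @return A [hybrid_design()] of the between-group crosses.
#' @export
enumerate_ncii <- function(partition, observed_design = NULL) {
  gs <- unique(partition$group)
  if (length(gs) != 2) stop("NCII enumeration requires exactly two groups")
  g1 <- partition$parent[partition$group == gs[1]]
  g2 <- partition$parent[partition$group == gs[2]]
  grid <- expand.grid(parent_a = g1, parent_b = g2,
                      stringsAsFactors = FALSE)
  des <- hybrid_design(grid$parent_a, grid$parent_b)
  des$observed <- if (is.null(observed_design)) FALSE
  else des$cross %in% observed_design$cross[observed_design$observed]
  des
}

#' Concordance of two heterotic partitions
#'
#' Aligns the second two-group partition to the first (identity or label
#' swap, whichever agrees more), then reports the Pearson (phi)
#' correlation between the aligned 0/1 membership vectors, its t-test
#' p-value, and the fraction of groups whose elected tester coincides.
#'
#' @param p1,p2 `heterotic_partition`s over the same parents.
#' @param alpha significance level for the flag.
#' @return List: `r`, `p`, `significant`, `tester_coincidence`.
#' @export
partition_concordance <- function(p1, p2, alpha = 0.01) {
  if (!setequal(p1$parent, p2$parent))
    stop("partitions cover different parent sets")
  p2 <- p2[match(p1$parent, p2$parent), ]
  if (length(unique(p1$group)) != 2 || length(unique(p2$group)) != 2)
    stop("concordance defined for two-group partitions")
  a <- as.integer(factor(p1$group)) - 1L
  b <- as.integer(factor(p2$group)) - 1L
  if (sum(a == b) < sum(a == 1L - b)) b <- 1L - b
  ct <- suppressWarnings(cor.test(a, b))
  tc <- NA_real_
  if (any(p1$is_tester) && any(p2$is_tester)) {
    t1 <- sort(p1$parent[p1$is_tester])
    t2 <- sort(p2$parent[p2$is_tester])
    tc <- mean(t1 %in% t2)
  }
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha, tester_coincidence = tc)
}
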