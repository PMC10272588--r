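#' Single-cross mating design
#'
#' An ordered list of unordered crosses between inbred parents, with an
#' observed/to-predict flag. Cross ids are canonical: the two parent ids
#' sorted, joined by `":"`, so parent order never matters.
#'
#' @param parent_a,parent_b character vectors of parent ids.
#' @param observed logical vector (recycled): was the cross phenotyped?
#' @return A data frame of class `hybrid_design` with columns `parent_a`,
#'   `parent_b`, `cross`, `observed`.
#' @export
hybrid_design <- function(parent_a, parent_b, observed = TRUE) {
  parent_a <- as.character(parent_a); parent_b <- as.character(parent_b)
  stopifnot(length(parent_a) == length(parent_b))
  if (any(parent_a == parent_b)) stop("self-crosses are not allowed")
  a <- pmin(parent_a, parent_b); b <- pmax(parent_a, parent_b)
  id <- paste(a, b, sep = ":")
  if (anyDuplicated(id)) stop("duplicated crosses in design")
  out <- data.frame(parent_a = a, parent_b = b, cross = id,
                    observed = rep_len(observed, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("hybrid_design", "data.frame")
  out
}

#' @rdname hybrid_design
#' @param parents parent ids for a diallel among all pairs.
#' @param cross_fraction fraction of the possible crosses marked observed
#'   (an incomplete diallel); the remainder are kept with
#'   `observed = FALSE`.
#' @param seed seed for sampling which crosses are realised.
#' @export
diallel_design <- function(parents, cross_fraction = 1, seed = 1) {
  parents <- as.character(parents)
  stopifnot(length(parents) >= 2, !anyDuplicated(parents))
  pairs <- utils::combn(parents, 2)
  n <- ncol(pairs)
  obs <- rep(TRUE, n)
  if (cross_fraction < 1) {
    n_obs <- max(2, round(cross_fraction * n))
    obs <- rep(FALSE, n)
    obs[with_seed(seed, sample.int(n, n_obs))] <- TRUE
  }
  hybrid_design(pairs[1, ], pairs[2, ], observed = obs)
}

#' In-silico single-cross genotypes
#'
#' Combines homozygous parental dosages into hybrid marker matrices: the
#' additive code `W_A` (0 / 1 / 2 copies of the second allele, i.e. the
#' mean of the parental dosages) and the dominance code `W_D` (1 where the
#' parents carry different homozygous dosages — the hybrid is heterozygous
#' — and 0 otherwise). Parent order is irrelevant by construction.
#'
#' @param G_parents homozygous parental [genotype_matrix()] (post
#'   [qc_hybrid_panel()]).
#' @param design a [hybrid_design()].
#' @return A list of class `hybrid_genotypes` with matrices `W_A` and
#'   `W_D` (crosses x markers, rownames the cross ids).
#' @export
build_hybrid_genotypes <- function(G_parents, design) {
  d <- if (inherits(G_parents, "GenotypeMatrix")) G_parents$dosages else G_parents
  miss <- setdiff(unique(c(design$parent_a, design$parent_b)), rownames(d))
  if (length(miss) > 0)
    stop("parents absent from genotype matrix: ", paste(miss, collapse = ", "))
  het <- which(d == 1, arr.ind = TRUE)
  if (nrow(het) > 0)
    stop(sprintf("heterozygous parent dosage at line %s, marker %s",
                 rownames(d)[het[1, 1]], colnames(d)[het[1, 2]]))
  ga <- d[design$parent_a, , drop = FALSE]
  gb <- d[design$parent_b, , drop = FALSE]
  W_A <- (ga + gb) / 2
  W_D <- (ga != gb) * 1
  rownames(W_A) <- rownames(W_D) <- design$cross
  structure(list(W_A = W_A, W_D = W_D), class = "hybrid_genotypes")
}

#' Parental genomic relationship matrix
#'
#' VanRaden-style kernel on the parental lines from centred and
#' standardised marker columns: `G_P = W_P W_P' / p` with `W_P` the
#' column-wise scaled dosage matrix and `p` the marker count. The average
#' diagonal is ~1, putting the GCA variance component on the residual
#' scale.
#'
#' @param G_parents a [genotype_matrix()] or plain dosage matrix without
#'   missing values or monomorphic markers.
#' @return A `kinship_matrix` (symmetric, ids as dimnames, attribute
#'   `kind = "Gp"`).
#' @export
gp_matrix <- function(G_parents) {
  d <- if (inherits(G_parents, "GenotypeMatrix")) G_parents$dosages else as.matrix(G_parents)
  if (anyNA(d)) stop("missing dosages; impute first")
  sds <- apply(d, 2, sd)
  if (any(sds == 0)) stop("monomorphic (zero-variance) markers present")
  W <- scale(d)
  K <- tcrossprod(W) / ncol(W)
  kinship(K, "Gp")
}

kinship <- function(K, kind) {
  K <- (K + t(K)) / 2
  attr(K, "kind") <- kind
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Additive and dominance kernels of single crosses
#'
#' `additive_G()` centres the columns of the additive hybrid codes `W_A` by
#' twice the allele frequency and scales by `2 * sum p_i (1 - p_i)`;
#' `dominance_G()` centres the heterozygosity codes `W_D` by
#' `2 p_i (1 - p_i)` and scales by `4 * sum (p_i (1 - p_i))^2`. Allele
#' frequencies are computed from `W_A` of the modelled cross population
#' itself (pass `p` to override, e.g. to reuse training-set frequencies).
#'
#' @param W_A,W_D hybrid marker matrices from [build_hybrid_genotypes()].
#' @param p optional vector of allele frequencies per marker.
#' @return A `kinship_matrix` over the crosses.
#' @export
additive_G <- function(W_A, p = NULL) {
  if (nrow(W_A) < 2) stop("need at least two crosses")
  if (is.null(p)) p <- colMeans(W_A) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic across crosses")
  Z <- sweep(W_A, 2, 2 * p)
  kinship(tcrossprod(Z) / denom, "Ga")
}

#' @rdname additive_G
#' @param strict_uncentered if `TRUE`, skip the centering of `W_D` (the
#'   literal raw-coding form); default `FALSE`.
#' @export
dominance_G <- function(W_D, p = NULL, strict_uncentered = FALSE) {
  if (nrow(W_D) < 2) stop("need at least two crosses")
  if (all(W_D == 0))
    stop("no heterozygous hybrid genotypes; dominance kernel degenerate")
  if (is.null(p)) {
    # W_D alone does not identify allele frequency; require explicit p
    stop("supply allele frequencies p (e.g. colMeans(W_A)/2)")
  }
  pq <- p * (1 - p)
  denom <- 4 * sum(pq^2)
  if (denom == 0) stop("all markers monomorphic")
  Z <- if (strict_uncentered) W_D else sweep(W_D, 2, 2 * pq)
  kinship(tcrossprod(Z) / denom, "Gd")
}

#' SCA kernel of single crosses from the parental kernel
#'
#' Relationship among specific-combining-ability effects, derived from the
#' parental kernel by the Kronecker product `G_P (x) G_P` restricted to the
#' design's crosses. Because crosses are unordered, entries are symmetrised
#' over parent order:
#' `H[(i,j),(k,l)] = (Gp[i,k] Gp[j,l] + Gp[i,l] Gp[j,k]) / 2`. Set
#' `symmetrize = FALSE` for the plain Kronecker subset
#' `Gp[i,k] * Gp[j,l]`.
#'
#' @param Gp parental `kinship_matrix` from [gp_matrix()].
#' @param design a [hybrid_design()] (observed and to-predict crosses).
#' @param symmetrize symmetrise over parent order (default `TRUE`).
#' @return A `kinship_matrix` over the design's crosses.
#' @export
sca_kernel <- function(Gp, design, symmetrize = TRUE) {
  miss <- setdiff(unique(c(design$parent_a, design$parent_b)), rownames(Gp))
  if (length(miss) > 0)
    stop("unknown parent id: ", paste(miss, collapse = ", "))
  i <- design$parent_a; j <- design$parent_b
  H <- if (symmetrize) {
    0.5 * (Gp[i, i, drop = FALSE] * Gp[j, j, drop = FALSE] +
             Gp[i, j, drop = FALSE] * Gp[j, i, drop = FALSE])
  } else {
    Gp[i, i, drop = FALSE] * Gp[j, j, drop = FALSE]
  }
  dimnames(H) <- list(design$cross, design$cross)
  kinship(H, "H")
}
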