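test_that("hybrid designs are unordered, unique, self-free", {
  expect_error(hybrid_design("A", "A"), "self")
  expect_error(hybrid_design(c("A", "B"), c("B", "A")), "duplicated")
  d <- hybrid_design(c("B", "C"), c("A", "A"))
  expect_equal(d$cross, c("A:B", "A:C"))
  dd <- diallel_design(LETTERS[1:5], cross_fraction = 0.6, seed = 3)
  expect_equal(nrow(dd), 10)
  expect_equal(sum(dd$observed), 6)
})

test_that("in-silico hybrid codes follow the additive/dominance conventions", {
  G <- toy_gm(c(0, 0, 2, 2), c(0, 2, 0, 2), c(2, 2, 2, 0))
  des <- hybrid_design(c("L1", "L1", "L2"), c("L2", "L3", "L3"))
  W <- build_hybrid_genotypes(G, des)
  expect_equal(unname(W$W_A["L1:L2", ]), c(0, 1, 1, 2))
  expect_equal(unname(W$W_D["L1:L2", ]), c(0, 1, 1, 0))
  expect_equal(unname(W$W_A["L1:L3", ]), c(1, 1, 2, 1))
  expect_equal(unname(W$W_D["L1:L3", ]), c(1, 1, 0, 1))
  # parent-order swap changes nothing
  des_sw <- hybrid_design(c("L2", "L3", "L3"), c("L1", "L1", "L2"))
  W2 <- build_hybrid_genotypes(G, des_sw)
  expect_identical(W$W_A, W2$W_A)
  expect_identical(W$W_D, W2$W_D)
  # heterozygous parents rejected with location
  Gh <- toy_gm(c(0, 1), c(2, 0))
  expect_error(build_hybrid_genotypes(Gh, hybrid_design("L1", "L2")),
               "heterozygous parent dosage at line L1, marker M2")
  expect_error(build_hybrid_genotypes(G, hybrid_design("L1", "LX")),
               "absent")
})

test_that("parental kernel matches brute force and has ~unit diagonal", {
  d <- rbind(L1 = c(0, 2, 2, 0), L2 = c(2, 2, 0, 0), L3 = c(0, 0, 2, 2))
  colnames(d) <- paste0("M", 1:4)
  Gp <- gp_matrix(genotype_matrix(d))
  W <- scale(d)
  expect_equal(unclass(Gp), tcrossprod(W, W) / 4, tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated line: identical rows, off-diagonal equals diagonal
  d2 <- rbind(d, L4 = d["L1", ])
  Gp2 <- gp_matrix(genotype_matrix(d2))
  expect_equal(Gp2["L1", "L4"], Gp2["L1", "L1"])
  expect_equal(Gp2["L4", ], Gp2["L1", ], ignore_attr = TRUE)
  # average diagonal ~ 1 on a simulated panel
  qs <- quick_sim(41, n_lines = 50, n_markers = 1000)
  expect_lt(abs(mean(diag(gp_matrix(qs$G))) - 1), 0.1)
  expect_error(gp_matrix(toy_gm(c(0, 0), c(0, 2))), "monomorphic")
})

test_that("additive and dominance kernels match brute-force evaluation", {
  set.seed(42)
  G <- toy_gm(c(0, 0, 2, 2, 0), c(0, 2, 0, 2, 2), c(2, 2, 2, 0, 0),
              c(2, 0, 0, 0, 2))
  des <- diallel_design(paste0("L", 1:4))  # 6 crosses
  W <- build_hybrid_genotypes(G, des)
  p <- colMeans(W$W_A) / 2
  Ga <- additive_G(W$W_A, p)
  Gd <- dominance_G(W$W_D, p)
  # brute force by explicit loops
  Z <- W$W_A - matrix(2 * p, nrow(W$W_A), length(p), byrow = TRUE)
  Ga_ref <- (Z %*% t(Z)) / (2 * sum(p * (1 - p)))
  Zd <- W$W_D - matrix(2 * p * (1 - p), nrow(W$W_D), length(p), byrow = TRUE)
  Gd_ref <- (Zd %*% t(Zd)) / (4 * sum((p * (1 - p))^2))
  expect_equal(unclass(Ga), Ga_ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(Gd), Gd_ref, tolerance = 1e-12, ignore_attr = TRUE)
  # algebraic consequences of the centering
  expect_lt(max(abs(rowSums(unclass(Ga)))), 1e-9)
  # Gd centering uses 2pq, which matches the empirical heterozygote
  # frequency only under random parent pairing: row sums vanish
  # approximately on a large design, not on a 4-parent toy
  qsd <- quick_sim(46, n_lines = 25, n_markers = 1500, cross_fraction = 1,
                   directional_dominance = FALSE)
  Wd <- build_hybrid_genotypes(qsd$G, qsd$truth$design)
  pd <- colMeans(Wd$W_A) / 2
  Gdd <- dominance_G(Wd$W_D, pd)
  expect_lt(max(abs(rowSums(unclass(Gdd)))) / (nrow(Gdd) * mean(diag(Gdd))),
            0.1)
  # duplicating every marker leaves Ga unchanged
  Ga_dup <- additive_G(cbind(W$W_A, W$W_A))
  expect_equal(unclass(Ga_dup), unclass(Ga), tolerance = 1e-12)
  # degenerate dominance input rejected
  expect_error(dominance_G(matrix(0, 3, 4,
                                  dimnames = list(paste0("c", 1:3), NULL)),
                           p = rep(0.5, 4)), "degenerate")
  expect_error(dominance_G(W$W_D), "frequencies")
})

test_that("SCA kernel equals the symmetrised Kronecker product", {
  set.seed(7)
  # random PSD parental kernel over 5 parents
  A <- matrix(rnorm(25), 5)
  Gp <- tcrossprod(A) / 5
  dimnames(Gp) <- list(paste0("P", 1:5), paste0("P", 1:5))
  des <- diallel_design(paste0("P", 1:5))  # all 10 crosses
  H <- sca_kernel(structure(Gp, class = c("kinship_matrix", "matrix")), des)
  # explicit Kronecker oracle with named pair indices
  Kron <- kronecker(Gp, Gp)
  pair_names <- as.vector(outer(rownames(Gp), rownames(Gp),
                                function(a, b) paste(a, b, sep = "|")))
  dimnames(Kron) <- list(pair_names, pair_names)
  look <- function(i, j, k, l)
    Kron[paste(i, j, sep = "|"), paste(k, l, sep = "|")]
  for (r in seq_len(nrow(des))) for (s in seq_len(nrow(des))) {
    i <- des$parent_a[r]; j <- des$parent_b[r]
    k <- des$parent_a[s]; l <- des$parent_b[s]
    expect_equal(H[r, s], 0.5 * (look(i, j, k, l) + look(i, j, l, k)),
                 tolerance = 1e-10)
  }
  # identity parental kernel: diagonal 1/2, off-diagonal 0 without shared parents
  I5 <- diag(5); dimnames(I5) <- dimnames(Gp)
  Hi <- sca_kernel(structure(I5, class = c("kinship_matrix", "matrix")), des)
  expect_equal(unname(diag(Hi)), rep(0.5, 10))
  expect_equal(Hi["P1:P2", "P3:P4"], 0)
  # general diagonal identity
  expect_equal(H["P1:P2", "P1:P2"],
               0.5 * (Gp["P1", "P1"] * Gp["P2", "P2"] + Gp["P1", "P2"]^2))
  expect_error(sca_kernel(structure(I5, class = c("kinship_matrix", "matrix")),
                          hybrid_design("P1", "P9")), "unknown parent")
})

test_that("kernels are symmetric positive semidefinite", {
  qs <- quick_sim(43, n_lines = 25, n_markers = 500, cross_fraction = 1)
  W <- build_hybrid_genotypes(qs$G, qs$truth$design)
  p <- colMeans(W$W_A) / 2
  for (K in list(gp_matrix(qs$G), additive_G(W$W_A, p),
                 dominance_G(W$W_D, p),
                 sca_kernel(gp_matrix(qs$G), qs$truth$design))) {
    expect_equal(unclass(K), t(unclass(K)), tolerance = 1e-12)
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("Kronecker lookup works on kronecker-oracle sizes up to 6 parents", {
  set.seed(8)
  A <- matrix(rnorm(36), 6)
  Gp <- tcrossprod(A) / 6
  dimnames(Gp) <- list(paste0("Q", 1:6), paste0("Q", 1:6))
  des <- diallel_design(paste0("Q", 1:6))
  H <- sca_kernel(structure(Gp, class = c("kinship_matrix", "matrix")), des,
                  symmetrize = FALSE)
  Kron <- kronecker(Gp, Gp)
  pair_names <- as.vector(outer(rownames(Gp), rownames(Gp),
                                function(a, b) paste(a, b, sep = "|")))
  dimnames(Kron) <- list(pair_names, pair_names)
  for (r in c(1, 5, 15)) for (s in c(2, 9, 14)) {
    i <- des$parent_a[r]; j <- des$parent_b[r]
    k <- des$parent_a[s]; l <- des$parent_b[s]
    expect_equal(H[r, s], Kron[paste(i, j, sep = "|"), paste(k, l, sep = "|")],
                 tolerance = 1e-10)
  }
})
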