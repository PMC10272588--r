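test_that("simulated parents are fully homozygous, deterministic, and structured", {
  cfg <- sim_config(n_lines = 60, n_markers = 400, n_pools = 3,
                    divergence = 0.2, n_diallel_parents = 10, seed = 42)
  sim1 <- simulate_parents(cfg)
  sim2 <- simulate_parents(cfg)
  d <- sim1$genotypes$dosages
  expect_true(all(d %in% c(0, 2)))
  expect_identical(d, sim2$genotypes$dosages)
  expect_equal(length(sim1$truth$pool_labels), 60)
  # no monomorphic markers survive regeneration
  expect_true(all(apply(d, 2, function(x) length(unique(x))) == 2))
  # marker coordinates: 10 chromosomes, 1-based consecutive positions
  expect_equal(length(unique(sim1$genotypes$chrom)), 10)
  expect_true(all(sim1$genotypes$pos >= 1))
})

test_that("divergence controls between-pool vs within-pool Rogers distance", {
  gap <- vapply(c(0.05, 0.3), function(f) {
    cfg <- sim_config(n_lines = 200, n_markers = 2000, n_pools = 2,
                      divergence = f, n_diallel_parents = 10, seed = 7)
    sim <- simulate_parents(cfg)
    D <- rogers_distance(sim$genotypes)
    same <- outer(sim$truth$pool_labels, sim$truth$pool_labels, "==")
    lt <- lower.tri(D)
    mean(D[lt & !same]) - mean(D[lt & same])
  }, 0)
  expect_gt(gap[2], gap[1])
  expect_gt(gap[2], 0.01)
})

test_that("divergence zero yields no pool separation (permutation check)", {
  cfg <- sim_config(n_lines = 80, n_markers = 500, n_pools = 2,
                    divergence = 0, n_diallel_parents = 10, seed = 9)
  sim <- simulate_parents(cfg)
  D <- rogers_distance(sim$genotypes)
  lt <- lower.tri(D)
  gap_for <- function(lab) {
    same <- outer(lab, lab, "==")
    mean(D[lt & !same]) - mean(D[lt & same])
  }
  obs <- gap_for(sim$truth$pool_labels)
  perm <- withr::with_seed(1, vapply(1:200, function(i)
    gap_for(sample(sim$truth$pool_labels)), 0))
  p <- (1 + sum(perm >= obs)) / 201
  expect_gt(p, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(divergence = 1), "divergence")
  expect_error(sim_config(n_lines = 10, n_diallel_parents = 11),
               "n_diallel_parents")
  expect_error(sim_config(var_additive = -1), "non-negative")
  expect_error(sim_config(n_envs = 0), "positive")
})

test_that("platform views subset markers faithfully", {
  cfg <- sim_config(n_lines = 50, n_markers = 300, n_pools = 2,
                    divergence = 0.2, n_diallel_parents = 10, seed = 3)
  sim <- simulate_parents(cfg)
  # full-size, no-missingness view is the identity
  v <- simulate_platform_views(sim$genotypes,
                               list(list(size = 300, missing_rate = 0)),
                               seed = 5)[[1]]
  expect_identical(v$dosages, sim$genotypes$dosages)
  # missingness injected at the requested rate
  v2 <- simulate_platform_views(sim$genotypes,
                                list(list(size = 250, missing_rate = 0.2)),
                                seed = 5)[[1]]
  expect_lt(abs(mean(is.na(v2$dosages)) - 0.2), 0.02)
  # two random views of one structured panel agree on structure
  vs <- simulate_platform_views(sim$genotypes,
                                list(list(size = 150), list(size = 150)),
                                seed = 8)
  mt <- mantel_test(rogers_distance(vs[[1]]), rogers_distance(vs[[2]]),
                    n_perm = 99, seed = 1)
  expect_gt(mt$r, 0)
  expect_error(simulate_platform_views(sim$genotypes,
                                       list(list(size = 0))), "empty")
  expect_error(simulate_platform_views(sim$genotypes,
                                       list(list(size = 301))), "exceeds")
})

test_that("biased ascertainment enriches for common variants", {
  cfg <- sim_config(n_lines = 100, n_markers = 2000, n_pools = 2,
                    divergence = 0.2, n_diallel_parents = 10, seed = 13)
  sim <- simulate_parents(cfg)
  vs <- simulate_platform_views(
    sim$genotypes,
    list(list(size = 400, ascertainment = "biased"),
         list(size = 400, ascertainment = "random")), seed = 2)
  maf <- function(V) {
    p <- colMeans(V$dosages) / 2
    mean(pmin(p, 1 - p))
  }
  expect_gt(maf(vs[[1]]), maf(vs[[2]]))
})

test_that("genetic effects honour the configured variance components", {
  # additive: realized variance over ~500 hybrids within 10% of target
  qs <- quick_sim(21, n_lines = 33, n_markers = 1500, cross_fraction = 1,
                  var_additive = 2, var_dominance = 0.5,
                  directional_dominance = FALSE)
  W <- build_hybrid_genotypes(qs$G, qs$truth$design)
  add <- drop(W$W_A %*% qs$truth$alpha)
  expect_gt(length(add), 500)
  expect_lt(abs(var(add) / 2 - 1), 0.1)
  # dominance values are consistent with var_dominance on the model scale:
  # realized variance ~ var_dominance * mean diagonal of Gd
  p <- colMeans(W$W_A) / 2
  Gd <- dominance_G(W$W_D, p)
  dom <- drop(W$W_D %*% qs$truth$delta)
  expect_lt(abs(var(dom) / (0.5 * mean(diag(Gd))) - 1), 0.25)
})

test_that("degenerate effect configurations behave as stated", {
  cfg0 <- sim_config(n_lines = 20, n_markers = 100, n_pools = 2,
                     divergence = 0.1, n_diallel_parents = 20,
                     var_dominance = 0, seed = 4)
  sim <- simulate_parents(cfg0)
  tr <- simulate_genetic_effects(sim$genotypes, cfg0)
  expect_true(all(tr$delta == 0))
  cfg00 <- sim_config(n_lines = 20, n_markers = 100, n_pools = 2,
                      divergence = 0.1, n_diallel_parents = 20,
                      var_additive = 0, var_dominance = 0, seed = 4)
  tr0 <- simulate_genetic_effects(sim$genotypes, cfg00)
  expect_equal(var(tr0$true_hybrid_values), 0)
  # all-monomorphic input is rejected
  mono <- genotype_matrix(matrix(2, 4, 3,
                                 dimnames = list(paste0("L", 1:4),
                                                 paste0("M", 1:3))))
  expect_error(simulate_genetic_effects(mono, cfg0), "monomorphic")
})

test_that("trial layout follows the augmented-block rules", {
  cfg <- sim_config(n_lines = 40, n_markers = 100, n_pools = 2,
                    n_diallel_parents = 30, n_envs = 8, block_size = 16,
                    n_checks = 2, seed = 5)
  hv <- setNames(rnorm(320), sprintf("H%03d", 1:320))
  trial <- simulate_trial_data(hv, cfg)
  per_env <- split(trial, trial$env)
  expect_equal(length(per_env), 8)
  for (tr in per_env[1:2]) {
    expect_equal(nrow(tr), 360)                       # 320 + 20 blocks x 2 checks
    expect_equal(length(unique(tr$block)), 20)
    # every check exactly once per block
    ck <- table(tr$entry[tr$is_check], tr$block[tr$is_check])
    expect_true(all(ck == 1))
    # every hybrid exactly once per environment
    expect_equal(sort(unique(tr$entry[!tr$is_check])), sort(names(hv)))
  }
  # determinism
  trial2 <- simulate_trial_data(hv, cfg)
  expect_identical(trial$value, trial2$value)
})

test_that("noise-free trials reproduce the true hybrid values exactly", {
  cfg <- sim_config(n_lines = 20, n_markers = 50, n_pools = 2,
                    n_diallel_parents = 10, n_envs = 2, block_size = 4,
                    var_env = 0, var_block = 0, var_residual = 0, seed = 6)
  hv <- setNames(1:10 * 1.0, sprintf("H%02d", 1:10))
  trial <- simulate_trial_data(hv, cfg)
  hy <- trial[!trial$is_check, ]
  expect_equal(hy$value, unname(hv[hy$entry]))
})
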