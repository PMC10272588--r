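test_that("intercept-only REML returns the n-1 sample variance", {
  set.seed(1)
  y <- rnorm(12, 5, 2)
  f <- reml_fit(y)
  expect_equal(unname(f$varcomps["residual"]), var(y), tolerance = 1e-6)
  expect_equal(unname(f$beta), mean(y), tolerance = 1e-8)
})

test_that("balanced one-way design matches closed-form ANOVA REML", {
  set.seed(2)
  b <- 8; n_per <- 5
  g <- rep(1:b, each = n_per)
  u <- rnorm(b, 0, sqrt(2))
  y <- 10 + u[g] + rnorm(b * n_per, 0, 1)
  Z <- outer(g, 1:b, "==") * 1
  f <- reml_fit(y, random = list(grp = list(Z = Z)))
  # textbook: sigma2_e = MSE, sigma2_g = (MSB - MSE) / n_per
  means <- tapply(y, g, mean)
  mse <- sum((y - means[g])^2) / (b * (n_per - 1))
  msb <- n_per * sum((means - mean(y))^2) / (b - 1)
  expect_equal(unname(f$varcomps["grp"]), (msb - mse) / n_per,
               tolerance = 1e-5)
  expect_equal(unname(f$varcomps["residual"]), mse, tolerance = 1e-5)
})

test_that("single-kernel fits agree with a dense grid-search oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- 12
    A <- matrix(rnorm(n * n), n)
    K <- tcrossprod(A) / n
    u <- drop(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n))
    y <- 3 + u + rnorm(n, 0, 1)
    f <- reml_fit(y, random = list(k = list(K = K)), tol = 1e-10)
    orc <- grid_reml_1k(y, K)
    # near a boundary optimum the profile is flat; 1e-3 covers the grid gap
    expect_lt(abs(f$logl - orc$logl), 1e-3)
    expect_lt(abs(f$varcomps["k"] - orc$sigma2_g), 1e-3)
    expect_lt(abs(f$varcomps["residual"] - orc$sigma2_e), 1e-3)
  }
})

test_that("BLUPs equal the direct mixed-model-equation solution", {
  set.seed(4)
  n <- 20; q <- 8
  Z <- matrix(0, n, q); Z[cbind(1:n, sample(1:q, n, TRUE))] <- 1
  A <- matrix(rnorm(q * q), q); K <- tcrossprod(A) / q + diag(q) * 0.1
  y <- 1 + drop(Z %*% (t(chol(K)) %*% rnorm(q))) + rnorm(n, 0, 0.7)
  X <- matrix(1, n, 1)
  f <- reml_fit(y, X, random = list(g = list(Z = Z, K = K)))
  ref <- mme_solve(y, X, Z, K, f$varcomps["g"], f$varcomps["residual"])
  expect_equal(unname(f$u$g), unname(ref$u), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(ref$beta), tolerance = 1e-6)
})

test_that("the REML log-likelihood trajectory never decreases", {
  for (s in 1:5) {
    set.seed(s)
    n <- 25
    A <- matrix(rnorm(n * 5), n, 5)
    K1 <- tcrossprod(A) / 5
    K2 <- diag(n)
    y <- rnorm(n) + drop(t(chol(K1 + 1e-6 * diag(n))) %*% rnorm(n))
    f <- reml_fit(y, random = list(a = list(K = K1), b = list(K = K2)))
    expect_true(all(diff(f$trajectory) >= -1e-8))
  }
})

test_that("BLUP prediction honours duplicates, zero kernels, and the MME", {
  set.seed(5)
  q <- 8
  A <- matrix(rnorm(q * q), q)
  K <- tcrossprod(A) / q + 0.05 * diag(q)
  dimnames(K) <- list(paste0("t", 1:q), paste0("t", 1:q))
  y <- drop(t(chol(K)) %*% rnorm(q)) + rnorm(q, 0, 0.5)
  f <- reml_fit(y, random = list(g = list(K = K)))
  u <- setNames(f$u$g, rownames(K))
  # a new level with a kernel row duplicating t3 predicts t3's BLUP
  pred_dup <- blup_predict(u, K_cross = matrix(K["t3", ], 1,
                                               dimnames = list("dup", colnames(K))),
                           K_train = K)
  expect_equal(unname(pred_dup), unname(u["t3"]), tolerance = 1e-4)
  # zero relationship predicts the prior mean 0
  z <- matrix(0, 1, q, dimnames = list("new", colnames(K)))
  expect_equal(unname(blup_predict(u, z, K_train = K)), 0)
  # augmented-MME oracle for a genuinely new level
  set.seed(6)
  B <- matrix(rnorm((q + 1)^2), q + 1)
  Kfull <- tcrossprod(B) / (q + 1) + 0.05 * diag(q + 1)
  dimnames(Kfull) <- list(paste0("s", 1:(q + 1)), paste0("s", 1:(q + 1)))
  yq <- drop(t(chol(Kfull[1:q, 1:q])) %*% rnorm(q)) + rnorm(q, 0, 0.5)
  fq <- reml_fit(yq, random = list(g = list(K = Kfull[1:q, 1:q])))
  # direct augmented solve: Z maps obs to the first q of q+1 levels
  Zaug <- cbind(diag(q), 0)
  ref <- mme_solve(yq, matrix(1, q, 1), Zaug, Kfull,
                   fq$varcomps["g"], fq$varcomps["residual"])
  pred <- blup_predict(setNames(fq$u$g, paste0("s", 1:q)),
                       K_cross = Kfull[q + 1, 1:q, drop = FALSE],
                       K_train = Kfull[1:q, 1:q], ridge = 1e-10)
  expect_equal(unname(pred), unname(ref$u[q + 1]), tolerance = 1e-6)
  # id overlap between new and training levels is an error
  expect_error(blup_predict(u, K_cross = rbind(t3 = K["t3", ]), K_train = K),
               "overlap")
})

test_that("BLUP shrinkage reaches both extremes", {
  set.seed(7)
  n <- 15
  A <- matrix(rnorm(n * n), n); K <- tcrossprod(A) / n
  # noiseless data generated by the kernel: fitted values -> observations
  y <- drop(t(chol(K + 1e-10 * diag(n))) %*% rnorm(n))
  f0 <- reml_fit(y, random = list(g = list(K = K)))
  expect_lt(max(abs(f0$fitted - y)), 1e-3)
  # pure noise orthogonal to a zero kernel relationship: predictions ~ 0
  u <- setNames(rnorm(n), paste0("t", 1:n))
  expect_equal(unname(blup_predict(u, matrix(0, 2, n,
                                             dimnames = list(c("a", "b"),
                                                             names(u))),
                                   K_train = K + diag(n))), c(0, 0))
})

test_that("heterogeneous residuals recover per-environment noise levels", {
  set.seed(8)
  n_per <- 80
  env <- rep(c("E1", "E2"), each = n_per)
  y <- c(rnorm(n_per, 0, 1), rnorm(n_per, 0, 3))
  f <- reml_fit(y, residual_groups = env)
  expect_lt(abs(f$varcomps["residual.E1"] - 1), 0.5)
  expect_gt(f$varcomps["residual.E2"], 5)
})

test_that("stage-1 BLUEs equal plot means in the noise-free case", {
  cfg <- sim_config(n_lines = 20, n_markers = 50, n_pools = 2,
                    n_diallel_parents = 10, n_envs = 3, block_size = 5,
                    var_env = 0, var_block = 0, var_residual = 0, seed = 9)
  hv <- setNames(seq(-2, 2, length.out = 15), sprintf("H%02d", 1:15))
  trial <- simulate_trial_data(hv, cfg)
  am <- stage1_blues(trial)
  expect_equal(setNames(am$blue, am$entry), hv[am$entry], tolerance = 1e-5)
  # checks never appear among adjusted means
  expect_false(any(grepl("^CHK", am$entry)))
})

test_that("balanced complete designs reproduce least-squares means", {
  # blocks containing every entry -> entry BLUEs orthogonal to blocks
  set.seed(10)
  entries <- sprintf("H%02d", 1:6)
  envs <- c("E1", "E2")
  plots <- expand.grid(entry = entries, block = c("B1", "B2"), env = envs,
                       stringsAsFactors = FALSE)
  plots$block <- paste(plots$env, plots$block, sep = "_")
  eff <- setNames(rnorm(6), entries)
  plots$value <- eff[plots$entry] + rnorm(nrow(plots), 0, 0.3) +
    c(E1 = 1, E2 = -1)[plots$env]
  plots$is_check <- FALSE
  am <- stage1_blues(plots, homogeneous = TRUE)
  ols <- lm(value ~ 0 + entry + env, data = plots,
            contrasts = list(env = "contr.sum"))
  expect_equal(am$blue, unname(coef(ols)[paste0("entry", entries)]),
               tolerance = 1e-5)
})
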