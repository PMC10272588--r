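#' Multi-kernel REML mixed model
#'
#' Fits `y = X b + sum_k Z_k u_k + e` with `u_k ~ N(0, s2_k K_k)` and
#' either a homogeneous residual `e ~ N(0, s2 I)` or independent
#' per-group (typically per-environment) residual variances. Variance
#' components are estimated by REML with EM updates accelerated by
#' average-information (AI) steps; any step that would decrease the REML
#' log-likelihood or cross the variance floor is rejected in favour of a
#' (step-halved) EM move, so the log-likelihood trajectory is
#' non-decreasing. BLUEs of the fixed effects and BLUPs of every random
#' term are returned from the mixed-model equations at the final variance
#' components.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default: intercept only). Must be
#'   full column rank.
#' @param random named list of random terms; each term is a list with
#'   optional `Z` (n x q incidence, default identity) and optional `K`
#'   (q x q covariance kernel, default identity).
#' @param residual_groups optional factor of length n: independent residual
#'   variance per level; `NULL` gives a homogeneous residual.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change in REML log-likelihood.
#' @param floor lower bound for every variance component.
#' @return An object of class `lmm_fit`: `varcomps` (named, residual
#'   components prefixed `"residual"`), `beta`, `u` (list of named BLUP
#'   vectors), `logl`, `trajectory`, `converged`, `fitted`, plus the
#'   per-term kernels for downstream prediction.
#' @examples
#' set.seed(1)
#' y <- rnorm(12)
#' f <- reml_fit(y)  # intercept only: residual = sample variance
#' all.equal(unname(f$varcomps["residual"]), var(y))
#' @export
reml_fit <- function(y, X = NULL, random = list(), residual_groups = NULL,
                     max_iter = 200, tol = 1e-8, floor = 1e-8) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X not conformable with y")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (n < ncol(X) + 2) stop("too few observations for REML")

  # expand random terms into n x n covariance structures G_k = Z K Z'
  terms <- lapply(random, function(tm) {
    Z <- tm$Z; K <- tm$K
    if (!is.null(Z)) {
      Z <- as.matrix(Z)
      if (nrow(Z) != n) stop("random-term incidence not conformable")
    }
    if (!is.null(K)) {
      K <- as.matrix(K)
      ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                          only.values = TRUE)$values)
      if (ev_min < -1e-6) stop("kernel is not positive semidefinite")
      if (!is.null(Z) && ncol(Z) != nrow(K))
        stop("kernel does not match incidence levels")
    }
    G <- if (is.null(Z) && is.null(K)) diag(n)
    else if (is.null(Z)) K
    else if (is.null(K)) tcrossprod(Z)
    else Z %*% K %*% t(Z)
    q <- if (!is.null(Z)) ncol(Z) else n
    list(Z = Z, K = K, G = (G + t(G)) / 2, q = q)
  })
  if (is.null(names(terms)) && length(terms) > 0)
    names(terms) <- paste0("u", seq_along(terms))

  # residual structures as additional variance components
  if (is.null(residual_groups)) {
    res_idx <- list(residual = seq_len(n))
  } else {
    residual_groups <- factor(residual_groups)
    res_idx <- split(seq_len(n), residual_groups)
    names(res_idx) <- paste0("residual.", names(res_idx))
  }
  res_G <- lapply(res_idx, function(ix) {
    D <- numeric(n); D[ix] <- 1; diag(D)
  })
  Gs <- c(lapply(terms, `[[`, "G"), res_G)
  qs <- c(vapply(terms, `[[`, 0, "q"), lengths(res_idx))
  nt <- length(Gs)

  # equal-split initialization of the phenotypic variance
  vy <- var(y)
  theta <- rep(max(vy, floor) / nt, nt)
  names(theta) <- names(Gs)

  loglik <- function(th) {
    V <- matrix(0, n, n)
    for (k in seq_len(nt)) V <- V + th[k] * Gs[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVinv <- crossprod(X, Vinv)
    XtVinvX <- XtVinv %*% X
    chx <- tryCatch(chol((XtVinvX + t(XtVinvX)) / 2),
                    error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - t(XtVinv) %*% chol2inv(chx) %*% XtVinv
    r <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * r))
    list(ll = ll, P = P, r = r, Vinv = Vinv, XtVinvX = XtVinvX)
  }

  st <- loglik(theta)
  if (is.null(st)) stop("initial covariance matrix not positive definite")
  traj <- st$ll
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    trPG <- vapply(Gs, function(G) sum(st$P * G), 0)
    yPGPy <- vapply(Gs, function(G) drop(crossprod(st$r, G %*% st$r)), 0)
    score <- -0.5 * (trPG - yPGPy)

    em_step <- theta + theta^2 / qs * (yPGPy - trPG)
    em_step <- pmax(em_step, floor)

    proposal <- NULL
    if (iter > 2) {  # AI acceleration after a couple of EM moves
      W <- lapply(Gs, function(G) G %*% st$r)
      AI <- matrix(0, nt, nt)
      for (k in seq_len(nt)) {
        PWk <- st$P %*% W[[k]]
        for (l in k:nt)
          AI[k, l] <- AI[l, k] <- 0.5 * sum(W[[l]] * PWk)
      }
      delta <- tryCatch(solve(AI + diag(1e-10, nt), score),
                        error = function(e) NULL)
      if (!is.null(delta)) proposal <- pmax(theta + delta, floor)
    }

    accepted <- FALSE
    for (cand in list(proposal, em_step)) {
      if (is.null(cand)) next
      step <- cand - theta
      for (h in 0:4) {  # step-halving against logL decreases
        th_try <- pmax(theta + step / 2^h, floor)
        st_try <- loglik(th_try)
        if (!is.null(st_try) && st_try$ll >= traj[length(traj)] - 1e-10) {
          theta <- th_try; st <- st_try; accepted <- TRUE
          break
        }
      }
      if (accepted) break
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill move left
    traj <- c(traj, st$ll)
    if (abs(traj[length(traj)] - traj[length(traj) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  beta <- drop(solve(st$XtVinvX, crossprod(X, st$Vinv %*% y)))
  names(beta) <- colnames(X)
  u <- vector("list", length(terms)); names(u) <- names(terms)
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    Ztr <- if (is.null(tm$Z)) st$r else drop(crossprod(tm$Z, st$r))
    u[[k]] <- theta[k] * (if (is.null(tm$K)) Ztr else drop(tm$K %*% Ztr))
    nm <- if (!is.null(tm$Z)) colnames(tm$Z) else rownames(tm$K)
    if (!is.null(nm)) names(u[[k]]) <- nm
  }
  fitted <- drop(X %*% beta)
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    fitted <- fitted + (if (is.null(tm$Z)) u[[k]] else drop(tm$Z %*% u[[k]]))
  }
  structure(list(varcomps = theta, beta = beta, u = u, logl = st$ll,
                 trajectory = traj, converged = converged,
                 n_iter = length(traj) - 1, fitted = fitted,
                 kernels = lapply(terms, `[[`, "K"),
                 residual_groups = residual_groups),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("REML fit:", if (x$converged) "converged" else "NOT converged",
      "after", x$n_iter, "iterations; logL =", format(x$logl), "\n")
  cat("variance components:\n")
  print(round(x$varcomps, 6))
  invisible(x)
}

#' BLUP prediction for unobserved levels
#'
#' Predicts random effects of new levels from their kernel relationship to
#' the training levels: `u_new = K_cross (K_train + ridge I)^-1 u_train`.
#' Used for untested crosses and for cross-validation folds.
#'
#' @param fit an `lmm_fit`, or a named numeric vector of training BLUPs.
#' @param K_cross kernel rows of the new levels against the training
#'   levels (new x train).
#' @param K_train kernel among training levels; taken from `fit` when a
#'   fitted model with a stored kernel is supplied.
#' @param term which random term of `fit` to predict from (name or index).
#' @param ridge stabilising ridge added to `K_train` before inversion.
#' @return Named numeric vector of predictions for the new levels.
#' @export
blup_predict <- function(fit, K_cross, K_train = NULL, term = 1,
                         ridge = 1e-6) {
  if (inherits(fit, "lmm_fit")) {
    u <- fit$u[[term]]
    if (is.null(K_train)) K_train <- fit$kernels[[term]]
  } else u <- fit
  if (is.null(K_train)) stop("K_train required")
  K_cross <- rbind(K_cross)
  if (!is.null(colnames(K_cross)) && !is.null(names(u))) {
    if (!all(names(u) %in% colnames(K_cross)))
      stop("K_cross does not cover the training levels")
    K_cross <- K_cross[, names(u), drop = FALSE]
    if (!is.null(dimnames(K_train)))
      K_train <- K_train[names(u), names(u)]
    if (any(rownames(K_cross) %in% names(u)))
      stop("new levels overlap the training levels")
  }
  drop(K_cross %*% ridge_solve(K_train, u, ridge))
}

#' Stage-1 adjusted means from augmented-block trials
#'
#' Joint analysis of plot-level data across environments: fixed
#' environments, fixed checks, fixed entries (single crosses), fixed
#' check-by-environment interaction, random blocks nested in environments,
#' and a residual variance per environment (set `homogeneous = TRUE` for a
#' single residual). Environment effects enter with sum-to-zero contrasts,
#' so each entry's coefficient is directly its BLUE in the average
#' environment. Entries are fixed at this stage so that downstream genomic
#' models receive unshrunken adjusted means.
#'
#' @param trial data frame with columns `env`, `block`, `entry`,
#'   `is_check`, `value` (one plot per row), as produced by
#'   [simulate_trial_data()].
#' @param homogeneous single residual variance instead of per-environment.
#' @param ... passed to [reml_fit()].
#' @return A data frame of class `adjusted_means` (`entry`, `blue`),
#'   checks excluded, with the `lmm_fit` as attribute `fit`.
#' @export
stage1_blues <- function(trial, homogeneous = FALSE, ...) {
  need <- c("env", "block", "entry", "is_check", "value")
  if (!all(need %in% names(trial))) stop("trial data missing columns")
  trial$env <- factor(trial$env)
  trial$block <- factor(trial$block)
  entries <- sort(unique(trial$entry[!trial$is_check]))
  checks <- sort(unique(trial$entry[trial$is_check]))
  obs_per_entry <- table(trial$entry[!trial$is_check])
  if (any(obs_per_entry < 1)) stop("entry without observations")
  n <- nrow(trial)

  E <- matrix(0, n, length(entries), dimnames = list(NULL, entries))
  hy <- which(!trial$is_check)
  E[cbind(hy, match(trial$entry[hy], entries))] <- 1
  Xc <- NULL
  if (length(checks) > 0) {
    Cm <- matrix(0, n, length(checks),
                 dimnames = list(NULL, paste0("chk_", checks)))
    ck <- which(trial$is_check)
    Cm[cbind(ck, match(trial$entry[ck], checks))] <- 1
    Xc <- Cm
  }
  Q <- NULL
  if (nlevels(trial$env) > 1) {
    contr <- stats::contr.sum(nlevels(trial$env))
    Q <- contr[as.integer(trial$env), , drop = FALSE]
    colnames(Q) <- paste0("env", seq_len(ncol(Q)))
  }
  CQ <- NULL
  if (!is.null(Q) && length(checks) > 0) {
    CQ <- do.call(cbind, lapply(seq_along(checks), function(ci) {
      M <- Q * Xc[, ci]
      colnames(M) <- paste0("chk", ci, "_", colnames(Q))
      M
    }))
  }
  X <- cbind(E, Xc, Q, CQ)

  Zb <- matrix(0, n, nlevels(trial$block),
               dimnames = list(NULL, levels(trial$block)))
  Zb[cbind(seq_len(n), as.integer(trial$block))] <- 1
  fit <- reml_fit(trial$value, X = X,
                  random = list(block = list(Z = Zb)),
                  residual_groups = if (homogeneous) NULL else trial$env,
                  ...)
  out <- data.frame(entry = entries, blue = unname(fit$beta[entries]),
                    stringsAsFactors = FALSE)
  class(out) <- c("adjusted_means", "data.frame")
  attr(out, "fit") <- fit
  out
}
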