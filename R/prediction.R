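#' Additive-dominance GBLUP of single crosses
#'
#' Fits `y = 1 mu + Z a + Z d + e` on the adjusted means of single
#' crosses, with `a ~ N(0, s2_a Ga)` and `d ~ N(0, s2_d Gd)` built from
#' the in-silico hybrid marker codes, and reports broad- and narrow-sense
#' genomic heritabilities
#' `H2 = (s2_a + s2_d) / (s2_a + s2_d + s2_e)` and
#' `h2 = s2_a / (s2_a + s2_d + s2_e)`.
#'
#' @param means `adjusted_means` data frame or named numeric vector keyed
#'   by cross id.
#' @param Ga,Gd additive and dominance kernels over (at least) the crosses
#'   in `means`, from [additive_G()] and [dominance_G()].
#' @param ... passed to [reml_fit()].
#' @return Object of class `ad_gblup_fit`: `mu`, `a`, `d`, `gebv`
#'   (`a + d`, named by cross), `varcomps` (`additive`, `dominance`,
#'   `residual`), `H2`, `h2`, `logl`, `fit`.
#' @export
fit_ad_gblup <- function(means, Ga, Gd, ...) {
  y <- as_means_vector(means)
  ids <- names(y)
  if (!all(ids %in% rownames(Ga)) || !all(ids %in% rownames(Gd)))
    stop("kernels do not cover the crosses in the means")
  Ga <- unclass(Ga)[ids, ids]; Gd <- unclass(Gd)[ids, ids]
  fit <- reml_fit(y, random = list(a = list(K = Ga), d = list(K = Gd)), ...)
  vc <- setNames(fit$varcomps, c("additive", "dominance", "residual"))
  tot <- sum(vc)
  a <- setNames(fit$u$a, ids); d <- setNames(fit$u$d, ids)
  structure(list(mu = unname(fit$beta[1]), a = a, d = d, gebv = a + d,
                 varcomps = vc,
                 H2 = (vc[["additive"]] + vc[["dominance"]]) / tot,
                 h2 = vc[["additive"]] / tot,
                 logl = fit$logl, fit = fit, Ga = Ga, Gd = Gd),
            class = "ad_gblup_fit")
}

#' @export
print.ad_gblup_fit <- function(x, ...) {
  cat(sprintf("additive-dominance GBLUP: %d crosses\n", length(x$gebv)))
  print(round(x$varcomps, 6))
  cat(sprintf("H2 = %.3f, h2 = %.3f\n", x$H2, x$h2))
  invisible(x)
}

#' Replicated k-fold cross-validation of the AD-GBLUP model
#'
#' The CV-alpha scheme: in each replicate the crosses are partitioned at
#' random into `folds` near-equal folds (sizes differing by at most one);
#' each fold in turn is masked, the model is refit on the remainder, and
#' the masked crosses are predicted through the kernel rows
#' ([blup_predict()] for the additive and dominance terms, plus the
#' training intercept). Predictive ability is the Pearson correlation
#' between predicted and observed adjusted means over the validation set,
#' reported per fold and pooled per replicate.
#'
#' @param means adjusted means (data frame or named vector).
#' @param Ga,Gd kernels over the crosses.
#' @param folds,reps folds per replicate and number of replicates.
#' @param seed integer seed for the fold draws.
#' @param ... passed to [reml_fit()].
#' @return Object of class `cv_result`: `by_fold` (data frame with
#'   replicate, fold, n, pa), `by_rep` (replicate-pooled pa, plus H2 and
#'   h2 of the replicate's training fits averaged), `predictions`
#'   (replicate x cross matrix), `folds`, `reps`, `seed`.
#' @export
cv_alpha <- function(means, Ga, Gd, folds = 5, reps = 4, seed = 1, ...) {
  y <- as_means_vector(means)
  n <- length(y)
  if (n < folds) stop("fewer crosses than folds")
  if (floor(n / folds) < 3) stop("folds would contain fewer than 3 crosses")
  ids <- names(y)
  Ga <- unclass(Ga)[ids, ids]; Gd <- unclass(Gd)[ids, ids]
  by_fold <- list(); by_rep <- list()
  preds <- matrix(NA_real_, reps, n, dimnames = list(NULL, ids))
  assign_rec <- matrix(NA_integer_, reps, n, dimnames = list(NULL, ids))
  for (r in seq_len(reps)) {
    fold_of <- with_seed(child_seed(seed, r),
                         sample(rep_len(seq_len(folds), n)))
    assign_rec[r, ] <- fold_of
    H2s <- h2s <- numeric(folds)
    for (f in seq_len(folds)) {
      val <- which(fold_of == f); trn <- which(fold_of != f)
      fit <- fit_ad_gblup(y[trn], Ga[trn, trn], Gd[trn, trn], ...)
      a_hat <- blup_predict(fit$a, K_cross = Ga[val, trn, drop = FALSE],
                            K_train = Ga[trn, trn])
      d_hat <- blup_predict(fit$d, K_cross = Gd[val, trn, drop = FALSE],
                            K_train = Gd[trn, trn])
      preds[r, val] <- fit$mu + a_hat + d_hat
      H2s[f] <- fit$H2; h2s[f] <- fit$h2
      by_fold[[length(by_fold) + 1L]] <- data.frame(
        replicate = r, fold = f, n = length(val),
        pa = cor(preds[r, val], y[val]))
    }
    by_rep[[r]] <- data.frame(replicate = r,
                              pa = cor(preds[r, ], y),
                              H2 = mean(H2s), h2 = mean(h2s))
  }
  structure(list(by_fold = do.call(rbind, by_fold),
                 by_rep = do.call(rbind, by_rep),
                 predictions = preds, fold_assignment = assign_rec,
                 folds = folds, reps = reps, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV: %d folds x %d replicates\n", x$folds, x$reps))
  cat(sprintf("predictive ability (per-replicate pooled): mean %.3f, range %.3f..%.3f\n",
              mean(x$by_rep$pa), min(x$by_rep$pa), max(x$by_rep$pa)))
  invisible(x)
}

#' Prediction accuracy from predictive ability and heritability
#'
#' Scales each replicate's predictive ability by the square root of the
#' broad-sense genomic heritability, `accuracy = pa / sqrt(H2)`, clamped
#' to `[-1, 1]`.
#'
#' @param cv a `cv_result`.
#' @param fit an `ad_gblup_fit` on the full data providing `H2` (or a
#'   single numeric `H2` value).
#' @return The `by_rep` data frame with an `accuracy` column added.
#' @export
prediction_metrics <- function(cv, fit) {
  H2 <- if (inherits(fit, "ad_gblup_fit")) fit$H2 else as.numeric(fit)
  if (!is.finite(H2) || H2 <= 0) stop("heritability must be positive")
  out <- cv$by_rep
  out$accuracy <- pmax(-1, pmin(1, out$pa / sqrt(H2)))
  out
}

#' Coincidence of phenotypic and genomic selection
#'
#' For each selection intensity (percent), selects the top
#' `ceiling(s * n / 100)` crosses once by observed adjusted means and once
#' by GEBV, and reports the percentage of shared selections. With
#' `direction = "lower"` the best crosses are the smallest values (e.g.
#' plant height).
#'
#' @param means adjusted means (data frame or named vector).
#' @param gebvs named vector of genomic estimated total genetic values
#'   over the same crosses.
#' @param intensities selection intensities in percent.
#' @param direction `"higher"` (default) or `"lower"` is better.
#' @return Data frame of class `coincidence_table`: `intensity`,
#'   `n_selected`, `coincidence` (percent; `NA` when the selected set
#'   would be empty).
#' @export
selection_coincidence <- function(means, gebvs,
                                  intensities = c(1, 10, 20, 30, 40),
                                  direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  y <- as_means_vector(means)
  if (!setequal(names(y), names(gebvs)))
    stop("means and GEBVs cover different crosses")
  g <- gebvs[names(y)]
  sgn <- if (direction == "higher") -1 else 1
  n <- length(y)
  out <- lapply(intensities, function(s) {
    k <- ceiling(s * n / 100)
    if (k < 1) return(data.frame(intensity = s, n_selected = 0L,
                                 coincidence = NA_real_))
    top_y <- names(sort(sgn * y))[seq_len(k)]
    top_g <- names(sort(sgn * g))[seq_len(k)]
    data.frame(intensity = s, n_selected = k,
               coincidence = 100 * length(intersect(top_y, top_g)) / k)
  })
  out <- do.call(rbind, out)
  class(out) <- c("coincidence_table", "data.frame")
  out
}
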