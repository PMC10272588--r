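#' Configuration of the synthetic breeding scenario
#'
#' Bundles every knob of the simulated world: a structured panel of fully
#' inbred lines, a diallel among a subset of parents, marker effects, and
#' multi-environment augmented-block trials. Defaults emulate a tropical
#' maize diversity panel: 330 lines in 6 subpopulations, a 45-parent
#' diallel with 751 of the 990 possible crosses realised, and 8
#' environments with blocks of 16 entries plus 2 replicated checks.
#'
#' @param n_lines number of inbred lines in the panel.
#' @param n_markers number of biallelic markers.
#' @param n_pools number of subpopulations.
#' @param divergence Fst-like differentiation between subpopulations, in
#'   `[0, 1)`. 0 means no structure; 0.15 (default) is moderate
#'   differentiation typical of breeding germplasm split by origin.
#' @param n_diallel_parents number of lines entering the diallel.
#' @param cross_fraction fraction of the possible crosses actually made, in
#'   `(0, 1]`.
#' @param var_additive,var_dominance,var_residual variance components (trait
#'   units squared) of the additive and dominance genetic effects and of the
#'   residual on hybrid adjusted means.
#' @param var_env,var_block variances of environment main effects and of
#'   blocks nested in environments in the plot-level trial model.
#' @param n_envs,block_size,n_checks trial layout: number of environments,
#'   single crosses per block, and replicated checks per block.
#' @param directional_dominance if `TRUE` (default) dominance effects are
#'   drawn all-positive (half-normal), the directional dominance that makes
#'   heterozygotes superior and between-pool crosses systematically more
#'   heterotic — the regime in which SCA-based heterotic grouping is
#'   meaningful. `FALSE` gives zero-mean (non-directional) dominance.
#' @param n_chrom chromosomes over which markers are spread evenly.
#' @param seed integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 330, n_markers = 12000, n_pools = 6,
                       divergence = 0.15, n_diallel_parents = 45,
                       cross_fraction = 751 / 990,
                       var_additive = 1, var_dominance = 0.5,
                       var_residual = 1, var_env = 1, var_block = 0.25,
                       n_envs = 8, block_size = 16, n_checks = 2,
                       n_chrom = 10, directional_dominance = TRUE,
                       seed = 1) {
  cfg <- list(n_lines = n_lines, n_markers = n_markers, n_pools = n_pools,
              divergence = divergence,
              n_diallel_parents = n_diallel_parents,
              cross_fraction = cross_fraction,
              var_additive = var_additive, var_dominance = var_dominance,
              var_residual = var_residual, var_env = var_env,
              var_block = var_block, n_envs = n_envs,
              block_size = block_size, n_checks = n_checks,
              n_chrom = n_chrom,
              directional_dominance = isTRUE(directional_dominance),
              seed = seed)
  counts <- c("n_lines", "n_markers", "n_pools", "n_diallel_parents",
              "n_envs", "block_size", "n_checks", "n_chrom")
  for (nm in counts)
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop(sprintf("%s must be a positive integer", nm))
  vars <- c("var_additive", "var_dominance", "var_residual", "var_env",
            "var_block")
  for (nm in vars)
    if (cfg[[nm]] < 0) stop(sprintf("%s must be non-negative", nm))
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  if (cross_fraction <= 0 || cross_fraction > 1)
    stop("cross_fraction must lie in (0, 1]")
  if (n_diallel_parents > n_lines)
    stop("n_diallel_parents cannot exceed n_lines")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured panel of inbred lines
#'
#' Generates fully homozygous genotypes (dosages 0/2) under a two-level
#' allele-frequency model in the Balding-Nichols style: each marker draws
#' an ancestral frequency from Uniform(0.1, 0.9), each subpopulation draws
#' its own frequency from a Beta distribution centred on the ancestral one
#' with spread controlled by `divergence` (the Fst-like parameter), and a
#' line's allele is a Bernoulli draw at its subpopulation's frequency,
#' doubled to a homozygous dosage. Markers monomorphic across the whole
#' panel are redrawn. Markers are assigned evenly to `n_chrom` chromosomes
#' with consecutive 1-based positions.
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (list with `pool_labels`, the subpopulation id per line, and
#'   `pool_freqs`, the subpopulation allele-frequency matrix).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_lines; m <- config$n_markers; K <- config$n_pools
    F <- config$divergence
    pools <- sort(rep_len(seq_len(K), n))
    draw <- function(mm) {
      anc <- runif(mm, 0.1, 0.9)
      if (F == 0) {
        pf <- matrix(rep(anc, each = K), nrow = K)
      } else {
        a <- anc * (1 - F) / F
        b <- (1 - anc) * (1 - F) / F
        pf <- matrix(rbeta(K * mm, rep(a, each = K), rep(b, each = K)),
                     nrow = K)
      }
      dos <- matrix(0, n, mm)
      for (k in seq_len(K)) {
        rows <- which(pools == k)
        dos[rows, ] <- 2 * matrix(
          rbinom(length(rows) * mm, 1L, rep(pf[k, ], each = length(rows))),
          nrow = length(rows))
      }
      list(dos = dos, pf = pf)
    }
    d <- draw(m)
    for (it in 1:100) {
      mono <- which(apply(d$dos, 2, function(x) length(unique(x)) == 1))
      if (length(mono) == 0) break
      redo <- draw(length(mono))
      d$dos[, mono] <- redo$dos
      d$pf[, mono] <- redo$pf
    }
    if (any(apply(d$dos, 2, function(x) length(unique(x)) == 1)))
      stop("could not generate polymorphic markers; check configuration")
    rownames(d$dos) <- sprintf("L%03d", seq_len(n))
    colnames(d$dos) <- sprintf("M%05d", seq_len(m))
    chrom <- as.character(rep(seq_len(config$n_chrom),
                              length.out = m)[order(rep(seq_len(config$n_chrom),
                                                        length.out = m))])
    pos <- integer(m)
    for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc))
    G <- genotype_matrix(d$dos, chrom = chrom, pos = pos)
    list(genotypes = G,
         truth = list(pool_labels = setNames(pools, rownames(d$dos)),
                      pool_freqs = d$pf))
  })
}

#' Simulate platform-specific views of one panel
#'
#' Emulates genotyping the same lines on several marker platforms of
#' different density and ascertainment (e.g. a fixed SNP array versus two
#' GBS marker sets). Each view is a marker subset of the input panel with
#' missing calls injected completely at random; `"biased"` ascertainment
#' samples markers with probability proportional to their minor allele
#' frequency in a reference subset of lines, mimicking array design on a
#' discovery panel, while `"random"` samples uniformly.
#'
#' @param G a [genotype_matrix()] of the full panel.
#' @param panels list of panel descriptors; each a list with elements
#'   `size` (marker count), `ascertainment` (`"random"` or `"biased"`),
#'   `missing_rate` in `[0, 1)`, and optional `error_rate` (homozygote
#'   flips, default 0) and `label`.
#' @param seed integer seed.
#' @param ref_fraction fraction of lines forming the ascertainment
#'   reference subset for `"biased"` panels.
#' @return A named list of `GenotypeMatrix` views.
#' @export
simulate_platform_views <- function(G, panels, seed = 1, ref_fraction = 0.2) {
  stopifnot(inherits(G, "GenotypeMatrix"), length(panels) > 0)
  m <- ncol(G$dosages); n <- nrow(G$dosages)
  with_seed(seed, {
    out <- list()
    for (i in seq_along(panels)) {
      p <- panels[[i]]
      if (is.null(p$size) || p$size < 1) stop("empty panel request")
      if (p$size > m) stop("panel size exceeds available markers")
      mode <- if (is.null(p$ascertainment)) "random" else p$ascertainment
      miss <- if (is.null(p$missing_rate)) 0 else p$missing_rate
      err <- if (is.null(p$error_rate)) 0 else p$error_rate
      if (mode == "biased") {
        ref <- sample(n, max(2, ceiling(ref_fraction * n)))
        pr <- colMeans(G$dosages[ref, , drop = FALSE], na.rm = TRUE) / 2
        w <- pmin(pr, 1 - pr) + 1e-6
        sel <- sort(sample.int(m, p$size, prob = w))
      } else {
        sel <- sort(sample.int(m, p$size))
      }
      V <- subset_markers(G, sel)
      if (err > 0) {
        flip <- which(runif(length(V$dosages)) < err & V$dosages != 1)
        V$dosages[flip] <- 2 - V$dosages[flip]
      }
      if (miss > 0)
        V$dosages[runif(length(V$dosages)) < miss] <- NA
      label <- if (is.null(p$label)) paste0("panel", i) else p$label
      out[[label]] <- V
    }
    out
  })
}

#' Simulate additive and dominance marker effects
#'
#' Draws per-marker additive and dominance effects i.i.d. normal and
#' rescales them to match the configured variances. Additive effects are
#' scaled so the realized variance of the additive values over the
#' design's hybrids equals `var_additive` exactly. Dominance effects are
#' scaled on the model scale — the implied covariance of the dominance
#' values is `var_dominance * Gd` — because with the 0/1 heterozygosity
#' coding and the standard `4 * sum (p q)^2` denominator the realized
#' dominance variance exceeds the variance component by the ratio
#' `sum h(1-h) / sum (2 p q)^2` (about 1.4 for intermediate frequencies);
#' variance-component recovery is only well defined on the model scale.
#' Under directional dominance (the default) the positive effect mean adds
#' the heterosis variance carried by per-cross heterozygosity differences
#' on top of `var_dominance`. True hybrid genetic values are returned for
#' every cross in the design.
#'
#' @param G a homozygous parental `GenotypeMatrix` (post-QC).
#' @param config a [sim_config()]; supplies the variances and (through its
#'   seed) the effect draws.
#' @param design optional [hybrid_design()]; defaults to a diallel among
#'   the first `n_diallel_parents` lines with `cross_fraction` of the
#'   possible crosses realised.
#' @return A list (`sim_truth`) with `alpha`, `delta` (per-marker effects),
#'   `design`, `true_hybrid_values` (named by cross id), and
#'   `true_varcomps`.
#' @export
simulate_genetic_effects <- function(G, config, design = NULL) {
  stopifnot(inherits(G, "GenotypeMatrix"), inherits(config, "sim_config"))
  d <- G$dosages
  if (all(apply(d, 2, function(x) length(unique(x))) == 1))
    stop("all markers monomorphic; cannot assign genetic effects")
  if (is.null(design))
    design <- diallel_design(rownames(d)[seq_len(config$n_diallel_parents)],
                             cross_fraction = config$cross_fraction,
                             seed = child_seed(config$seed, 1))
  W <- build_hybrid_genotypes(G, design)
  p <- colMeans(W$W_A) / 2
  sum_pq <- sum(p * (1 - p))
  sum_pq2 <- sum((p * (1 - p))^2)
  m <- ncol(d)
  with_seed(child_seed(config$seed, 2), {
    alpha <- rnorm(m)
    delta <- if (config$directional_dominance) abs(rnorm(m)) else rnorm(m)
  })
  # additive effects: rescale so the realized additive variance over the
  # design's hybrids equals var_additive exactly
  if (config$var_additive > 0 && sum_pq > 0) {
    va <- stats::var(drop(W$W_A %*% alpha))
    alpha <- alpha * sqrt(config$var_additive / va)
  } else alpha <- rep(0, m)
  if (config$var_dominance > 0 && sum_pq2 > 0) {
    tau_d <- sqrt(config$var_dominance / (4 * sum_pq2))
    # directional: preserve the positive mean, scale the spread to tau_d
    delta <- if (config$directional_dominance)
      delta / stats::sd(delta) * tau_d
    else rnorm_rescale(delta, tau_d)
  } else delta <- rep(0, m)
  names(alpha) <- names(delta) <- colnames(d)
  tv <- drop(W$W_A %*% alpha + W$W_D %*% delta)
  names(tv) <- design$cross
  structure(list(alpha = alpha, delta = delta, design = design,
                 true_hybrid_values = tv,
                 true_varcomps = c(additive = config$var_additive,
                                   dominance = config$var_dominance,
                                   residual = config$var_residual)),
            class = "sim_truth")
}

# Standardize a draw to mean 0 / sd `s` so the implied variance component is
# exact rather than subject to sampling noise in the effect draws.
rnorm_rescale <- function(x, s) {
  (x - mean(x)) / stats::sd(x) * s
}

#' True genetic values for arbitrary crosses
#'
#' Evaluates the generating marker-effect model for any set of crosses of
#' the simulated parents — including crosses absent from the design used
#' when effects were drawn.
#'
#' @param G parental `GenotypeMatrix`.
#' @param truth a `sim_truth` from [simulate_genetic_effects()].
#' @param design a [hybrid_design()].
#' @return Named numeric vector of true genetic values.
#' @export
true_cross_values <- function(G, truth, design) {
  W <- build_hybrid_genotypes(G, design)
  tv <- drop(W$W_A %*% truth$alpha + W$W_D %*% truth$delta)
  setNames(tv, design$cross)
}

#' Simulate multi-environment augmented-block trial data
#'
#' Lays the hybrids of a design out in augmented blocks — `block_size`
#' unreplicated single crosses plus `n_checks` replicated checks per block
#' — in each of `n_envs` environments, and generates plot values as
#' true hybrid value + environment effect + block effect + residual. The
#' residual variance is heterogeneous across environments (the configured
#' `var_residual` scaled by a Uniform(0.5, 1.5) factor per environment).
#' Every entry appears once per environment; the last block of an
#' environment may be short. Checks are not genotyped entries: they carry
#' fixed true values placed at the mean of the hybrid values plus
#' (j - (n_checks+1)/2)/2 hybrid standard deviations for check j.
#'
#' @param hybrid_values named numeric vector of true hybrid genetic values.
#' @param config a [sim_config()].
#' @param seed optional seed; defaults to `config$seed` offset.
#' @return A data frame (`env`, `block`, `entry`, `is_check`, `value`) with
#'   attribute `residual_sd` (per-environment residual standard deviations).
#' @export
simulate_trial_data <- function(hybrid_values, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(hybrid_values) > 0,
            !is.null(names(hybrid_values)))
  if (config$n_envs < 1) stop("at least one environment required")
  if (is.null(seed)) seed <- child_seed(config$seed, 3)
  n_h <- length(hybrid_values)
  mu_h <- mean(hybrid_values); sd_h <- stats::sd(hybrid_values)
  if (!is.finite(sd_h) || sd_h == 0) sd_h <- 1
  checks <- setNames(
    mu_h + ((seq_len(config$n_checks)) - (config$n_checks + 1) / 2) / 2 * sd_h,
    sprintf("CHK%d", seq_len(config$n_checks)))
  with_seed(seed, {
    res_sd <- sqrt(config$var_residual * runif(config$n_envs, 0.5, 1.5))
    env_eff <- rnorm(config$n_envs, 0, sqrt(config$var_env))
    rows <- vector("list", config$n_envs)
    for (e in seq_len(config$n_envs)) {
      ord <- sample(names(hybrid_values))
      n_blocks <- ceiling(n_h / config$block_size)
      blk <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(n_h)]
      is_check <- c(rep(FALSE, n_h), rep(TRUE, n_blocks * config$n_checks))
      entries <- c(ord, rep(names(checks), times = n_blocks))
      blocks <- c(blk, rep(seq_len(n_blocks), each = config$n_checks))
      blk_eff <- rnorm(n_blocks, 0, sqrt(config$var_block))
      g <- ifelse(is_check, checks[entries], hybrid_values[entries])
      val <- g + env_eff[e] + blk_eff[blocks] +
        rnorm(length(g), 0, res_sd[e])
      rows[[e]] <- data.frame(env = sprintf("E%d", e),
                              block = sprintf("E%d_B%d", e, blocks),
                              entry = entries, is_check = is_check,
                              value = val, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "residual_sd") <- res_sd
    attr(out, "check_values") <- checks
    out
  })
}
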