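#' Run the full heterotic-pool analysis pipeline
#'
#' Orchestrates the whole workflow for one or more marker panels of the
#' same parental lines: QC (structure and prediction branches), population
#' structure (Rogers distance, PCoA, k-means), parental kernel, GCA/SCA
#' diallel fit on the adjusted means, heterotic partition and testers,
#' NCII enumeration, additive-dominance GBLUP with cross-validation and
#' selection coincidence — then, when at least two panels are supplied,
#' all pairwise concordance statistics (Mantel r on distance matrices,
#' Kendall tau on cluster labels, eigenvector R-squared, partition
#' correlation, tester coincidence, predictive-ability comparison). Every
#' intermediate is written as a delimited table under `out_dir` together
#' with a manifest, and the run is reproducible under the master seed
#' (per-stage seeds are derived deterministically from it).
#'
#' @param config a list (see Details) or the path of a `key = value` text
#'   file parsed by [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#'
#' @details Config elements: `panels` — named list of genotype inputs
#'   (file paths of dosage tables, or `GenotypeMatrix` objects); `means` —
#'   adjusted means (data frame `entry`/`blue`, named vector, or file
#'   path) keyed by cross id `"parentA:parentB"`; alternatively `trial` —
#'   plot-level data passed through [stage1_blues()]. Optional:
#'   `min_call_rate` (0.90), `r2_max` (0.99), `maf_min` (0.05), `k_range`
#'   (1:8), `n_coords` (3, PCoA axes fed to k-means), `n_eig` (10),
#'   `n_perm` (1000), `k_groups` (2), `tester_rule` ("mean_cross"),
#'   `folds` (5), `reps` (4), `intensities` (1,10,20,30,40), `direction`
#'   ("higher"), `seed` (1).
#' @return Invisibly, a list with the per-panel results and (if >= 2
#'   panels) the concordance rows; all artifacts are on disk in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- read_pipeline_config(config)
  cfg <- pipeline_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  put <- function(x, name, panel = NULL) {
    dir <- if (is.null(panel)) out_dir else file.path(out_dir, panel)
    dir.create(dir, showWarnings = FALSE)
    path <- file.path(dir, paste0(name, ".tsv"))
    if (is.matrix(x))
      x <- data.frame(id = rownames(x), x, check.names = FALSE)
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
    manifest <<- c(manifest, path)
    path
  }

  means <- pipeline_means(cfg, log_line, put)
  design <- design_from_cross_ids(names(means))

  panels <- cfg$panels
  if (is.null(names(panels)))
    names(panels) <- paste0("panel", seq_along(panels))
  results <- list()
  for (pn in names(panels)) {
    res <- tryCatch(
      run_panel(panels[[pn]], pn, means, design, cfg, log_line, put),
      error = function(e) stop(sprintf("stage failure in panel '%s': %s",
                                       pn, conditionMessage(e)), call. = FALSE))
    results[[pn]] <- res
  }

  if (length(results) >= 2) {
    log_line("computing pairwise concordance statistics")
    rows <- list()
    cmb <- utils::combn(names(results), 2)
    for (ci in seq_len(ncol(cmb))) {
      a <- results[[cmb[1, ci]]]; b <- results[[cmb[2, ci]]]
      mt <- mantel_test(a$distance, b$distance, n_perm = cfg$n_perm,
                        seed = child_seed(cfg$seed, 40 + ci))
      kc <- kendall_coincidence(a$clusters$labels, b$clusters$labels)
      r2 <- eigenvector_r2(a$pcoa, b$pcoa, n = cfg$n_eig)
      pc <- partition_concordance(a$partition, b$partition)
      rows[[ci]] <- data.frame(
        panel_a = cmb[1, ci], panel_b = cmb[2, ci],
        mantel_r = mt$r, mantel_p = mt$p,
        kendall_tau = kc$tau, kendall_p = kc$p,
        r2_11 = r2[1, 1],
        partition_r = pc$r, tester_coincidence = pc$tester_coincidence,
        pa_a = mean(a$cv$by_rep$pa), pa_b = mean(b$cv$by_rep$pa))
      put(data.frame(id = rownames(r2), r2, check.names = FALSE),
          sprintf("eigenvector_r2_%s_vs_%s", cmb[1, ci], cmb[2, ci]))
    }
    concordance <- do.call(rbind, rows)
    put(concordance, "concordance")
  } else concordance <- NULL

  writeLines(sub(paste0(out_dir, "/"), "", manifest, fixed = TRUE),
             file.path(out_dir, "manifest.txt"))
  log_line("pipeline complete: %d panels, %d artifacts",
           length(results), length(manifest))
  invisible(list(panels = results, concordance = concordance,
                 means = means, out_dir = out_dir))
}

pipeline_defaults <- function(cfg) {
  defs <- list(min_call_rate = 0.90, r2_max = 0.99, maf_min = 0.05,
               k_range = 1:8, n_coords = 3, n_eig = 10, n_perm = 1000,
               k_groups = 2, tester_rule = "mean_cross", folds = 5,
               reps = 4, intensities = c(1, 10, 20, 30, 40),
               direction = "higher", seed = 1)
  for (nm in names(defs)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defs[[nm]]
  if (is.null(cfg$panels) || length(cfg$panels) == 0)
    stop("config must provide at least one genotype panel")
  if (is.null(cfg$means) && is.null(cfg$trial))
    stop("config must provide adjusted means or plot-level trial data")
  cfg
}

pipeline_means <- function(cfg, log_line, put) {
  if (!is.null(cfg$means)) {
    m <- cfg$means
    if (is.character(m) && length(m) == 1)
      m <- data.table::fread(m, data.table = FALSE)
    means <- as_means_vector(m)
  } else {
    trial <- cfg$trial
    if (is.character(trial) && length(trial) == 1)
      trial <- data.table::fread(trial, data.table = FALSE)
    log_line("stage 1: adjusted means from %d plots", nrow(trial))
    am <- stage1_blues(trial)
    means <- as_means_vector(am)
  }
  put(data.frame(entry = names(means), blue = unname(means)), "adjusted_means")
  means
}

design_from_cross_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("cross ids must be 'parentA:parentB'")
  hybrid_design(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
}

run_panel <- function(panel, pn, means, design, cfg, log_line, put) {
  G <- if (inherits(panel, "GenotypeMatrix")) panel
  else read_genotypes(panel, format = "dosage")
  log_line("[%s] %d lines x %d markers", pn, nrow(G$dosages), ncol(G$dosages))

  qc1 <- qc_parent_panel(G, min_call_rate = cfg$min_call_rate,
                         r2_max = cfg$r2_max)
  put(qc1$report, "qc_parent_report", pn)

  D <- rogers_distance(qc1$genotypes)
  put(D, "rogers_distance", pn)
  pc <- pcoa(D, k = max(cfg$n_eig, cfg$n_coords))
  put(pc$vectors, "pcoa_coordinates", pn)
  cl <- kmeans_partition(pc$vectors[, seq_len(cfg$n_coords), drop = FALSE],
                         k_range = cfg$k_range,
                         seed = child_seed(cfg$seed, 10))
  put(data.frame(line = names(cl$labels), cluster = unname(cl$labels)),
      "clusters", pn)
  log_line("[%s] structure: chose k = %d clusters", pn, cl$k)

  qc2 <- qc_hybrid_panel(qc1$genotypes, design = design,
                         maf_min = cfg$maf_min)
  put(qc2$report, "qc_hybrid_report", pn)
  Gh <- qc2$genotypes
  parents <- unique(c(design$parent_a, design$parent_b))
  Gp <- gp_matrix(subset_lines(Gh, parents))

  dfit <- fit_diallel(means, design, Gp)
  put(data.frame(parent = names(dfit$gca), gca = unname(dfit$gca)),
      "gca", pn)
  put(data.frame(component = names(dfit$varcomps),
                 variance = unname(dfit$varcomps)), "diallel_varcomps", pn)
  S <- complete_sca_matrix(dfit, Gp)
  put(unclass(S), "sca_matrix", pn)
  part <- heterotic_partition(S, k = cfg$k_groups,
                              seed = child_seed(cfg$seed, 20))
  part <- choose_testers(part, dfit, S, rule = cfg$tester_rule)
  put(part, "heterotic_partition", pn)
  log_line("[%s] testers: %s", pn,
           paste(part$parent[part$is_tester], collapse = ", "))
  ncii <- enumerate_ncii(part, observed_design = design)
  put(ncii, "ncii_design", pn)

  W <- build_hybrid_genotypes(Gh, design)
  p_freq <- colMeans(W$W_A) / 2
  Ga <- additive_G(W$W_A, p = p_freq)
  Gd <- dominance_G(W$W_D, p = p_freq)
  gfit <- fit_ad_gblup(means, Ga, Gd)
  put(data.frame(component = c(names(gfit$varcomps), "H2", "h2"),
                 value = c(unname(gfit$varcomps), gfit$H2, gfit$h2)),
      "adgblup_varcomps", pn)
  cv <- cv_alpha(means, Ga, Gd, folds = cfg$folds, reps = cfg$reps,
                 seed = child_seed(cfg$seed, 30))
  metrics <- prediction_metrics(cv, gfit)
  put(metrics, "cv_metrics", pn)
  coin <- selection_coincidence(means, gfit$gebv,
                                intensities = cfg$intensities,
                                direction = cfg$direction)
  put(coin, "selection_coincidence", pn)
  log_line("[%s] mean predictive ability %.3f (H2 = %.2f)",
           pn, mean(metrics$pa), gfit$H2)

  list(qc_parent = qc1$report, qc_hybrid = qc2$report, distance = D,
       pcoa = pc, clusters = cl, Gp = Gp, diallel = dfit, sca = S,
       partition = part, ncii = ncii, adgblup = gfit, cv = cv,
       metrics = metrics, coincidence = coin)
}

# Subset lines (rows) of a GenotypeMatrix.
subset_lines <- function(G, lines) {
  genotype_matrix(G$dosages[lines, , drop = FALSE], chrom = G$chrom,
                  pos = G$pos, biallelic = G$biallelic)
}

#' Read a pipeline configuration file
#'
#' Parses a plain `key = value` text file (one pair per line, `#`
#' comments). Comma-separated values become vectors; `panels` may be given
#' as `panels = label1:path1, label2:path2`.
#'
#' @param path config file path.
#' @return A config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (key == "panels") {
      pv <- strsplit(parts, ":", fixed = TRUE)
      cfg$panels <- setNames(lapply(pv, `[[`, 2), vapply(pv, `[[`, "", 1))
    } else {
      num <- suppressWarnings(as.numeric(parts))
      cfg[[key]] <- if (anyNA(num)) parts else num
    }
  }
  cfg
}

#' Assemble the cross-panel concordance report of a finished run
#'
#' Reads the artifacts a multi-panel [run_pipeline()] call left on disk
#' and returns the pairwise concordance table (Mantel r and p on Rogers
#' distance matrices, Kendall tau on cluster memberships, leading
#' eigenvector R-squared, heterotic-partition correlation, tester
#' coincidence, and the two panels' mean predictive abilities). No new
#' statistics are computed here.
#'
#' @param out_dir directory of a completed multi-panel run.
#' @return The concordance data frame.
#' @export
concordance_report <- function(out_dir) {
  path <- file.path(out_dir, "concordance.tsv")
  if (!file.exists(path))
    stop("no concordance table found; was the run single-panel?")
  data.table::fread(path, data.table = FALSE)
}
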