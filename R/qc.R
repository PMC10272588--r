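#' Quality-control cascades for marker panels
#'
#' Two sequential filter cascades with exact, auditable per-step counts.
#' `qc_parent_panel()` is the structure branch applied to the raw parental
#' matrix: call-rate filter, biallelic filter, mode imputation, and LD
#' pruning. `qc_hybrid_panel()` is the prediction branch applied to the
#' parental matrix that feeds in-silico hybrid construction: removal of
#' markers heterozygous in any line, removal of duplicated marker content
#' across chromosomes, and a minor-allele-frequency filter computed on the
#' derived single-cross matrix.
#'
#' Both return the filtered matrix together with a `QCReport` data frame in
#' which `markers_out = markers_in - markers_removed` at every step and
#' consecutive steps chain.
#'
#' @param G a [genotype_matrix()]; for `qc_hybrid_panel()` it should
#'   already have passed `qc_parent_panel()` (no missing values).
#' @param min_call_rate markers observed in less than this fraction of
#'   lines are removed (boundary kept: call rate exactly at the threshold
#'   is retained).
#' @param r2_max LD pruning threshold: for each marker pair with squared
#'   allele-frequency correlation strictly greater than `r2_max`, the later
#'   marker in input order is removed. Pruning is restricted to pairs on
#'   the same chromosome when coordinates are present, otherwise global.
#' @return A list with elements `genotypes` (`GenotypeMatrix`) and `report`
#'   (data frame: step, markers_in, markers_removed, markers_out).
#' @examples
#' sim <- simulate_parents(sim_config(n_lines = 40, n_markers = 200, seed = 7))
#' qc <- qc_parent_panel(sim$genotypes)
#' qc$report
#' @export
qc_parent_panel <- function(G, min_call_rate = 0.90, r2_max = 0.99) {
  stopifnot(inherits(G, "GenotypeMatrix"),
            min_call_rate > 0, min_call_rate <= 1, r2_max > 0)
  report <- list()
  note <- function(step, n_in, keep) {
    report[[length(report) + 1L]] <<- data.frame(
      step = step, markers_in = n_in, markers_removed = n_in - sum(keep),
      markers_out = sum(keep))
  }

  # 1. call rate
  cr <- colMeans(!is.na(G$dosages))
  keep <- cr >= min_call_rate
  note("call_rate", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  # 2. biallelic
  keep <- G$biallelic
  note("biallelic", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  # 3. imputation (no removals; recorded for audit)
  G <- impute_missing(G)
  note("imputation", ncol(G$dosages), rep(TRUE, ncol(G$dosages)))

  # 4. LD pruning
  keep <- ld_prune_keep(G$dosages, G$chrom, r2_max)
  note("ld_prune", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  if (ncol(G$dosages) == 0)
    stop("qc_parent_panel removed every marker")
  out <- list(genotypes = G, report = do.call(rbind, report))
  attr(out$report, "parameters") <-
    list(min_call_rate = min_call_rate, r2_max = r2_max)
  out
}

# Greedy sequential LD prune: scan markers in input order, drop any marker
# whose r^2 with an already-kept marker (same chromosome) exceeds r2_max.
ld_prune_keep <- function(d, chrom, r2_max) {
  m <- ncol(d)
  keep <- rep(TRUE, m)
  groups <- if (is.null(chrom)) list(seq_len(m)) else split(seq_len(m), chrom)
  for (idx in groups) {
    if (length(idx) < 2) next
    cc <- suppressWarnings(cor(d[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0  # monomorphic columns cannot be in LD
    r2 <- cc^2
    kept <- logical(length(idx))
    for (j in seq_along(idx)) {
      if (j == 1L || !any(r2[j, kept] > r2_max)) kept[j] <- TRUE
    }
    keep[idx] <- kept
  }
  keep
}

#' @rdname qc_parent_panel
#' @param design optional [hybrid_design()] giving the single crosses whose
#'   in-silico genotypes define the allele frequencies for the MAF filter;
#'   by default all pairwise crosses among the panel's lines.
#' @param maf_min markers with minor allele frequency strictly below this
#'   value among the crosses are removed (frequency exactly at the
#'   threshold is retained).
#' @export
qc_hybrid_panel <- function(G, design = NULL, maf_min = 0.05) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  if (anyNA(G$dosages))
    stop("qc_hybrid_panel expects an imputed matrix; run qc_parent_panel first")
  report <- list()
  note <- function(step, n_in, keep) {
    report[[length(report) + 1L]] <<- data.frame(
      step = step, markers_in = n_in, markers_removed = n_in - sum(keep),
      markers_out = sum(keep))
  }

  # 1. heterozygous in at least one line
  keep <- colSums(G$dosages == 1) == 0
  note("heterozygous", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  # 2. duplicated marker content across chromosomes (keep first occurrence)
  keep <- !duplicated_across_chrom(G$dosages, G$chrom)
  note("duplicate_across_chrom", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  # 3. MAF on the derived single-cross matrix
  if (is.null(design)) {
    ids <- rownames(G$dosages)
    pairs <- utils::combn(ids, 2)
    design <- hybrid_design(pairs[1, ], pairs[2, ])
  }
  W <- build_hybrid_genotypes(G, design)
  p <- colMeans(W$W_A) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  note("maf", ncol(G$dosages), keep)
  G <- subset_markers(G, keep)

  if (ncol(G$dosages) == 0)
    stop("qc_hybrid_panel removed every marker")
  out <- list(genotypes = G, report = do.call(rbind, report))
  attr(out$report, "parameters") <- list(maf_min = maf_min)
  out
}

# TRUE for a column identical in content to an earlier column that sits on a
# different chromosome (multicollinearity from mis-mapped duplicated loci).
duplicated_across_chrom <- function(d, chrom) {
  m <- ncol(d)
  if (is.null(chrom)) chrom <- rep("1", m)
  key <- apply(d, 2, paste, collapse = ",")
  dup <- logical(m)
  seen <- list()  # key -> chromosomes already carrying it
  for (j in seq_len(m)) {
    prev <- seen[[key[j]]]
    if (!is.null(prev) && any(prev != chrom[j])) {
      dup[j] <- TRUE
    } else {
      seen[[key[j]]] <- c(prev, chrom[j])
    }
  }
  dup
}
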