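#' Genotype matrix of inbred lines
#'
#' Container for an allele-dosage matrix (lines in rows, markers in columns)
#' with optional marker coordinates. Dosages count copies of the second
#' (alternate) allele, so fully inbred lines carry 0 or 2, heterozygous
#' calls 1, and missing calls `NA`.
#'
#' @param dosages numeric matrix, lines x markers, values in `{0, 1, 2, NA}`.
#'   Row names are line ids, column names marker ids; both are required and
#'   must be unique.
#' @param chrom optional character/integer vector of chromosome labels, one
#'   per marker.
#' @param pos optional integer vector of 1-based marker positions.
#' @param biallelic optional logical vector flagging markers confirmed
#'   biallelic at read time; defaults to all `TRUE`.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosages`, `chrom`, `pos`, `biallelic`.
#' @export
genotype_matrix <- function(dosages, chrom = NULL, pos = NULL, biallelic = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) || (ncol(dosages) > 0 && is.null(colnames(dosages))))
    stop("dosage matrix needs line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(dosages))) stop("duplicated line ids")
  if (anyDuplicated(colnames(dosages))) stop("duplicated marker ids")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  m <- ncol(dosages)
  if (!is.null(chrom) && length(chrom) != m) stop("chrom length mismatch")
  if (!is.null(pos) && length(pos) != m) stop("pos length mismatch")
  if (is.null(biallelic)) biallelic <- rep(TRUE, m)
  if (length(biallelic) != m) stop("biallelic length mismatch")
  structure(list(dosages = dosages, chrom = chrom, pos = pos,
                 biallelic = biallelic),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("GenotypeMatrix: %d lines x %d markers\n", nrow(d), ncol(d)))
  cat(sprintf("  missing: %.2f%%; heterozygous calls: %d\n",
              100 * mean(is.na(d)), sum(d == 1, na.rm = TRUE)))
  if (!is.null(x$chrom))
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(x$chrom)[seq_len(min(10, length(unique(x$chrom))))],
                      collapse = ", ")))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

# Subset markers (columns), keeping metadata aligned.
subset_markers <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  chrom = if (!is.null(G$chrom)) G$chrom[keep],
                  pos = if (!is.null(G$pos)) G$pos[keep],
                  biallelic = G$biallelic[keep])
}

#' Read genotypes from file
#'
#' Reads a parental genotype panel into a [genotype_matrix()]. Three
#' formats are supported: a plain delimited dosage table (first column the
#' line id, header row of marker ids), VCF v4.x (diploid GT field; parsed
#' with the VariantAnnotation package), and HapMap (tab-delimited with the
#' standard 11 annotation columns, IUPAC single-letter or allele-pair
#' calls).
#'
#' Dosages count the second-listed (ALT) allele: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, missing preserved as `NA`. Multi-allelic VCF records are
#' kept but flagged non-biallelic (genotypes carrying a third allele become
#' `NA`) so the QC cascade can remove them.
#'
#' @param path file path.
#' @param format one of `"dosage"`, `"vcf"`, `"hapmap"`.
#' @return A `GenotypeMatrix`.
#' @seealso [write_genotypes()], [qc_parent_panel()]
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf", "hapmap")) {
  format <- match.arg(format)
  switch(format,
         dosage = read_dosage_table(path),
         vcf = read_vcf_genotypes(path),
         hapmap = read_hapmap_genotypes(path))
}

read_dosage_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  genotype_matrix(mat)
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  biallelic <- n_alt == 1L
  code <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
            "1|0" = 1, "1/1" = 2, "1|1" = 2)
  dos <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0(chrom, "_", pos)
  dm <- t(dos)
  colnames(dm) <- ids
  genotype_matrix(dm, chrom = chrom, pos = pos, biallelic = biallelic)
}

# IUPAC ambiguity codes for unphased diploid single-letter HapMap calls.
iupac_pairs <- c(A = "AA", C = "CC", G = "GG", T = "TT",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 N = NA_character_)

read_hapmap_genotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "NN", "N"))
  if (ncol(dt) < 12) stop("HapMap file needs 11 annotation columns plus samples")
  marker_ids <- as.character(dt[[1]])
  alleles <- strsplit(as.character(dt[[2]]), "/", fixed = TRUE)
  second <- vapply(alleles, function(a) if (length(a) >= 2) a[2] else NA_character_, "")
  chrom <- as.character(dt[[3]])
  pos <- as.integer(dt[[4]])
  calls <- as.matrix(dt[, -(1:11), drop = FALSE])
  one_letter <- nchar(calls) == 1L & !is.na(calls)
  calls[one_letter] <- iupac_pairs[calls[one_letter]]
  # dosage = count of the second-listed allele in the two-letter call
  dos <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (j in seq_len(nrow(calls))) {
    cj <- calls[j, ]
    known <- !is.na(cj) & !is.na(second[j])
    dos[j, known] <- vapply(strsplit(cj[known], ""),
                            function(g) sum(g == second[j]), 0)
  }
  dm <- t(dos)
  colnames(dm) <- marker_ids
  genotype_matrix(dm, chrom = chrom, pos = pos)
}

#' Write genotypes to file
#'
#' Writes a `GenotypeMatrix` as a delimited dosage table (tab-separated,
#' first column `line`) or as a minimal VCF v4.2 with synthetic REF/ALT
#' alleles (A/C) and a diploid GT field. Positions are 1-based; markers
#' without coordinates are written on chromosome `"1"` at consecutive
#' positions.
#'
#' @param G a `GenotypeMatrix`.
#' @param path output path.
#' @param format `"dosage"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage") {
    df <- data.frame(line = rownames(G$dosages), G$dosages,
                     check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    d <- G$dosages
    chrom <- if (!is.null(G$chrom)) G$chrom else rep("1", ncol(d))
    pos <- if (!is.null(G$pos)) G$pos else seq_len(ncol(d))
    gt_code <- c("0/0", "0/1", "1/1")
    lines_out <- c("##fileformat=VCFv4.2",
                   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                   paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "INFO", "FORMAT", rownames(d)),
                         collapse = "\t"))
    body <- vapply(seq_len(ncol(d)), function(j) {
      g <- d[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
      paste(c(chrom[j], pos[j], colnames(d)[j], "A", "C", ".", "PASS",
              ".", "GT", gt), collapse = "\t")
    }, "")
    writeLines(c(lines_out, body), path)
  }
  invisible(path)
}

#' Impute missing dosages by the per-marker mode
#'
#' Replaces each missing call with the most frequent observed dosage of the
#' same marker; ties are broken towards the lower dosage. Observed entries
#' are never changed. This simple imputer stands in for haplotype-based
#' imputation and is adequate for panels of inbred lines with low
#' missingness.
#'
#' @param G a `GenotypeMatrix`.
#' @return A `GenotypeMatrix` with no missing values.
#' @export
impute_missing <- function(G) {
  d <- G$dosages
  miss_mk <- which(colSums(is.na(d)) > 0)
  for (j in miss_mk) {
    obs <- d[, j][!is.na(d[, j])]
    if (length(obs) == 0)
      stop(sprintf("marker %s is entirely missing; apply the call-rate filter first",
                   colnames(d)[j]))
    tab <- table(obs)
    mode_val <- as.numeric(names(tab)[which.max(tab)])  # ties: lowest dosage
    d[is.na(d[, j]), j] <- mode_val
  }
  G$dosages <- d
  G
}
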