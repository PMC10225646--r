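#' Per-SNP minor allele frequency
#'
#' `p` is the effect-allele frequency, `mean(dosage) / 2` over non-missing
#' entries; MAF is `min(p, 1 - p)`. Monomorphic SNPs get MAF 0 (valid; they
#' are filtered downstream, not errored here).
#'
#' @param genotypes A `gest_genotypes` object or bare dosage matrix.
#' @return Tibble: `snp_id`, `eaf` (effect-allele frequency), `maf`.
#' @export
compute_maf <- function(genotypes) {
  G <- dosage_matrix(genotypes)
  if (any(G < 0 | G > 2, na.rm = TRUE)) {
    rlang::abort("dosages must lie in [0, 2].")
  }
  p <- colMeans(G, na.rm = TRUE) / 2
  tibble::tibble(
    snp_id = colnames(G), eaf = unname(p), maf = unname(pmin(p, 1 - p))
  )
}

dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "gest_genotypes")) genotypes$dosage else as.matrix(genotypes)
}

# per-SNP standardised dosage matrix: mean-impute, centre at 2p, scale by
# sqrt(2p(1-p)); SNPs failing the MAF filter are dropped
standardise_dosages <- function(G, maf_min = 0) {
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(maf >= maf_min & maf > 0)
  if (!length(keep)) rlang::abort("no polymorphic SNP passes the MAF filter.")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j]); if (any(nas)) G[nas, j] <- 2 * p[j]
    }
  }
  Z <- sweep(G, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  list(Z = Z, p = p, keep = keep)
}

#' Genetic relationship matrix
#'
#' GCTA-style GRM of standardised dosages:
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' with allele frequencies estimated in-sample and missing dosages
#' mean-imputed per SNP. Only SNPs with `maf >= maf_min` (and > 0) enter.
#'
#' @param genotypes `gest_genotypes` or dosage matrix.
#' @param maf_min MAF filter applied before computing the GRM.
#' @return A `gest_grm`: list with `A` (n x n symmetric), `m_snps`,
#'   `sample_id`.
#' @export
compute_grm <- function(genotypes, maf_min = 0.01) {
  G <- dosage_matrix(genotypes)
  sd_ <- standardise_dosages(G, maf_min)
  m <- ncol(sd_$Z)
  A <- tcrossprod(sd_$Z) / m
  structure(
    list(A = A, m_snps = m, sample_id = rownames(G)),
    class = "gest_grm"
  )
}

#' Genotype principal components
#'
#' PCA of the mean-imputed, per-SNP standardised dosage matrix (the same
#' standardisation as the GRM). Used to adjust association scans for
#' population stratification (PC1 and PC2 enter the MLMA fixed effects) and
#' to check whether strata separate.
#'
#' @param genotypes `gest_genotypes` or dosage matrix.
#' @param n_components Number of PCs to return.
#' @param maf_min MAF filter applied before the PCA.
#' @return List with `scores` (tibble: sample_id, PC1..PCk) and
#'   `variance_fraction` (length-k numeric, non-increasing).
#' @export
genotype_pca <- function(genotypes, n_components = 2, maf_min = 0.01) {
  G <- dosage_matrix(genotypes)
  if (nrow(G) < n_components) rlang::abort("need n >= n_components.")
  sd_ <- standardise_dosages(G, maf_min)
  if (all(abs(sd_$Z) < 1e-12)) rlang::abort("zero-variance genotype matrix.")
  pc <- stats::prcomp(sd_$Z, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(G) %||% sprintf("S%05d", seq_len(nrow(G)))),
    scores
  )
  vf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  list(scores = scores, variance_fraction = vf)
}

#' Pairwise composite LD r-squared
#'
#' Squared Pearson correlation of dosage vectors (composite LD; phase-free,
#' matching PLINK's dosage r2). A monomorphic SNP has undefined LD and is
#' reported as `NA`; the instrument-thinning step treats `NA` as r2 = 0.
#'
#' @param genotypes `gest_genotypes` or dosage matrix.
#' @param snp_a,snp_b SNP ids (column names) or indices.
#' @return Scalar r-squared in `[0, 1]`, or `NA` if either SNP is monomorphic.
#' @export
ld_r2 <- function(genotypes, snp_a, snp_b) {
  G <- dosage_matrix(genotypes)
  xa <- G[, snp_a]; xb <- G[, snp_b]
  ok <- !is.na(xa) & !is.na(xb)
  if (stats::var(xa[ok]) == 0 || stats::var(xb[ok]) == 0) return(NA_real_)
  stats::cor(xa[ok], xb[ok])^2
}

# full r2 matrix for a set of SNPs (used by LD thinning)
ld_r2_matrix <- function(G) {
  sds <- apply(G, 2, stats::sd, na.rm = TRUE)
  R <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}

#' Write a GRM in the GCTA-like text layout
#'
#' Two files: `<prefix>.grm` (tab-delimited lower triangle: index i, index j,
#' number of SNPs, A_ij) and `<prefix>.grm.id` (sample ids).
#'
#' @param grm A `gest_grm`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$A)
  ij <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tab <- data.frame(
    i = ij[, 1], j = ij[, 2], m = grm$m_snps,
    a = grm$A[ij]
  )
  grm_path <- paste0(prefix, ".grm")
  id_path <- paste0(prefix, ".grm.id")
  utils::write.table(tab, grm_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(fid = grm$sample_id, iid = grm$sample_id),
    id_path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(c(grm_path, id_path))
}
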