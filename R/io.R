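#' Write genotypes as a minimal VCF
#'
#' One ALT allele per site, unphased GT genotypes reconstructed from dosage
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1). The effect allele is written as ALT so a
#' round trip through ALT-dosage recovers the matrix.
#'
#' @param genotypes `gest_genotypes`.
#' @param path Output path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  snps <- genotypes$snps
  G <- genotypes$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow(G), ncol(G))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(snps$chr[j], snps$pos[j], snps$snp_id[j],
            snps$other_allele[j], snps$effect_allele[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genotypes as a PLINK-raw-style dosage table
#'
#' Tab-delimited with header: `FID`, `IID`, then one `SNP_EFFECTALLELE`
#' column per SNP holding the 0/1/2 effect-allele dosage.
#'
#' @param genotypes `gest_genotypes`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_raw <- function(genotypes, path) {
  G <- genotypes$dosage
  cols <- paste0(genotypes$snps$snp_id, "_", genotypes$snps$effect_allele)
  d <- data.frame(
    FID = genotypes$samples$family_id %||% genotypes$samples$sample_id,
    IID = genotypes$samples$sample_id,
    G, check.names = FALSE
  )
  d$FID[is.na(d$FID)] <- d$IID[is.na(d$FID)]
  colnames(d) <- c("FID", "IID", cols)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PLINK-raw-style dosage table back into a genotype object
#'
#' @param path File written by [write_raw()] (or PLINK `--recode A`).
#' @return A `gest_genotypes` with SNP metadata reconstructed from the
#'   column names (`snp_id`, `effect_allele`; positions unknown are filled
#'   sequentially on one chromosome).
#' @export
read_raw <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                         names(d))
  snp_cols <- setdiff(names(d), meta_cols)
  parts <- regmatches(snp_cols, regexpr("_[ACGT]$", snp_cols))
  snp_id <- sub("_[ACGT]$", "", snp_cols)
  ea <- sub("^_", "", parts)
  G <- as.matrix(d[, snp_cols, drop = FALSE])
  colnames(G) <- snp_id
  rownames(G) <- d$IID
  storage.mode(G) <- "integer"
  structure(
    list(
      dosage = G,
      snps = tibble::tibble(
        snp_id = snp_id, chr = 1L, pos = seq_along(snp_id) * 10000L,
        effect_allele = ea, other_allele = NA_character_,
        maf_target = NA_real_
      ),
      samples = tibble::tibble(
        sample_id = d$IID, stratum = "unknown",
        family_id = if ("FID" %in% names(d)) d$FID else NA_character_
      )
    ),
    class = "gest_genotypes"
  )
}

#' Write a phenotype/covariate table as TSV
#'
#' @param phenotypes Tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth as key-value text
#'
#' @param truth `sim_truth` from [simulate_phenotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  lines <- c(paste0("stratum\t", truth$stratum))
  for (m in names(truth$snp_effects)) {
    eff <- truth$snp_effects[[m]]
    for (s in names(eff)) {
      lines <- c(lines, sprintf("snp_effect\t%s\t%s\t%.10g", m, s, eff[[s]]))
    }
  }
  for (i in seq_len(nrow(truth$causal_beta))) {
    lines <- c(lines, sprintf(
      "causal_beta\t%s\tfasting\t%.10g", truth$causal_beta$metabolite[i],
      truth$causal_beta$fasting[i]
    ), sprintf(
      "causal_beta\t%s\ttwo_hour\t%.10g", truth$causal_beta$metabolite[i],
      truth$causal_beta$two_hour[i]
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write association results in a GCTA-mlma-compatible layout
#'
#' Columns `SNP, CHR, BP, A1, A2, FREQ, BETA, SE, P, N` (A1 = effect allele).
#'
#' @param records Tibble from [mlma_scan()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(records, path) {
  out <- data.frame(
    SNP = records$snp_id, CHR = records$chr, BP = records$pos,
    A1 = records$effect_allele, A2 = records$other_allele,
    FREQ = records$maf, BETA = records$beta, SE = records$se,
    P = records$p, N = records$n
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
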