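# shared fixture builders; everything is generated in code at test time

# bare genotype object from an explicit dosage matrix
toy_genotypes <- function(dosage, chr = NULL, effect_allele = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  ids <- colnames(dosage) %||% sprintf("rs%06d", seq_len(m))
  colnames(dosage) <- ids
  rownames(dosage) <- rownames(dosage) %||% sprintf("S_%05d", seq_len(n))
  structure(
    list(
      dosage = dosage,
      snps = tibble::tibble(
        snp_id = ids,
        chr = chr %||% rep(1L, m),
        pos = seq_len(m) * 1000L,
        effect_allele = effect_allele %||% rep("A", m),
        other_allele = rep("G", m),
        maf_target = colMeans(dosage) / 2
      ),
      samples = tibble::tibble(
        sample_id = rownames(dosage), stratum = "S", family_id = NA_character_
      )
    ),
    class = "gest_genotypes"
  )
}

# random HWE genotypes
random_genotypes <- function(n, m, maf = 0.3, seed = 1, chr = NULL) {
  set.seed(seed)
  maf <- rep_len(maf, m)
  G <- sapply(maf, function(p) stats::rbinom(n, 2L, p))
  storage.mode(G) <- "integer"
  toy_genotypes(G, chr = chr)
}

# single-stratum config with one instrumented metabolite; used by several tests
one_met_config <- function(n = 2000, seed = 1, n_snps = 4,
                           snp_effect = 0.172, beta_fasting = 0.2,
                           confound = TRUE, m_snps = 10) {
  eff <- stats::setNames(rep(snp_effect, n_snps), sprintf("rs%06d", seq_len(n_snps)))
  cohort_config(
    n_per_stratum = c(S = n), m_snps = m_snps, n_chromosomes = 2,
    maf_range_per_stratum = list(S = c(0.3, 0.3)),
    relatedness = list(n_families = 0, kinship = 0),
    metabolites = list(
      metabolite_architecture("met", "cls", eff, residual_sd = 1)
    ),
    causal_effects = list(met = c(fasting = beta_fasting, two_hour = 0)),
    confounder_sd = if (confound) 1 else 0,
    confounder_loadings = if (confound) c(met = 0.6, fasting = 0.35) else c(),
    seed = seed
  )
}

# per-SNP OLS weights for a GRS (the plain first-stage GWAS used in tests)
ols_weights <- function(metabolite, genotypes) {
  G <- genotypes$dosage
  vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    stats::cov(metabolite, x) / stats::var(x)
  }, numeric(1)) |> stats::setNames(colnames(G))
}

# build a gest_instrument directly
manual_instrument <- function(snp_ids, weights, exposure = "met",
                              class_label = "cls",
                              effect_allele = rep("A", length(snp_ids))) {
  structure(
    list(
      exposure = exposure, class_label = class_label,
      snps = tibble::tibble(
        snp_id = snp_ids, effect_allele = effect_allele,
        weight = weights, p = NA_real_
      ),
      audit = tibble::tibble()
    ),
    class = "gest_instrument"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
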