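#' Simulate genotype matrices for every stratum of a cohort
#'
#' Genotypes are drawn in Hardy-Weinberg proportions per stratum at per-SNP
#' target minor-allele frequencies sampled uniformly from the stratum's MAF
#' range. Relatedness is injected as family blocks: the first `2 * n_families`
#' individuals form pairs in which each allele of the second member is an
#' identical-by-descent copy of the partner's corresponding allele with
#' probability `2 * kinship` (and a fresh population draw otherwise), which
#' gives an expected genotypic correlation of `2 * kinship` within a pair —
#' full sibs in expectation when `kinship = 0.25`. SNPs are assigned
#' round-robin to chromosomes.
#'
#' @param config A [cohort_config()].
#' @return Named list (one element per stratum) of `gest_genotypes` objects:
#'   each a list with `dosage` (n x m integer matrix, 0/1/2), `snps` (tibble:
#'   `snp_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `maf_target`)
#'   and `samples` (tibble: `sample_id`, `stratum`, `family_id`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  m <- config$m_snps
  snp_ids <- sprintf("rs%06d", seq_len(m))
  chr <- ((seq_len(m) - 1L) %% config$n_chromosomes) + 1L
  pos <- integer(m)
  for (c_ in unique(chr)) pos[chr == c_] <- seq_len(sum(chr == c_)) * 10000L
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- vapply(alleles[same, 1], function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, character(1))

  out <- list()
  for (st in names(config$n_per_stratum)) {
    n <- config$n_per_stratum[[st]]
    rg <- config$maf_range_per_stratum[[st]]
    maf <- stats::runif(m, rg[1], rg[2])
    n_fam <- config$relatedness$n_families
    phi <- 2 * config$relatedness$kinship   # per-allele IBD copy probability

    # allele pairs for every individual; dosage = a1 + a2
    a1 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
    a2 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
    family_id <- rep(NA_character_, n)
    if (n_fam > 0 && phi > 0) {
      i1 <- seq_len(n_fam) * 2L - 1L   # first member of each pair
      i2 <- i1 + 1L
      copy1 <- matrix(stats::runif(n_fam * m) < phi, n_fam, m)
      copy2 <- matrix(stats::runif(n_fam * m) < phi, n_fam, m)
      a1[i2, ][copy1] <- a1[i1, ][copy1]
      a2[i2, ][copy2] <- a2[i1, ][copy2]
      family_id[c(i1, i2)] <- rep(sprintf("%s_fam%04d", st, seq_len(n_fam)), 2)
    } else if (n_fam > 0) {
      i1 <- seq_len(n_fam) * 2L - 1L
      family_id[c(i1, i1 + 1L)] <- rep(sprintf("%s_fam%04d", st, seq_len(n_fam)), 2)
    }
    dosage <- a1 + a2
    storage.mode(dosage) <- "integer"
    sample_id <- sprintf("%s_%05d", st, seq_len(n))
    rownames(dosage) <- sample_id
    colnames(dosage) <- snp_ids
    out[[st]] <- structure(
      list(
        dosage = dosage,
        snps = tibble::tibble(
          snp_id = snp_ids, chr = chr, pos = pos,
          effect_allele = alleles[, 1], other_allele = alleles[, 2],
          maf_target = maf
        ),
        samples = tibble::tibble(
          sample_id = sample_id, stratum = st, family_id = family_id
        )
      ),
      class = "gest_genotypes"
    )
  }
  out
}

#' @export
print.gest_genotypes <- function(x, ...) {
  cat(sprintf(
    "<gest_genotypes> %d samples x %d SNPs (%d chromosomes), stratum %s\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chr)),
    x$samples$stratum[1]
  ))
  invisible(x)
}

#' Simulate metabolites, glucose outcomes and covariates on top of genotypes
#'
#' Metabolites are linear in allele dosage plus a shared confounder and a
#' (possibly class-correlated) residual:
#' `met_k = mean_k + sum_j effect_jk * dosage_j + lambda_k * U + eps_k`.
#' Fasting and 2-hour post-load glucose are generated multiplicatively,
#' `glucose = exp(mu + sum_k beta_k * (met_k - mean(met_k)) + lambda_y * U +
#' direct pleiotropic SNP effects + eps_y)`, so the natural log of the outcome
#' is the scale on which the causal model is linear and log-normalisation is
#' the correct preparation step. Covariates (parity, maternal age, BMI,
#' smoking, multiple pregnancy, gestational age) are drawn per individual with
#' the configured confounder loadings on BMI and maternal age.
#'
#' @param genotypes A single stratum's `gest_genotypes`.
#' @param config The [cohort_config()] used to generate it.
#' @param stratum Stratum name (defaults to the genotype object's stratum).
#' @return List with `phenotypes` (tibble: sample_id, stratum, covariates,
#'   one column per metabolite, `fasting`, `two_hour` in mmol/L) and `truth`
#'   (a `sim_truth` list recording every coefficient actually used).
#' @export
simulate_phenotypes <- function(genotypes, config,
                                stratum = genotypes$samples$stratum[1]) {
  stopifnot(inherits(genotypes, "gest_genotypes"),
            inherits(config, "cohort_config"))
  # stratum-specific stream, reproducible from the config seed
  set.seed(config$seed + 7919L * match(stratum, names(config$n_per_stratum)))
  G <- genotypes$dosage
  n <- nrow(G)
  snp_ids <- colnames(G)
  loading <- function(nm) {
    if (nm %in% names(config$confounder_loadings)) {
      config$confounder_loadings[[nm]]
    } else 0
  }

  U <- stats::rnorm(n, 0, config$confounder_sd)

  mets <- config$metabolites
  met_names <- vapply(mets, `[[`, character(1), "name")
  # one shared residual factor per class for class_correlation
  class_of <- vapply(mets, `[[`, character(1), "class_label")
  class_factor <- matrix(stats::rnorm(n * length(unique(class_of))), n)
  colnames(class_factor) <- unique(class_of)

  M <- matrix(0, n, length(mets), dimnames = list(rownames(G), met_names))
  snp_effects <- list()
  for (k in seq_along(mets)) {
    arch <- mets[[k]]
    eff <- arch$causal_snps
    bad <- setdiff(names(eff), snp_ids)
    if (length(bad)) {
      rlang::abort(paste0("metabolite '", arch$name,
                          "' names unknown SNP(s): ", paste(bad, collapse = ", ")))
    }
    genetic <- if (length(eff)) drop(G[, names(eff), drop = FALSE] %*% eff) else 0
    rho <- arch$class_correlation
    resid <- arch$residual_sd *
      (sqrt(rho) * class_factor[, arch$class_label] +
         sqrt(1 - rho) * stats::rnorm(n))
    M[, k] <- arch$mean + genetic + loading(arch$name) * U + resid
    snp_effects[[arch$name]] <- eff
  }

  # covariates
  parity <- stats::rpois(n, 1.2)
  maternal_age <- stats::rnorm(n, 27.5, 5) + loading("maternal_age") * U
  bmi <- stats::rnorm(n, 26, 4.5) + loading("bmi") * U
  smoking <- stats::rbinom(n, 1, 0.15)
  multiple_pregnancy <- stats::rbinom(n, 1, 0.015)
  gestational_age <- stats::rnorm(n, 184, 2.4)  # days; deliberately low-variance

  causal <- config$causal_effects[[stratum]]
  beta_f <- beta_2h <- stats::setNames(numeric(length(met_names)), met_names)
  for (nm in names(causal)) {
    b <- causal[[nm]]
    beta_f[nm] <- if ("fasting" %in% names(b)) b[["fasting"]] else b[1]
    beta_2h[nm] <- if ("two_hour" %in% names(b)) b[["two_hour"]] else b[2]
  }
  Mc <- sweep(M, 2, colMeans(M))   # centred so medians sit at glucose_meds
  direct <- function(which_outcome) {
    d <- numeric(n)
    if (!is.null(config$pleiotropy)) {
      pl <- config$pleiotropy[config$pleiotropy$outcome == which_outcome, ]
      for (i in seq_len(nrow(pl))) {
        if (!pl$snp_id[i] %in% snp_ids) {
          rlang::abort(paste0("pleiotropy names unknown SNP: ", pl$snp_id[i]))
        }
        d <- d + pl$direct_effect[i] * G[, pl$snp_id[i]]
      }
    }
    d
  }
  lp_f <- drop(Mc %*% beta_f) + loading("fasting") * U + direct("fasting")
  lp_2h <- drop(Mc %*% beta_2h) + loading("two_hour") * U + direct("two_hour")
  fasting <- exp(log(config$glucose_meds[["fasting"]]) + lp_f +
                   stats::rnorm(n, 0, config$outcome_sd))
  two_hour <- exp(log(config$glucose_meds[["two_hour"]]) + lp_2h +
                    stats::rnorm(n, 0, config$outcome_sd))

  phen <- tibble::tibble(
    sample_id = genotypes$samples$sample_id,
    stratum = stratum,
    parity = parity, maternal_age = maternal_age, bmi = bmi,
    smoking = smoking, multiple_pregnancy = multiple_pregnancy,
    gestational_age = gestational_age
  )
  phen <- dplyr::bind_cols(phen, tibble::as_tibble(M))
  phen$fasting <- fasting
  phen$two_hour <- two_hour

  truth <- structure(
    list(
      stratum = stratum,
      snp_effects = snp_effects,
      causal_beta = tibble::tibble(
        metabolite = met_names, fasting = unname(beta_f),
        two_hour = unname(beta_2h)
      ),
      confounder = U,
      confounder_loadings = config$confounder_loadings,
      pleiotropy = config$pleiotropy,
      outcome_sd = config$outcome_sd
    ),
    class = "sim_truth"
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full two-stratum cohort
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()] for every stratum.
#'
#' @param config A [cohort_config()].
#' @return List with `genotypes` (per stratum), `phenotypes` (one tibble, all
#'   strata stacked) and `truth` (per stratum).
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  sim <- lapply(names(geno), function(st) {
    simulate_phenotypes(geno[[st]], config, stratum = st)
  })
  names(sim) <- names(geno)
  list(
    genotypes = geno,
    phenotypes = dplyr::bind_rows(lapply(sim, `[[`, "phenotypes")),
    truth = lapply(sim, `[[`, "truth")
  )
}
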