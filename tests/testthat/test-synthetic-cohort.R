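test_that("simulation is reproducible and strata independent", {
  cfg <- cohort_config(
    n_per_stratum = c(SA = 50, WE = 40), m_snps = 30, n_chromosomes = 3,
    metabolites = list(metabolite_architecture("m1", "c1", residual_sd = 1)),
    seed = 99
  )
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$SA$dosage, b$genotypes$SA$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  # round-robin chromosome assignment
  expect_equal(a$genotypes$SA$snps$chr, ((seq_len(30) - 1L) %% 3L) + 1L)
})

test_that("empirical MAF tracks the stratum target and dosages are 0/1/2", {
  cfg <- cohort_config(
    n_per_stratum = c(S = 800), m_snps = 150,
    maf_range_per_stratum = list(S = c(0.25, 0.35)),
    seed = 3
  )
  g <- simulate_genotypes(cfg)$S
  expect_true(all(g$dosage %in% 0:2))
  maf <- compute_maf(g)$maf
  expect_true(all(abs(maf - g$snps$maf_target) < 0.05))
})

test_that("unrelated cohorts give a near-zero mean off-diagonal GRM", {
  cfg <- cohort_config(
    n_per_stratum = c(S = 500), m_snps = 400,
    maf_range_per_stratum = list(S = c(0.3, 0.3)),
    relatedness = list(n_families = 0, kinship = 0), seed = 11
  )
  g <- simulate_genotypes(cfg)$S
  A <- compute_grm(g, maf_min = 0.01)$A
  offd <- A[lower.tri(A)]
  expect_lt(abs(mean(offd)), 0.02)
})

test_that("sib pairs at kinship 0.25 show GRM entries near 0.5", {
  # Monte-Carlo over 10 seeds against the expectation 2 * kinship
  means <- vapply(1:10, function(s) {
    cfg <- cohort_config(
      n_per_stratum = c(S = 500), m_snps = 300,
      relatedness = list(n_families = 250, kinship = 0.25), seed = s
    )
    g <- simulate_genotypes(cfg)$S
    A <- compute_grm(g, maf_min = 0.01)$A
    fam <- g$samples$family_id
    ix <- split(seq_along(fam), fam)
    mean(vapply(ix, function(i) A[i[1], i[2]], numeric(1)))
  }, numeric(1))
  expect_true(all(means > 0.4 & means < 0.6))
  expect_lt(abs(mean(means) - 0.5), 0.03)
})

test_that("degenerate configs are rejected", {
  expect_error(cohort_config(m_snps = 0), "m_snps")
  expect_error(cohort_config(n_per_stratum = c(S = 1)), "n >= 2")
  expect_error(cohort_config(relatedness = list(n_families = 0, kinship = 0.6)),
               "kinship")
  expect_error(
    cohort_config(maf_range_per_stratum = list(SA = c(0, 0.5), WE = c(0.1, 0.2))),
    "MAF"
  )
})

test_that("null architecture gives metabolites independent of genotype", {
  cfg <- cohort_config(
    n_per_stratum = c(S = 400), m_snps = 1000, n_chromosomes = 5,
    metabolites = list(metabolite_architecture("m1", "c1", residual_sd = 1)),
    confounder_sd = 0, seed = 5
  )
  ch <- simulate_cohort(cfg)
  y <- ch$phenotypes$m1
  G <- ch$genotypes$S$dosage
  tmax <- max(abs(vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    r <- stats::cor(x, y)
    r * sqrt((length(y) - 2) / (1 - r^2))
  }, numeric(1))))
  # largest |t| over 1000 null SNPs: p_min should not cross the suggestive level
  expect_gt(2 * stats::pt(-tmax, length(y) - 2), 1e-5)
})

test_that("causal effect on log fasting glucose is recovered without confounding", {
  cfg <- one_met_config(n = 5000, seed = 7, confound = FALSE)
  ch <- simulate_cohort(cfg)
  fit <- stats::lm(log(ch$phenotypes$fasting) ~ ch$phenotypes$met)
  expect_lt(abs(stats::coef(fit)[2] - 0.2), 0.02)
  # multiplicative generation: medians sit near the clinical range
  expect_lt(abs(stats::median(ch$phenotypes$fasting) - 4.5), 0.4)
  expect_lt(abs(stats::median(ch$phenotypes$two_hour) - 6.0), 0.6)
})

test_that("realised heritability matches the architecture", {
  # h2 = var(genetic) / total; architecture: 4 SNPs, maf 0.3, effect 0.2 each,
  # residual_sd 1  ->  var_g = 4 * 0.2^2 * 2*0.3*0.7 = 0.0672
  eff <- stats::setNames(rep(0.2, 4), sprintf("rs%06d", 1:4))
  cfg <- cohort_config(
    n_per_stratum = c(S = 5000), m_snps = 8,
    maf_range_per_stratum = list(S = c(0.3, 0.3)),
    metabolites = list(metabolite_architecture("m1", "c", eff, residual_sd = 1)),
    confounder_sd = 0, seed = 21
  )
  ch <- simulate_cohort(cfg)
  gcomp <- drop(ch$genotypes$S$dosage[, names(eff)] %*% eff)
  h2_hat <- stats::var(gcomp) / stats::var(ch$phenotypes$m1)
  h2_exp <- 0.0672 / 1.0672
  expect_lt(abs(h2_hat - h2_exp), 0.02)
})

test_that("unknown SNP ids in the architecture fail loudly", {
  cfg <- cohort_config(
    n_per_stratum = c(S = 10), m_snps = 5,
    metabolites = list(
      metabolite_architecture("m1", "c", c(rs999999 = 0.5))
    ), seed = 1
  )
  g <- simulate_genotypes(cfg)$S
  expect_error(simulate_phenotypes(g, cfg), "rs999999")
})

test_that("simulation truth records the generating coefficients", {
  cfg <- one_met_config(n = 50, seed = 2)
  ch <- simulate_cohort(cfg)
  tr <- ch$truth$S
  expect_equal(tr$causal_beta$fasting[tr$causal_beta$metabolite == "met"], 0.2)
  expect_named(tr$snp_effects, "met")
  expect_length(tr$confounder, 50)
})
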