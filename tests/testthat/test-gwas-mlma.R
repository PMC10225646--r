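test_that("REML finds no genetic variance for a non-genetic phenotype", {
  g <- random_genotypes(1000, 500, maf = stats::runif(500, 0.1, 0.5), seed = 41)
  grm <- compute_grm(g, maf_min = 0.05)
  set.seed(42)
  y <- stats::rnorm(1000)
  vc <- reml_variance_components(y, NULL, grm)
  expect_lt(vc$sigma2_g, 0.05 * (vc$sigma2_g + vc$sigma2_e))
  expect_true(vc$identifiable)
})

test_that("REML recovers heritability in a sib-pair cohort", {
  h2_hats <- vapply(1:10, function(s) {
    cfg <- cohort_config(
      n_per_stratum = c(S = 400), m_snps = 400,
      relatedness = list(n_families = 200, kinship = 0.25), seed = s
    )
    g <- simulate_genotypes(cfg)$S
    grm <- compute_grm(g, maf_min = 0.05)
    set.seed(1000 + s)
    # phenotype with GRM-structured genetic component, h2 = 0.5
    sd_ <- eigen(grm$A, symmetric = TRUE)
    u <- sd_$vectors %*% (sqrt(pmax(sd_$values, 0)) * stats::rnorm(400))
    y <- drop(u) * sqrt(0.5) + stats::rnorm(400, 0, sqrt(0.5))
    reml_variance_components(y, NULL, grm)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hats) - 0.5), 0.1)
})

test_that("identity GRM is flagged non-identifiable", {
  vc <- reml_variance_components(stats::rnorm(50), NULL, diag(50))
  expect_false(vc$identifiable)
})

test_that("with no genetic variance the scan collapses to per-SNP OLS", {
  g <- random_genotypes(300, 40, seed = 23, chr = rep(1:2, each = 20))
  set.seed(77)
  y <- stats::rnorm(300)
  covs <- cbind(cv = stats::rnorm(300))
  scan <- mlma_scan(y, covs, g, grm_policy = "global", maf_min = 0.05)
  vc <- attr(scan, "variance_components")[[1]]
  expect_equal(vc$lambda, 0)   # REML at the no-genetic-variance boundary
  # betas collapse to OLS exactly; SEs use the null-model residual variance
  # (variance components are estimated once and reused), so they agree to
  # O(R2) rather than machine precision
  for (j in c(1, 17, 38)) {
    id <- scan$snp_id[j]
    fit <- summary(stats::lm(y ~ g$dosage[, id] + covs))
    expect_equal(scan$beta[j], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(scan$se[j], fit$coefficients[2, 2], tolerance = 1e-2)
  }
})

test_that("fast eigendecomposition path equals dense GLS with explicit V inverse", {
  cfg <- cohort_config(
    n_per_stratum = c(S = 200), m_snps = 50, n_chromosomes = 2,
    relatedness = list(n_families = 80, kinship = 0.25),
    metabolites = list(metabolite_architecture(
      "met", "c", c(rs000003 = 0.4), residual_sd = 1
    )),
    seed = 15
  )
  ch <- simulate_cohort(cfg)
  g <- ch$genotypes$S
  y <- ch$phenotypes$met
  covs <- cbind(parity = ch$phenotypes$parity)
  for (policy in c("global", "loo_chromosome")) {
    scan <- mlma_scan(y, covs, g, grm_policy = policy, maf_min = 0.05)
    vcs <- attr(scan, "variance_components")
    parts <- lapply(split(g$snps$snp_id, g$snps$chr), identity)
    maf <- compute_maf(g)
    for (j in c(2L, nrow(scan) %/% 2L, nrow(scan))) {
      id <- scan$snp_id[j]
      chr_j <- scan$chr[j]
      vc <- if (policy == "global") vcs[[1]] else vcs[[as.character(chr_j)]]
      keep <- maf$snp_id[maf$maf >= 0.05 & maf$maf > 0]
      grm_snps <- if (policy == "global") keep else
        setdiff(keep, g$snps$snp_id[g$snps$chr == chr_j])
      A <- compute_grm(g$dosage[, grm_snps, drop = FALSE], maf_min = 0)$A
      V <- vc$sigma2_g * A + vc$sigma2_e * diag(200)
      X <- cbind(1, covs, g$dosage[, id])
      Vi_X <- solve(V, X)
      XtVX <- crossprod(X, Vi_X)
      beta <- solve(XtVX, crossprod(Vi_X, y))
      se <- sqrt(diag(solve(XtVX)))
      expect_equal(scan$beta[j], beta[length(beta)], tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(scan$se[j], se[length(se)], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("exact per-SNP GRM exclusion agrees with the chromosome scheme on toys", {
  g <- random_genotypes(120, 20, seed = 31, chr = rep(1:4, each = 5))
  set.seed(32)
  y <- stats::rnorm(120) + 0.3 * g$dosage[, 7]
  s_chr <- mlma_scan(y, NULL, g, grm_policy = "loo_chromosome", maf_min = 0.05)
  s_snp <- mlma_scan(y, NULL, g, grm_policy = "loo_snp", maf_min = 0.05)
  expect_equal(s_chr$snp_id, s_snp$snp_id)
  # same association signal, mild numerical differences from the GRM content
  expect_gt(stats::cor(s_chr$beta, s_snp$beta), 0.99)
})

test_that("a strong causal SNP is detected at the suggestive level", {
  hits <- vapply(1:20, function(s) {
    g <- random_genotypes(2000, 30, maf = 0.3, seed = 300 + s,
                          chr = rep(1:3, each = 10))
    set.seed(600 + s)
    x <- g$dosage[, 5]
    y <- 0.5 * x + stats::rnorm(2000)   # 0.5 per allele on a unit-SD background
    scan <- mlma_scan(y, NULL, g, maf_min = 0.05)
    scan$p[scan$snp_id == g$snps$snp_id[5]] <= 1e-5
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("genomic inflation bins and flags follow the definitions", {
  rec <- tibble::tibble(
    maf = c(rep(0.2, 25), rep(0.07, 25), rep(0.002, 5)),
    beta = 1,
    se = 1 / sqrt(c(rep(stats::qchisq(0.5, 1), 25),
                    rep(1.15 * stats::qchisq(0.5, 1), 25),
                    rep(stats::qchisq(0.5, 1), 5)))
  )
  gi <- genomic_inflation(rec)
  expect_equal(nrow(gi), 3)
  r1 <- gi[gi$maf_bin == ">=0.1", ]
  expect_equal(r1$lambda, 1, tolerance = 1e-12)
  expect_false(r1$inflated)
  r2 <- gi[gi$maf_bin == "[0.05,0.1)", ]
  expect_equal(r2$lambda, 1.15, tolerance = 1e-12)
  expect_true(r2$inflated)     # lambda >= 1.1 rule
  r3 <- gi[gi$maf_bin == "[0.001,0.005)", ]
  expect_false(r3$reliable)    # < 20 SNPs
  # empty bins omitted
  expect_false("[0.01,0.05)" %in% gi$maf_bin)
})

test_that("significance thresholds are inclusive (suggestive) and strict (GWS)", {
  rec <- tibble::tibble(p = c(1e-5, 5e-8, 1e-9, 2e-5))
  fl <- flag_thresholds(rec)
  expect_equal(fl$suggestive, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fl$gws, c(FALSE, FALSE, TRUE, FALSE))
})
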