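test_that("using the exposure as its own instrument degenerates to OLS", {
  set.seed(51)
  x <- stats::rnorm(200); y <- 0.4 * x + stats::rnorm(200)
  est <- mr_tsls(y, x, grs = x)
  expect_equal(est$beta_iv, est$ols_beta, tolerance = 1e-12)
  expect_equal(est$wu_hausman$statistic, 0)
  expect_equal(est$wu_hausman$p, 1)
})

test_that("single-instrument TSLS equals the covariate-projected ratio estimator", {
  # tiny worked dataset, checked against explicit matrix algebra
  y <- c(4.1, 4.6, 4.2, 5.0, 4.4, 4.9, 4.0, 5.2)
  x <- c(1.0, 2.1, 1.2, 2.9, 1.5, 2.5, 0.8, 3.2)
  z <- c(0, 1, 0, 2, 1, 2, 0, 2)
  cv <- c(0, 1, 1, 0, 2, 1, 0, 1)
  est <- mr_tsls(y, x, z, covariates = cbind(cv = cv))
  ry <- stats::lm(y ~ cv)$residuals
  rx <- stats::lm(x ~ cv)$residuals
  rz <- stats::lm(z ~ cv)$residuals
  ratio <- sum(ry * rz) / sum(rx * rz)
  expect_equal(est$beta_iv, ratio, tolerance = 1e-10)
  # and without covariates against the raw covariance ratio
  est0 <- mr_tsls(y, x, z)
  expect_equal(est0$beta_iv, stats::cov(y, z) / stats::cov(x, z),
               tolerance = 1e-10)
  expect_true(est0$ci95[1] <= est0$beta_iv && est0$beta_iv <= est0$ci95[2])
})

test_that("TSLS de-biases a confounded exposure where OLS cannot", {
  set.seed(52)
  n <- 5000
  z <- stats::rnorm(n); u <- stats::rnorm(n)
  x <- sqrt(0.05) * z + 0.6 * u + stats::rnorm(n, 0, sqrt(0.59))
  y <- 0.2 * x + 0.5 * u + stats::rnorm(n, 0, 0.5)
  est <- mr_tsls(y, x, z)
  expect_lt(abs(est$beta_iv - 0.2), 3 * est$se)
  expect_gt(abs(est$ols_beta - 0.2), 0.1)
  expect_lt(est$wu_hausman$p, 0.01)
  expect_false(est$first_stage$weak)
})

test_that("estimates are invariant to positive rescaling of GRS weights", {
  set.seed(53)
  g <- random_genotypes(800, 4, seed = 53)
  w <- c(0.4, 0.3, 0.2, 0.1)
  grs1 <- genetic_risk_score(manual_instrument(g$snps$snp_id, w), g)
  grs5 <- genetic_risk_score(manual_instrument(g$snps$snp_id, 5 * w), g)
  x <- grs1 + stats::rnorm(800)
  y <- 0.25 * x + stats::rnorm(800)
  e1 <- mr_tsls(y, x, grs1); e5 <- mr_tsls(y, x, grs5)
  expect_equal(e1$beta_iv, e5$beta_iv, tolerance = 1e-10)
  expect_equal(e1$se, e5$se, tolerance = 1e-10)
})

test_that("Wu-Hausman keeps its size under exogeneity (small calibration)", {
  set.seed(54)
  rej <- mean(vapply(1:400, function(i) {
    n <- 500
    z <- stats::rnorm(n)
    x <- 0.4 * z + stats::rnorm(n)
    y <- 0.2 * x + stats::rnorm(n)
    wu_hausman(y, x, z)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("leave-one-out isolates a pleiotropic SNP and handles edge cases", {
  set.seed(55)
  g <- random_genotypes(3000, 3, seed = 55)
  w <- c(0.5, 0.5, 0.5)
  inst <- manual_instrument(g$snps$snp_id, w)
  grs <- genetic_risk_score(inst, g)
  x <- grs + stats::rnorm(3000)
  # SNP 3 has a direct (horizontally pleiotropic) outcome effect
  y <- 0.2 * x + 0.4 * g$dosage[, 3] + stats::rnorm(3000)
  loo <- mr_leave_one_out(inst, g, y, x)
  expect_equal(nrow(loo), 3)
  bias <- abs(loo$beta_iv - 0.2)
  expect_equal(loo$excluded_snp[which.min(bias)], "rs000003")

  # 2-SNP instrument: each row equals the remaining single-SNP Wald ratio
  inst2 <- manual_instrument(g$snps$snp_id[1:2], w[1:2])
  loo2 <- mr_leave_one_out(inst2, g, y, x)
  for (i in 1:2) {
    other <- g$dosage[, inst2$snps$snp_id[-i]] * inst2$snps$weight[-i]
    expect_equal(loo2$beta_iv[i], stats::cov(y, other) / stats::cov(x, other),
                 tolerance = 1e-10)
  }

  single <- manual_instrument("rs000001", 0.5)
  loo1 <- mr_leave_one_out(single, g, y, x)
  expect_equal(nrow(loo1), 0)
  expect_match(attr(loo1, "reason"), "single-SNP")
})

test_that("refits after SNP removal behave as the algebra dictates", {
  set.seed(56)
  g <- random_genotypes(2500, 3, seed = 56)
  inst <- manual_instrument(g$snps$snp_id, c(0.5, 0.4, 0))
  grs <- genetic_risk_score(inst, g)
  x <- 0.5 * g$dosage[, 1] + 0.4 * g$dosage[, 2] + stats::rnorm(2500)
  y <- 0.2 * x + 0.4 * g$dosage[, 3] + stats::rnorm(2500)
  # removing the zero-weight SNP changes nothing
  r0 <- mr_refit_excluding(inst, "rs000003", g, y, x)
  expect_equal(r0$estimate$beta_iv, r0$full$beta_iv, tolerance = 1e-12)
  # removing the pleiotropic SNP reduces bias versus the generating truth
  expect_lte(abs(r0$estimate$beta_iv - 0.2), abs(r0$full$beta_iv - 0.2) + 1e-12)
  # 2-SNP instrument reduced to one equals the single-SNP Wald ratio
  inst2 <- manual_instrument(g$snps$snp_id[1:2], c(0.5, 0.4))
  r1 <- mr_refit_excluding(inst2, "rs000001", g, y, x)
  zz <- g$dosage[, 2] * 0.4
  expect_equal(r1$estimate$beta_iv, stats::cov(y, zz) / stats::cov(x, zz),
               tolerance = 1e-10)
  expect_error(mr_refit_excluding(inst2, c("rs000001", "rs000002"), g, y, x),
               "empty")
  expect_error(mr_refit_excluding(inst2, "rs000099", g, y, x), "not in instrument")
})

test_that("tidy and glance return the documented one-row summaries", {
  set.seed(57)
  x <- stats::rnorm(300); z <- 0.5 * x + stats::rnorm(300)
  y <- 0.3 * x + stats::rnorm(300)
  est <- mr_tsls(y, x, 0.4 * x + stats::rnorm(300),
                 exposure_name = "leucine", outcome_name = "log_fasting")
  td <- tidy(est)
  expect_equal(nrow(td), 1)
  expect_equal(td$exposure, "leucine")
  expect_true(all(c("estimate", "std.error", "conf.low", "conf.high",
                    "f_statistic", "wu_hausman_p", "ols_estimate") %in% names(td)))
  gl <- glance(est)
  expect_equal(gl$significant, est$ci95[1] > 0 || est$ci95[2] < 0)
})

test_that("collinear covariates are rejected", {
  set.seed(58)
  x <- stats::rnorm(100); z <- stats::rnorm(100); y <- stats::rnorm(100)
  cv <- cbind(a = x * 0 + 1, b = 2)   # both constant -> collinear with intercept
  expect_error(mr_tsls(y, x, z, covariates = cv), "collinear")
})
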