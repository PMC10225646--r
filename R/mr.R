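#' One-sample Mendelian randomization by two-stage least squares
#'
#' The exposure is regressed on the genetic risk score (stage 1), the outcome
#' on the fitted exposure (stage 2), with the GRS as the single excluded
#' instrument. The standard error uses the standard 2SLS convention:
#' residuals from the *observed* exposure with the second-stage coefficient,
#' `var = sigma2_u * (Xhat' Xhat)^{-1}`. With a single instrument the
#' estimate equals the covariate-projected ratio `cov(y, z) / cov(x, z)`.
#' The Wu-Hausman endogeneity test is run alongside in its control-function
#' form (see [wu_hausman()]), and the plain OLS coefficient is retained for
#' comparison. Covariates default to none, matching a fully stratified
#' analysis; supplying them enters them in both stages.
#'
#' @param outcome Numeric vector (log-scale glucose).
#' @param exposure Numeric vector (prepared metabolite, mmol/L).
#' @param grs Numeric instrument from [genetic_risk_score()].
#' @param covariates Optional covariate matrix/data.frame (both stages).
#' @param exposure_name,outcome_name Labels carried into the result.
#' @param conf_level Confidence level for the Wald CI.
#' @return An `mr_estimate` object; see [tidy.mr_estimate()].
#' @export
mr_tsls <- function(outcome, exposure, grs, covariates = NULL,
                    exposure_name = "exposure", outcome_name = "outcome",
                    conf_level = 0.95) {
  ok <- stats::complete.cases(outcome, exposure, grs)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(as.matrix(covariates))
  y <- outcome[ok]; x <- exposure[ok]; z <- grs[ok]
  C <- design_matrix(
    if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE],
    length(y)
  )
  if (qr(C)$rank < ncol(C)) rlang::abort("covariates are collinear.")
  n <- length(y)

  Z <- cbind(C, z)
  X <- cbind(C, x)
  # stage 1: project the endogenous column onto the instrument set
  xhat <- Z %*% qr.coef(qr(Z), x)
  Xhat <- cbind(C, drop(xhat))
  qx <- qr(Xhat)
  coefs <- qr.coef(qx, y)
  beta_iv <- unname(coefs[length(coefs)])
  # 2SLS variance: residuals with the observed exposure
  resid_u <- y - X %*% coefs
  sigma2_u <- sum(resid_u^2) / (n - ncol(X))
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2_u * XtX_inv[ncol(Xhat), ncol(Xhat)])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(beta_iv - zq * se, beta_iv + zq * se)

  fs <- first_stage(x, z, if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])
  wh <- wu_hausman(y, x, z, if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])

  ols <- stats::lm.fit(X, y)
  ols_beta <- unname(ols$coefficients[ncol(X)])
  ols_s2 <- sum(ols$residuals^2) / (n - ncol(X))
  ols_se <- sqrt(ols_s2 * chol2inv(qr.R(qr(X)))[ncol(X), ncol(X)])

  structure(
    list(
      exposure = exposure_name, outcome = outcome_name,
      beta_iv = beta_iv, se = se, ci95 = ci, conf_level = conf_level,
      first_stage = fs, wu_hausman = wh,
      ols_beta = ols_beta, ols_se = ols_se, n = n,
      covariate_adjusted = !is.null(covariates)
    ),
    class = "mr_estimate"
  )
}

#' Wu-Hausman endogeneity test (control-function form)
#'
#' Augments the OLS regression of the outcome on the exposure (plus
#' covariates) with the first-stage residual; the two-sided t-test on the
#' residual coefficient contrasts the IV and OLS estimates. When the GRS
#' coincides with the exposure the residual is identically zero and the test
#' degenerates to statistic 0, p = 1.
#'
#' @inheritParams mr_tsls
#' @return List: `statistic` (squared t, 1 df), `p`, `df`.
#' @export
wu_hausman <- function(outcome, exposure, grs, covariates = NULL) {
  ok <- stats::complete.cases(outcome, exposure, grs)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(as.matrix(covariates))
  y <- outcome[ok]; x <- exposure[ok]; z <- grs[ok]
  C <- design_matrix(
    if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE],
    length(y)
  )
  v <- stats::lm.fit(cbind(C, z), x)$residuals
  if (stats::var(v) < .Machine$double.eps * stats::var(x) ||
      stats::var(v) == 0) {
    return(list(statistic = 0, p = 1, df = length(y) - ncol(C) - 2))
  }
  Xa <- cbind(C, x, v)
  fit <- stats::lm.fit(Xa, y)
  df <- length(y) - ncol(Xa)
  s2 <- sum(fit$residuals^2) / df
  vcv <- chol2inv(qr.R(qr(Xa)))
  tstat <- fit$coefficients["v"] / sqrt(s2 * vcv[ncol(Xa), ncol(Xa)])
  list(statistic = unname(tstat^2),
       p = unname(2 * stats::pt(-abs(tstat), df)), df = df)
}

#' Leave-one-out sensitivity analysis of an instrument
#'
#' Removes each SNP in turn, rebuilds the GRS from the remaining SNPs with
#' their original weights (no re-estimation), and refits the full TSLS.
#' Instruments with fewer than two SNPs cannot be analysed and return an
#' empty table with the reason attached.
#'
#' @param instrument `gest_instrument`.
#' @param genotypes `gest_genotypes`.
#' @param outcome,exposure,covariates As in [mr_tsls()].
#' @return Tibble: `excluded_snp`, `beta_iv`, `se`, `ci_lo`, `ci_hi`, `f`,
#'   `wu_hausman_p`; forest-plot ready. `attr(, "reason")` set when empty.
#' @export
mr_leave_one_out <- function(instrument, genotypes, outcome, exposure,
                             covariates = NULL) {
  snps <- instrument$snps
  if (nrow(snps) < 2) {
    out <- tibble::tibble(
      excluded_snp = character(), beta_iv = numeric(), se = numeric(),
      ci_lo = numeric(), ci_hi = numeric(), f = numeric(),
      wu_hausman_p = numeric()
    )
    attr(out, "reason") <- "single-SNP instrument: leave-one-out not possible"
    return(out)
  }
  rows <- lapply(seq_len(nrow(snps)), function(j) {
    inst_j <- instrument
    inst_j$snps <- snps[-j, , drop = FALSE]
    grs <- genetic_risk_score(inst_j, genotypes)
    est <- mr_tsls(outcome, exposure, grs, covariates,
                   exposure_name = instrument$exposure)
    tibble::tibble(
      excluded_snp = snps$snp_id[j], beta_iv = est$beta_iv, se = est$se,
      ci_lo = est$ci95[1], ci_hi = est$ci95[2], f = est$first_stage$f,
      wu_hausman_p = est$wu_hausman$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Refit an instrument with named SNPs removed
#'
#' Used after database screens mark SNPs as potentially pleiotropic: the
#' named SNPs are dropped, the GRS rebuilt with the remaining original
#' weights, TSLS refit, and the report states whether the confidence interval
#' excluded zero before vs after removal.
#'
#' @param instrument `gest_instrument`.
#' @param snp_ids SNPs to remove (must be a subset of the instrument).
#' @param genotypes,outcome,exposure,covariates As in [mr_leave_one_out()].
#' @return List: `estimate` (refit `mr_estimate`), `full` (original
#'   `mr_estimate`), `report` (one-row tibble with `significant_before`,
#'   `significant_after`, `n_removed`).
#' @export
mr_refit_excluding <- function(instrument, snp_ids, genotypes, outcome,
                               exposure, covariates = NULL) {
  bad <- setdiff(snp_ids, instrument$snps$snp_id)
  if (length(bad)) {
    rlang::abort(paste0("not in instrument: ", paste(bad, collapse = ", ")))
  }
  keep <- !(instrument$snps$snp_id %in% snp_ids)
  if (!any(keep)) rlang::abort("removal would empty the instrument.")
  full <- mr_tsls(outcome, exposure, genetic_risk_score(instrument, genotypes),
                  covariates, exposure_name = instrument$exposure)
  inst2 <- instrument
  inst2$snps <- instrument$snps[keep, , drop = FALSE]
  refit <- mr_tsls(outcome, exposure, genetic_risk_score(inst2, genotypes),
                   covariates, exposure_name = instrument$exposure)
  excl0 <- function(e) e$ci95[1] > 0 || e$ci95[2] < 0
  list(
    estimate = refit, full = full,
    report = tibble::tibble(
      n_removed = sum(!keep),
      significant_before = excl0(full),
      significant_after = excl0(refit)
    )
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s -> %s\n  beta_IV = %.4f (%.0f%% CI %.4f, %.4f), F = %.1f%s, Wu-Hausman p = %.3g\n  OLS beta = %.4f, n = %d\n",
    x$exposure, x$outcome, x$beta_iv, 100 * x$conf_level, x$ci95[1], x$ci95[2],
    x$first_stage$f, if (x$first_stage$weak) " (weak)" else "",
    x$wu_hausman$p, x$ols_beta, x$n
  ))
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble: exposure, outcome, estimate, std.error, conf.low,
#'   conf.high, first-stage F, Wu-Hausman p, OLS comparison, n.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    estimate = x$beta_iv, std.error = x$se,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    f_statistic = x$first_stage$f, weak_instrument = x$first_stage$weak,
    wu_hausman_p = x$wu_hausman$p,
    ols_estimate = x$ols_beta, n = x$n
  )
}

#' Model-level summary of an MR estimate
#'
#' @inheritParams tidy.mr_estimate
#' @return One-row tibble: r2 of the first stage, F, n, significance flag.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(
    r2_first = x$first_stage$r2_first, f_statistic = x$first_stage$f,
    significant = x$ci95[1] > 0 || x$ci95[2] < 0,
    covariate_adjusted = x$covariate_adjusted, n = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
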