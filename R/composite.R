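#' Build a composite metabolite-class exposure from PC1
#'
#' Members of a class are screened for outliers with the stringent
#' median-anchored rule (`median +/- iqr_multiplier * IQR`, default 3),
#' complete rows are standardised, and the first principal component is
#' extracted. The class is eligible as a composite exposure iff it has more
#' than two usable members and PC1 explains at least 70% of the class
#' variance. PC1's sign is fixed so the sum of loadings is positive, making
#' scores deterministic across linear-algebra backends.
#'
#' @param class_table Tibble of the class's metabolite columns (rows =
#'   individuals; non-metabolite columns must be excluded beforehand).
#' @param iqr_multiplier Outlier fence multiplier (3 = stringent screen).
#' @param anchor Fence anchor; the class stage defaults to `"median"`.
#' @param min_members Minimum usable members for eligibility (`> 2` rule).
#' @param var_threshold PC1 variance fraction required for eligibility.
#' @param class_label Label carried through.
#' @return A `composite_class`: list with `class_label`, `members`,
#'   `pc1_variance_fraction`, `scores` (NA for rows dropped as incomplete),
#'   `loadings` (unit norm), `eligible`, `reason`.
#' @export
build_composite <- function(class_table, iqr_multiplier = 3,
                            anchor = "median", min_members = 3,
                            var_threshold = 0.70, class_label = "class") {
  M <- as.data.frame(class_table)
  usable <- vapply(M, function(v) sum(!is.na(v)) > 2, logical(1))
  M <- M[, usable, drop = FALSE]
  if (ncol(M) == 0) {
    return(structure(list(
      class_label = class_label, members = character(),
      pc1_variance_fraction = NA_real_, scores = rep(NA_real_, nrow(class_table)),
      loadings = NULL, eligible = FALSE,
      reason = "no usable metabolites"
    ), class = "composite_class"))
  }
  if (ncol(M) == 1) {
    # degenerate class: the composite is the standardised metabolite itself,
    # but a single member can never be eligible
    v <- remove_outliers_iqr(M[[1]], iqr_multiplier, anchor = anchor)$values
    return(structure(list(
      class_label = class_label, members = colnames(M),
      pc1_variance_fraction = 1,
      scores = drop(scale(v)), loadings = c(1), eligible = FALSE,
      reason = "class has 1 member; composites need more than 2"
    ), class = "composite_class"))
  }
  for (j in seq_len(ncol(M))) {
    M[[j]] <- remove_outliers_iqr(M[[j]], iqr_multiplier, anchor = anchor)$values
  }
  cc <- stats::complete.cases(M)
  X <- scale(as.matrix(M[cc, , drop = FALSE]))
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  load1 <- pc$rotation[, 1]
  if (sum(load1) < 0) load1 <- -load1
  scores <- rep(NA_real_, nrow(class_table))
  scores[cc] <- drop(X %*% load1)
  eligible <- ncol(M) >= min_members && vf[1] >= var_threshold
  reason <- if (eligible) NA_character_ else if (ncol(M) < min_members) {
    sprintf("class has %d members; composites need more than 2", ncol(M))
  } else {
    sprintf("PC1 explains %.1f%% < 70%% of class variance", 100 * vf[1])
  }
  structure(list(
    class_label = class_label, members = colnames(M),
    pc1_variance_fraction = vf[1], scores = scores,
    loadings = load1, eligible = eligible, reason = reason
  ), class = "composite_class")
}

#' @export
print.composite_class <- function(x, ...) {
  cat(sprintf("<composite_class> %s: %d members, PC1 %.1f%%, %s\n",
              x$class_label, length(x$members),
              100 * (x$pc1_variance_fraction %||% NA),
              if (x$eligible) "eligible" else paste0("ineligible (", x$reason, ")")))
  invisible(x)
}

#' Run the MR machinery on a composite class exposure
#'
#' The PC1 scores are treated exactly like a metabolite: MLMA scan, selection
#' of suggestive SNPs, LD thinning, GRS, TSLS. The same code path as for
#' individual metabolites is reused; the result is flagged
#' `direction_interpretable = FALSE` because PC1 coordinates carry no
#' intrinsic sign.
#'
#' @param composite `composite_class` (must be eligible).
#' @param genotypes `gest_genotypes`.
#' @param outcome Numeric log-scale outcome vector.
#' @param covariates Covariates for the GWAS stage (e.g. parity + PCs).
#' @param mr_covariates Covariates for the MR stage (default none).
#' @param maf_min,r2_max,suggestive_p Pipeline thresholds.
#' @param grm_policy,eigen_cache Passed to [mlma_scan()].
#' @param outcome_name Label for the result.
#' @return List with `estimate` (an `mr_estimate`, or `NULL` when no SNP
#'   reaches the suggestive level), `instrument`, `gwas`, and
#'   `direction_interpretable = FALSE`.
#' @export
composite_mr <- function(composite, genotypes, outcome, covariates = NULL,
                         mr_covariates = NULL, maf_min = 0.05, r2_max = 0.2,
                         suggestive_p = 1e-5,
                         grm_policy = "loo_chromosome", eigen_cache = NULL,
                         outcome_name = "outcome") {
  if (!composite$eligible) {
    rlang::abort(paste0("composite class not eligible: ", composite$reason))
  }
  ok <- !is.na(composite$scores)
  gwas <- mlma_scan(
    composite$scores[ok],
    if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE],
    subset_samples(genotypes, ok),
    grm_policy = grm_policy, maf_min = maf_min, eigen_cache = eigen_cache
  )
  label <- paste0(composite$class_label, "_PC1")
  insts <- select_and_thin(
    stats::setNames(list(gwas), label),
    tibble::tibble(metabolite = label, class_label = composite$class_label),
    subset_samples(genotypes, ok), r2_max = r2_max, suggestive_p = suggestive_p
  )
  if (is.null(insts[[label]])) {
    return(list(estimate = NULL, instrument = NULL, gwas = gwas,
                direction_interpretable = FALSE,
                reason = "no suggestive SNP for the class composite"))
  }
  grs <- genetic_risk_score(insts[[label]], subset_samples(genotypes, ok))
  est <- mr_tsls(outcome[ok], composite$scores[ok], grs, mr_covariates,
                 exposure_name = label, outcome_name = outcome_name)
  list(estimate = est, instrument = insts[[label]], gwas = gwas,
       direction_interpretable = FALSE)
}

# row-subset a gest_genotypes, keeping metadata aligned
subset_samples <- function(genotypes, idx) {
  structure(
    list(
      dosage = genotypes$dosage[idx, , drop = FALSE],
      snps = genotypes$snps,
      samples = genotypes$samples[idx, , drop = FALSE]
    ),
    class = "gest_genotypes"
  )
}
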