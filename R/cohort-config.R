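#' Describe the genetic architecture of one simulated metabolite
#'
#' Each simulated metabolite is driven by a handful of causal SNPs (per-allele
#' effects in mmol/L), an independent residual, and an optional class-shared
#' residual component so that metabolites in the same class are correlated the
#' way NMR lipoprotein measures are in real cohorts.
#'
#' @param name Metabolite name.
#' @param class_label Metabolite class the metabolite belongs to (e.g. "HDL").
#' @param causal_snps Named numeric vector: per-allele effects in mmol/L,
#'   names are SNP ids present in the simulated genotype matrix. May be empty.
#' @param residual_sd Residual standard deviation in mmol/L (> 0).
#' @param class_correlation Fraction (in `[0, 1)`) of the residual variance
#'   shared with other members of the same class.
#' @param mean Baseline metabolite mean in mmol/L.
#'
#' @return A `metabolite_architecture` list.
#' @export
metabolite_architecture <- function(name, class_label, causal_snps = numeric(),
                                    residual_sd = 1, class_correlation = 0,
                                    mean = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(causal_snps) > 0 && is.null(names(causal_snps))) {
    rlang::abort("`causal_snps` must be a named numeric vector (names = SNP ids).")
  }
  if (!all(is.finite(causal_snps))) {
    rlang::abort("causal SNP effects must be finite.")
  }
  if (!is.numeric(residual_sd) || residual_sd <= 0) {
    rlang::abort("`residual_sd` must be > 0.")
  }
  if (class_correlation < 0 || class_correlation >= 1) {
    rlang::abort("`class_correlation` must be in [0, 1).")
  }
  structure(
    list(
      name = name, class_label = class_label,
      causal_snps = causal_snps, residual_sd = residual_sd,
      class_correlation = class_correlation, mean = mean
    ),
    class = "metabolite_architecture"
  )
}

#' Configure a two-stratum synthetic pregnancy cohort
#'
#' The simulated cohort emulates the structure of an ethnically stratified
#' pregnancy study: two strata with their own allele-frequency spectra,
#' within-stratum relatedness in family blocks, metabolites with a sparse
#' polygenic architecture, glucose outcomes generated multiplicatively (so the
#' natural log is the linear scale), a shared unmeasured confounder, and
#' optional horizontally pleiotropic SNPs that hit the outcome directly.
#'
#' @param n_per_stratum Named integer vector of stratum sizes, e.g.
#'   `c(SA = 1000, WE = 1000)`. Each must be >= 2.
#' @param m_snps Number of SNPs (> 0), assigned round-robin to chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param maf_range_per_stratum Named list of length-2 MAF ranges in (0, 0.5],
#'   one per stratum; per-SNP target MAFs are drawn uniformly inside.
#' @param relatedness List with `n_families` (count of related pairs per
#'   stratum) and `kinship` (coefficient in `[0, 0.5]`; 0.25 = full sibs).
#' @param metabolites List of [metabolite_architecture()] objects.
#' @param causal_effects Causal metabolite-to-glucose effects on the log
#'   outcome scale: either a single named list
#'   `list(met = c(fasting = b1, two_hour = b2), ...)` applied to both strata,
#'   or a list of such lists keyed by stratum for stratum-specific causality.
#' @param confounder_sd Standard deviation of the shared confounder U (>= 0).
#' @param confounder_loadings Named numeric vector of loadings of U on
#'   `metabolite` (every metabolite), `fasting`, `two_hour`, `bmi`,
#'   `maternal_age` (any subset; missing entries default to 0).
#' @param pleiotropy Tibble or data.frame with columns `snp_id`,
#'   `outcome` (`"fasting"`/`"two_hour"`) and `direct_effect` (per-allele
#'   effect on the log outcome bypassing all metabolites). May be `NULL`.
#' @param glucose_meds Length-2 vector of target medians (mmol/L) for fasting
#'   and 2-hour glucose; defaults near the clinical range.
#' @param outcome_sd Residual SD of the log-scale glucose outcomes.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_per_stratum = c(SA = 1000, WE = 1000),
                          m_snps = 200,
                          n_chromosomes = 10,
                          maf_range_per_stratum = NULL,
                          relatedness = list(n_families = 0, kinship = 0.25),
                          metabolites = list(),
                          causal_effects = list(),
                          confounder_sd = 1,
                          confounder_loadings = c(),
                          pleiotropy = NULL,
                          glucose_meds = c(fasting = 4.5, two_hour = 6.0),
                          outcome_sd = 0.12,
                          seed = 1L) {
  if (is.null(names(n_per_stratum))) {
    names(n_per_stratum) <- paste0("S", seq_along(n_per_stratum))
  }
  if (any(n_per_stratum < 2)) {
    rlang::abort("every stratum needs n >= 2.")
  }
  if (m_snps < 1) rlang::abort("`m_snps` must be >= 1.")
  if (n_chromosomes < 1) rlang::abort("`n_chromosomes` must be >= 1.")
  if (is.null(maf_range_per_stratum)) {
    maf_range_per_stratum <- lapply(n_per_stratum, function(...) c(0.05, 0.5))
    names(maf_range_per_stratum) <- names(n_per_stratum)
  }
  if (!setequal(names(maf_range_per_stratum), names(n_per_stratum))) {
    rlang::abort("`maf_range_per_stratum` must be keyed by stratum name.")
  }
  for (rg in maf_range_per_stratum) {
    if (length(rg) != 2 || rg[1] <= 0 || rg[2] > 0.5 || rg[1] > rg[2]) {
      rlang::abort("MAF ranges must lie in (0, 0.5] with lo <= hi.")
    }
  }
  if (relatedness$kinship < 0 || relatedness$kinship > 0.5) {
    rlang::abort("`kinship` must be in [0, 0.5].")
  }
  if (any(2 * relatedness$n_families > n_per_stratum)) {
    rlang::abort("2 * n_families cannot exceed the stratum size.")
  }
  met_names <- vapply(metabolites, `[[`, character(1), "name")
  if (anyDuplicated(met_names)) rlang::abort("duplicate metabolite names.")
  # causal_effects: normalise to one map per stratum
  strata <- names(n_per_stratum)
  per_stratum <- length(causal_effects) > 0 &&
    all(names(causal_effects) %in% strata) &&
    all(vapply(causal_effects, is.list, logical(1)))
  if (!per_stratum) {
    causal_effects <- stats::setNames(
      rep(list(causal_effects), length(strata)), strata
    )
  } else {
    missing <- setdiff(strata, names(causal_effects))
    causal_effects[missing] <- list(list())
  }
  for (st in strata) {
    bad <- setdiff(names(causal_effects[[st]]), met_names)
    if (length(bad)) {
      rlang::abort(paste0("causal_effects name unknown metabolite(s): ",
                          paste(bad, collapse = ", ")))
    }
  }
  if (confounder_sd < 0) rlang::abort("`confounder_sd` must be >= 0.")
  if (!is.null(pleiotropy)) {
    pleiotropy <- tibble::as_tibble(pleiotropy)
    stopifnot(all(c("snp_id", "outcome", "direct_effect") %in% names(pleiotropy)))
    if (!all(pleiotropy$outcome %in% c("fasting", "two_hour"))) {
      rlang::abort("pleiotropy outcome must be 'fasting' or 'two_hour'.")
    }
  }
  structure(
    list(
      n_per_stratum = n_per_stratum, m_snps = as.integer(m_snps),
      n_chromosomes = as.integer(n_chromosomes),
      maf_range_per_stratum = maf_range_per_stratum,
      relatedness = relatedness, metabolites = metabolites,
      causal_effects = causal_effects, confounder_sd = confounder_sd,
      confounder_loadings = confounder_loadings, pleiotropy = pleiotropy,
      glucose_meds = glucose_meds, outcome_sd = outcome_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
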