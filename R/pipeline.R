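#' Run the full metabolite-MR pipeline on a simulated (or supplied) cohort
#'
#' End-to-end, per stratum: metabolite preparation (IQR outlier masking +
#' normalising transform), outcome log-normalisation and GDM flagging,
#' genotype PCA, MLMA association scan for every metabolite with parity +
#' PC1 + PC2 as covariates and a leave-one-chromosome-out GRM, suggestive-SNP
#' selection with LD thinning within metabolite class, GRS construction,
#' TSLS against log fasting and log 2-hour glucose with Wu-Hausman and
#' first-stage diagnostics, composite-class exposures where eligible, and
#' post-hoc power inputs (observational estimates).
#'
#' @param cohort A list as returned by [simulate_cohort()] (components
#'   `genotypes`, `phenotypes`), or a [cohort_config()] to simulate first.
#' @param metabolite_cols Metabolite column names; defaults to the simulated
#'   architecture names when a config is supplied.
#' @param class_map Tibble `metabolite`/`class_label`; defaults to the
#'   simulated architecture.
#' @param maf_min,r2_max,suggestive_p Pipeline thresholds.
#' @param iqr_multiplier,transform_policy Metabolite preparation settings.
#' @param grm_policy GRM handling for the scans.
#' @param run_composites Whether to run the composite-class stage.
#' @return A `gest_mr_results` list: `mr` (tidy tibble over stratum x
#'   metabolite x outcome), `gwas` (nested), `instruments`, `inflation`,
#'   `composites`, `prep_report`, `pca`, `observational`.
#' @export
run_mr_pipeline <- function(cohort,
                            metabolite_cols = NULL,
                            class_map = NULL,
                            maf_min = 0.05, r2_max = 0.2,
                            suggestive_p = 1e-5,
                            iqr_multiplier = 1.5,
                            transform_policy = "auto",
                            grm_policy = "loo_chromosome",
                            run_composites = TRUE) {
  if (inherits(cohort, "cohort_config")) {
    config <- cohort
    cohort <- simulate_cohort(config)
    if (is.null(metabolite_cols)) {
      metabolite_cols <- vapply(config$metabolites, `[[`, character(1), "name")
    }
    if (is.null(class_map)) {
      class_map <- tibble::tibble(
        metabolite = metabolite_cols,
        class_label = vapply(config$metabolites, `[[`, character(1), "class_label")
      )
    }
  }
  stopifnot(!is.null(metabolite_cols), !is.null(class_map))

  prep <- prep_metabolites(cohort$phenotypes, metabolite_cols,
                           iqr_multiplier = iqr_multiplier,
                           transform_policy = transform_policy)
  phen <- prep$phenotypes
  outc <- prepare_outcomes(phen$fasting, phen$two_hour)
  phen$log_fasting <- outc$log_fasting
  phen$log_two_hour <- outc$log_two_hour
  phen$gdm <- outc$gdm

  strata <- names(cohort$genotypes)
  gwas_all <- list(); inst_all <- list(); mr_rows <- list()
  inflation <- list(); pca_all <- list(); comp_rows <- list()
  obs_rows <- list()
  for (st in strata) {
    geno <- cohort$genotypes[[st]]
    idx <- which(phen$stratum == st)
    ph <- phen[idx, ]
    pca <- genotype_pca(geno, 2, maf_min = maf_min)
    pca_all[[st]] <- pca
    covs <- cbind(parity = ph$parity,
                  PC1 = pca$scores$PC1, PC2 = pca$scores$PC2)
    cache <- new.env(parent = emptyenv())

    gwas_st <- list()
    for (met in metabolite_cols) {
      keep <- !is.na(ph[[met]])
      gw <- mlma_scan(
        ph[[met]][keep], covs[keep, , drop = FALSE],
        subset_samples(geno, keep),
        grm_policy = grm_policy, maf_min = maf_min,
        eigen_cache = if (all(keep)) cache else NULL
      )
      gwas_st[[met]] <- flag_thresholds(gw, suggestive_p = suggestive_p)
    }
    gwas_all[[st]] <- gwas_st
    inflation[[st]] <- dplyr::bind_rows(
      lapply(gwas_st, genomic_inflation), .id = "metabolite"
    )

    insts <- select_and_thin(gwas_st, class_map, geno,
                             r2_max = r2_max, suggestive_p = suggestive_p)
    inst_all[[st]] <- insts
    for (met in names(insts)) {
      grs <- genetic_risk_score(insts[[met]], geno)
      for (oc in c("log_fasting", "log_two_hour")) {
        keep <- !is.na(ph[[met]])
        est <- mr_tsls(ph[[oc]][keep], ph[[met]][keep], grs[keep],
                       exposure_name = met, outcome_name = oc)
        mr_rows[[length(mr_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(stratum = st,
                         class_label = insts[[met]]$class_label),
          tidy(est)
        )
      }
      obs_rows[[length(obs_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(stratum = st, metabolite = met),
        observational_estimates(
          dplyr::mutate(ph, .oc = ph$log_fasting), ".oc", met
        )
      )
    }

    if (run_composites) {
      for (cl in unique(class_map$class_label)) {
        mets <- intersect(class_map$metabolite[class_map$class_label == cl],
                          metabolite_cols)
        comp <- build_composite(ph[, mets, drop = FALSE], class_label = cl)
        row <- tibble::tibble(
          stratum = st, class_label = cl, n_members = length(comp$members),
          pc1_variance_fraction = comp$pc1_variance_fraction,
          eligible = comp$eligible
        )
        if (comp$eligible) {
          # GWAS of the PC1 scores once; reuse the instrument for both outcomes
          cm <- composite_mr(comp, geno, ph$log_fasting, covariates = covs,
                             maf_min = maf_min, r2_max = r2_max,
                             suggestive_p = suggestive_p,
                             grm_policy = grm_policy,
                             outcome_name = "log_fasting")
          if (!is.null(cm$estimate)) {
            okc <- !is.na(comp$scores)
            grs_c <- genetic_risk_score(cm$instrument, subset_samples(geno, okc))
            est2 <- mr_tsls(ph$log_two_hour[okc], comp$scores[okc], grs_c,
                            exposure_name = paste0(cl, "_PC1"),
                            outcome_name = "log_two_hour")
            for (est in list(cm$estimate, est2)) {
              comp_rows[[length(comp_rows) + 1L]] <- dplyr::bind_cols(
                row, tidy(est)[, c("outcome", "estimate", "std.error",
                                   "conf.low", "conf.high",
                                   "f_statistic", "wu_hausman_p")]
              )
            }
          } else {
            comp_rows[[length(comp_rows) + 1L]] <- row
          }
        } else {
          comp_rows[[length(comp_rows) + 1L]] <- row
        }
      }
    }
  }
  structure(
    list(
      mr = dplyr::bind_rows(mr_rows),
      gwas = gwas_all,
      instruments = inst_all,
      inflation = inflation,
      composites = dplyr::bind_rows(comp_rows),
      prep_report = prep$report,
      pca = pca_all,
      observational = dplyr::bind_rows(obs_rows),
      phenotypes = phen
    ),
    class = "gest_mr_results"
  )
}

#' @export
print.gest_mr_results <- function(x, ...) {
  cat(sprintf(
    "<gest_mr_results> %d MR estimates (%d strata); %d composite rows\n",
    nrow(x$mr), length(x$gwas), nrow(x$composites)
  ))
  print(x$mr, n = 10)
  invisible(x)
}
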