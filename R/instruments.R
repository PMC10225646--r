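#' Select suggestive SNPs and thin them by LD within a metabolite class
#'
#' Pools every metabolite's suggestive SNPs (`p <= suggestive_p`) within each
#' class, orders them by ascending p (ties broken by chromosome then
#' position), and greedily keeps a SNP iff its in-sample dosage r-squared
#' against every already-kept SNP is below `r2_max`. Each metabolite's
#' instrument is then the kept SNPs among its own suggestive hits, weighted
#' by its own GWAS betas. Metabolites with no surviving SNP get no instrument
#' and are reported in the audit.
#'
#' @param records Named list of per-metabolite association tibbles (from
#'   [mlma_scan()], one per metabolite) for one stratum.
#' @param class_map Tibble with `metabolite`, `class_label`.
#' @param genotypes `gest_genotypes` used for in-sample LD.
#' @param r2_max LD threshold (kept pairs satisfy r2 < r2_max).
#' @param suggestive_p Selection threshold (inclusive).
#' @return List of `gest_instrument` objects keyed by metabolite (each: a
#'   list with `exposure`, `class_label`, `snps` tibble of
#'   `snp_id`/`effect_allele`/`weight`, `audit`), plus an `audit` attribute
#'   listing metabolites without instruments.
#' @export
select_and_thin <- function(records, class_map, genotypes,
                            r2_max = 0.2, suggestive_p = 1e-5) {
  stopifnot(all(names(records) %in% class_map$metabolite))
  G <- dosage_matrix(genotypes)
  instruments <- list()
  no_instrument <- character()
  for (cl in unique(class_map$class_label)) {
    mets <- intersect(class_map$metabolite[class_map$class_label == cl],
                      names(records))
    if (!length(mets)) next
    pooled <- dplyr::bind_rows(lapply(mets, function(m) {
      r <- records[[m]]
      r <- r[r$p <= suggestive_p, , drop = FALSE]
      if (nrow(r)) r$metabolite <- m
      r
    }))
    if (!nrow(pooled)) {
      no_instrument <- c(no_instrument, mets)
      next
    }
    # best p per SNP decides the thinning order over the pooled class list
    order_tbl <- pooled |>
      dplyr::group_by(.data$snp_id) |>
      dplyr::summarise(p = min(.data$p), chr = .data$chr[1], pos = .data$pos[1],
                       .groups = "drop") |>
      dplyr::arrange(.data$p, .data$chr, .data$pos)
    kept <- character()
    for (id in order_tbl$snp_id) {
      ok <- TRUE
      for (kid in kept) {
        r2 <- ld_r2(G, id, kid)
        if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, id)
    }
    for (m in mets) {
      mine <- pooled[pooled$metabolite == m & pooled$snp_id %in% kept, ,
                     drop = FALSE]
      if (!nrow(mine)) {
        no_instrument <- c(no_instrument, m)
        next
      }
      instruments[[m]] <- structure(
        list(
          exposure = m, class_label = cl,
          snps = tibble::tibble(
            snp_id = mine$snp_id, effect_allele = mine$effect_allele,
            weight = mine$beta, p = mine$p
          ),
          audit = tibble::tibble(
            class_label = cl, n_suggestive = sum(pooled$metabolite == m),
            n_kept = nrow(mine), r2_max = r2_max
          )
        ),
        class = "gest_instrument"
      )
    }
  }
  attr(instruments, "no_instrument") <- unique(no_instrument)
  instruments
}

#' @export
print.gest_instrument <- function(x, ...) {
  cat(sprintf("<gest_instrument> %s (%s): %d SNPs\n",
              x$exposure, x$class_label, nrow(x$snps)))
  invisible(x)
}

#' Weighted genetic risk score
#'
#' `GRS_i = sum_j w_j * dosage_ij` with the GWAS betas as weights; missing
#' dosages are mean-imputed per SNP.
#'
#' @param instrument `gest_instrument` (or tibble with `snp_id`, `weight`).
#' @param genotypes `gest_genotypes` or dosage matrix containing every
#'   instrument SNP.
#' @return Numeric vector, one score per individual.
#' @export
genetic_risk_score <- function(instrument, genotypes) {
  snps <- if (inherits(instrument, "gest_instrument")) instrument$snps else
    tibble::as_tibble(instrument)
  G <- dosage_matrix(genotypes)
  missing <- setdiff(snps$snp_id, colnames(G))
  if (length(missing)) {
    rlang::abort(paste0("instrument SNP(s) absent from genotypes: ",
                        paste(missing, collapse = ", ")))
  }
  X <- G[, snps$snp_id, drop = FALSE]
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  unname(drop(X %*% snps$weight))
}

#' First-stage strength of a genetic risk score
#'
#' OLS of the exposure on the GRS (plus covariates); returns the partial F
#' for the GRS term, the partial r-squared, and the conventional weak
#' instrument flag `F < 10`.
#'
#' @param exposure Numeric vector.
#' @param grs Numeric vector from [genetic_risk_score()].
#' @param covariates Optional covariate matrix/data.frame.
#' @return List: `f`, `r2_first`, `n`, `weak` (logical), `coef` (GRS slope).
#' @export
first_stage <- function(exposure, grs, covariates = NULL) {
  ok <- stats::complete.cases(exposure, grs)
  x <- exposure[ok]; z <- grs[ok]
  C <- design_matrix(if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE], length(x))
  if (stats::var(z) == 0) rlang::abort("zero-variance GRS.")
  n <- length(x)
  if (n <= ncol(C) + 2) rlang::abort("too few observations for a first stage.")
  fit0 <- stats::lm.fit(C, x)
  fit1 <- stats::lm.fit(cbind(C, grs = z), x)
  rss0 <- sum(fit0$residuals^2); rss1 <- sum(fit1$residuals^2)
  df2 <- n - ncol(C) - 1
  f <- (rss0 - rss1) / (rss1 / df2)
  list(
    f = f, r2_first = (rss0 - rss1) / rss0, n = n,
    weak = f < 10, coef = unname(fit1$coefficients["grs"])
  )
}
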