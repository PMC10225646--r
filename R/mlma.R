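#' REML variance components for a phenotype with a polygenic random effect
#'
#' Fits `y = C gamma + u + e` with `u ~ N(0, A sigma2_g)`,
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood. The likelihood is
#' profiled down to the single variance ratio `lambda = sigma2_g / sigma2_e`
#' using one eigendecomposition of the GRM, then optimised in 1-D on the log
#' scale; `sigma2_e` is recovered from the weighted residual sum of squares.
#' A ratio pinned at the lower boundary (no genetic variance) is reported,
#' not treated as failure. A GRM numerically equal to the identity makes the
#' two components non-identifiable; the fit is then flagged.
#'
#' @param phenotype Numeric vector, no missing values.
#' @param covariates Numeric matrix/data.frame of covariates or `NULL`; an
#'   intercept is always added.
#' @param grm A `gest_grm`, a bare symmetric matrix, or a precomputed
#'   eigendecomposition (list with `values`, `vectors`).
#' @return List: `sigma2_g`, `sigma2_e`, `h2` (ratio of genetic to total),
#'   `loglik` (restricted, up to a constant), `boundary` (logical),
#'   `identifiable` (logical).
#' @export
reml_variance_components <- function(phenotype, covariates = NULL, grm) {
  y <- as.numeric(phenotype)
  if (anyNA(y)) rlang::abort("phenotype must be complete (drop NAs upstream).")
  C <- design_matrix(covariates, length(y))
  if (qr(C)$rank < ncol(C)) rlang::abort("covariates are rank deficient.")
  eig <- grm_eigen(grm)
  identifiable <- !(max(abs(eig$values - eig$values[1])) < 1e-10)
  fit <- reml_profile(y, C, eig)
  c(fit, list(identifiable = identifiable))
}

design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  C <- as.matrix(covariates)
  storage.mode(C) <- "double"
  cbind(intercept = 1, C)
}

grm_eigen <- function(grm) {
  if (is.list(grm) && !is.null(grm$vectors) && !is.null(grm$values)) return(grm)
  A <- if (inherits(grm, "gest_grm")) grm$A else as.matrix(grm)
  eigen(A, symmetric = TRUE)
}

# profiled REML over log(lambda); rotated representation
reml_profile <- function(y, C, eig, log_lambda_bounds = c(-12, 8)) {
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ys <- drop(crossprod(U, y))
  Cs <- crossprod(U, C)
  n <- length(ys); p <- ncol(Cs)
  neg2_reml <- function(log_lambda) {
    w <- exp(log_lambda) * d + 1
    sw <- sqrt(w)
    yw <- ys / sw
    Cw <- Cs / sw
    fit <- stats::lm.fit(Cw, yw)
    rss <- sum(fit$residuals^2)
    XtX <- crossprod(Cw)
    (n - p) * log(rss / (n - p)) + sum(log(w)) + determinant(XtX)$modulus[1]
  }
  opt <- stats::optimize(neg2_reml, log_lambda_bounds, tol = 1e-7)
  lambda <- exp(opt$minimum)
  boundary <- opt$minimum <= log_lambda_bounds[1] + 1e-3
  if (boundary) lambda <- 0
  w <- lambda * d + 1
  sw <- sqrt(w)
  fit <- stats::lm.fit(Cs / sw, ys / sw)
  sigma2_e <- sum(fit$residuals^2) / (n - p)
  sigma2_g <- lambda * sigma2_e
  list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    h2 = sigma2_g / (sigma2_g + sigma2_e),
    lambda = lambda, loglik = -0.5 * opt$objective, boundary = boundary
  )
}

# standardised-genotype cross-product contributions per chromosome, so that
# leave-one-chromosome-out GRMs are cheap: A_loco = (K_all - K_chr)/(m - m_chr)
grm_parts <- function(geno, maf_min) {
  G <- dosage_matrix(geno)
  sd_ <- standardise_dosages(G, maf_min)
  chr <- geno$snps$chr[sd_$keep]
  parts <- lapply(split(seq_len(ncol(sd_$Z)), chr), function(j) {
    list(K = tcrossprod(sd_$Z[, j, drop = FALSE]), m = length(j))
  })
  K_all <- Reduce(`+`, lapply(parts, `[[`, "K"))
  list(parts = parts, K_all = K_all, m_all = ncol(sd_$Z))
}

#' Mixed-linear-model association scan
#'
#' Per-SNP association between a phenotype and allele dosage under a
#' polygenic random effect: for each SNP, a generalised-least-squares fixed
#' effect with covariance `V = A sigma2_g + I sigma2_e`. Variance components
#' are estimated once per (phenotype, left-out chromosome) under the no-SNP
#' null model and reused across that chromosome's SNPs; the GRM is rebuilt
#' with the tested SNP's chromosome excluded (`grm_policy = "loo_chromosome"`,
#' the default) so a SNP never sits in the fixed and random effects at once.
#' `"loo_snp"` excludes only the tested SNP (exact but O(n^3) per SNP, for
#' small problems); `"global"` keeps every SNP in the GRM. SNPs with
#' `maf < maf_min` are excluded before anything else; the default 0.05
#' reflects the least stringent cut-off that keeps the genomic inflation
#' factor near 1 in this design.
#'
#' @param phenotype Numeric vector aligned with the genotype rows.
#' @param covariates Covariate matrix/data.frame (e.g. parity, PC1, PC2) or
#'   `NULL`; an intercept is always included.
#' @param genotypes A `gest_genotypes`.
#' @param grm_policy `"loo_chromosome"`, `"loo_snp"` or `"global"`.
#' @param maf_min MAF filter for tested SNPs and for the GRM.
#' @param eigen_cache Optional environment used to memoise per-chromosome GRM
#'   eigendecompositions across phenotypes that share genotypes + covariates.
#' @return Tibble of association records: `snp_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`, `n`, `beta`, `se`, `p`, with the
#'   per-chromosome variance components in `attr(, "variance_components")`.
#' @export
mlma_scan <- function(phenotype, covariates = NULL, genotypes,
                      grm_policy = c("loo_chromosome", "loo_snp", "global"),
                      maf_min = 0.05, eigen_cache = NULL) {
  grm_policy <- match.arg(grm_policy)
  G <- dosage_matrix(genotypes)
  y <- as.numeric(phenotype)
  stopifnot(length(y) == nrow(G))
  C <- design_matrix(covariates, length(y))
  maf_tbl <- compute_maf(genotypes)
  keep <- which(maf_tbl$maf >= maf_min & maf_tbl$maf > 0)
  if (!length(keep)) rlang::abort("no SNP passes the MAF filter.")
  snps <- genotypes$snps[keep, , drop = FALSE]
  snps$maf <- maf_tbl$maf[keep]
  Gk <- G[, keep, drop = FALSE]
  if (anyNA(Gk)) {
    for (j in seq_len(ncol(Gk))) {
      nas <- is.na(Gk[, j])
      if (any(nas)) Gk[nas, j] <- mean(Gk[, j], na.rm = TRUE)
    }
  }
  parts <- grm_parts(genotypes, maf_min)
  n <- length(y)

  if (grm_policy == "loo_snp") {
    return(mlma_scan_loo_snp(y, C, Gk, snps, parts, n))
  }

  chr_groups <- split(seq_len(nrow(snps)), snps$chr)
  vc_list <- list()
  res <- vector("list", length(chr_groups))
  for (gi in seq_along(chr_groups)) {
    c_ <- names(chr_groups)[gi]
    idx <- chr_groups[[gi]]
    eig <- NULL
    cache_key <- paste0("chr", if (grm_policy == "global") "ALL" else c_)
    if (!is.null(eigen_cache) && !is.null(eigen_cache[[cache_key]])) {
      eig <- eigen_cache[[cache_key]]
    } else {
      A <- if (grm_policy == "global") {
        parts$K_all / parts$m_all
      } else {
        pc <- parts$parts[[c_]]
        if (is.null(pc) || parts$m_all - pc$m < 1) {
          parts$K_all / parts$m_all   # nothing to leave out
        } else {
          (parts$K_all - pc$K) / (parts$m_all - pc$m)
        }
      }
      eig <- eigen(A, symmetric = TRUE)
      if (!is.null(eigen_cache)) eigen_cache[[cache_key]] <- eig
    }
    fit <- reml_profile(y, C, eig)
    vc_list[[c_]] <- fit
    res[[gi]] <- gls_chunk(y, C, Gk[, idx, drop = FALSE], eig, fit)
  }
  out <- dplyr::bind_cols(
    snps[unlist(chr_groups, use.names = FALSE),
         c("snp_id", "chr", "pos", "effect_allele", "other_allele", "maf")],
    dplyr::bind_rows(res)
  )
  out$n <- n
  out <- dplyr::arrange(out, .data$chr, .data$pos)
  out <- out[, c("snp_id", "chr", "pos", "effect_allele", "other_allele",
                 "maf", "n", "beta", "se", "p")]
  attr(out, "variance_components") <- vc_list
  out
}

# GLS per SNP on eigen-rotated data with fixed variance components:
# V = sigma2_e * (lambda * A + I); block inversion over the covariates
gls_chunk <- function(y, C, Gchunk, eig, fit) {
  U <- eig$vectors
  sw <- sqrt(fit$lambda * pmax(eig$values, 0) + 1)
  yw <- drop(crossprod(U, y)) / sw
  Cw <- crossprod(U, C) / sw
  Gw <- crossprod(U, Gchunk) / sw
  S <- solve(crossprod(Cw))
  Cty <- drop(crossprod(Cw, yw))
  Ctg <- crossprod(Cw, Gw)                  # p x m
  gty <- drop(crossprod(Gw, yw))
  gtg <- colSums(Gw^2)
  SCtg <- S %*% Ctg
  qform <- gtg - colSums(Ctg * SCtg)        # Schur complement per SNP
  num <- gty - drop(crossprod(Ctg, S %*% Cty))
  beta <- unname(num / qform)
  se <- unname(sqrt(fit$sigma2_e / qform))
  z <- beta / se
  tibble::tibble(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

# exact per-SNP GRM exclusion via dense GLS solves; small problems only
mlma_scan_loo_snp <- function(y, C, Gk, snps, parts, n) {
  out <- vector("list", nrow(snps))
  for (j in seq_len(nrow(snps))) {
    # rebuild the GRM without SNP j (self-contribution removed exactly)
    x <- Gk[, j]
    p <- mean(x) / 2
    z <- (x - 2 * p) / sqrt(2 * p * (1 - p))
    K <- parts$K_all - tcrossprod(z)
    A <- K / (parts$m_all - 1)
    eig <- eigen(A, symmetric = TRUE)
    fit <- reml_profile(y, C, eig)
    out[[j]] <- gls_chunk(y, C, Gk[, j, drop = FALSE], eig, fit)
  }
  res <- dplyr::bind_cols(
    snps[, c("snp_id", "chr", "pos", "effect_allele", "other_allele", "maf")],
    dplyr::bind_rows(out)
  )
  res$n <- n
  res[, c("snp_id", "chr", "pos", "effect_allele", "other_allele",
          "maf", "n", "beta", "se", "p")]
}

#' Genomic inflation factors by MAF bin
#'
#' `lambda = median((beta/se)^2) / 0.4549` per MAF bin, the median of the
#' association chi-squares over the null median `qchisq(0.5, 1)`. Bins follow
#' the fixed scheme `<0.001, [0.001,0.005), [0.005,0.01), [0.01,0.05),
#' [0.05,0.1), >=0.1`; `lambda >= 1.1` flags inflation. Empty bins are
#' omitted; bins with fewer than `min_snps` records are reported but flagged
#' unreliable.
#'
#' @param records Association tibble from [mlma_scan()] (needs `maf`, `beta`,
#'   `se`).
#' @param min_snps Minimum records per bin for a reliable estimate.
#' @return Tibble: `maf_bin`, `n_snps`, `lambda`, `inflated`, `reliable`.
#' @export
genomic_inflation <- function(records, min_snps = 20) {
  breaks <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)
  labels <- c("<0.001", "[0.001,0.005)", "[0.005,0.01)", "[0.01,0.05)",
              "[0.05,0.1)", ">=0.1")
  bin <- cut(records$maf, breaks, labels = labels, right = FALSE,
             include.lowest = TRUE)
  chisq <- (records$beta / records$se)^2
  out <- tibble::tibble(maf_bin = bin, chisq = chisq) |>
    dplyr::filter(!is.na(.data$maf_bin)) |>
    dplyr::group_by(.data$maf_bin) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      lambda = stats::median(.data$chisq) / stats::qchisq(0.5, 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      inflated = .data$lambda >= 1.1,
      reliable = .data$n_snps >= min_snps
    )
  out$maf_bin <- as.character(out$maf_bin)
  out
}

#' Flag suggestive and genome-wide significant associations
#'
#' Suggestive significance is inclusive (`p <= 1e-5`); genome-wide
#' significance is strict (`p < 5e-8`).
#'
#' @param records Association tibble with a `p` column.
#' @param suggestive_p,gws_p Thresholds.
#' @return The records with logical `suggestive` and `gws` columns added.
#' @export
flag_thresholds <- function(records, suggestive_p = 1e-5, gws_p = 5e-8) {
  dplyr::mutate(
    records,
    suggestive = .data$p <= suggestive_p,
    gws = .data$p < gws_p
  )
}
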