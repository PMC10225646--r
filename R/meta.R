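#' Harmonise effect alleles between two association records
#'
#' Aligns record B onto record A's allele coding: if the effect/other alleles
#' are swapped, B's beta is sign-flipped and its effect-allele frequency
#' complemented. Strand-ambiguous (A/T or C/G) SNPs are kept but flagged;
#' allele pairs that cannot be reconciled are excluded with a reason.
#'
#' @param record_a,record_b One-row tibbles (or lists) with `snp_id`,
#'   `effect_allele`, `other_allele`, `beta` and optionally `eaf`.
#' @return List: `a`, `b` (aligned), `ambiguous` (logical), `excluded`
#'   (logical), `reason`.
#' @export
harmonise_alleles <- function(record_a, record_b) {
  a <- as.list(record_a); b <- as.list(record_b)
  if (a$snp_id != b$snp_id) rlang::abort("records refer to different SNPs.")
  pal <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "CG", "GC")
  }
  ambiguous <- pal(a$effect_allele, a$other_allele)
  same <- a$effect_allele == b$effect_allele && a$other_allele == b$other_allele
  swapped <- a$effect_allele == b$other_allele && a$other_allele == b$effect_allele
  if (!same && !swapped) {
    return(list(a = a, b = b, ambiguous = ambiguous, excluded = TRUE,
                reason = "incompatible allele pairs"))
  }
  if (swapped) {
    b$beta <- -b$beta
    if (!is.null(b$eaf)) b$eaf <- 1 - b$eaf
    tmp <- b$effect_allele; b$effect_allele <- b$other_allele; b$other_allele <- tmp
  }
  list(a = a, b = b, ambiguous = ambiguous, excluded = FALSE, reason = NA_character_)
}

#' Fixed-effect inverse-variance meta-analysis of stratum estimates
#'
#' Weights `w_i = 1 / se_i^2`; pooled `beta = sum(w b) / sum(w)`,
#' `se = sum(w)^(-1/2)`, Cochran's `Q = sum(w (b_i - beta)^2)` on `k - 1`
#' degrees of freedom, and `I2 = max(0, (Q - (k-1)) / Q) * 100` (floored at
#' zero, Higgins convention). Two-sided p from the normal approximation of
#' `beta / se`. With a single stratum the input is passed through and `I2`
#' reported missing.
#'
#' @param betas,ses Numeric vectors (one entry per stratum), `ses > 0`.
#' @param labels Optional stratum labels for the direction string.
#' @return One-row tibble: `k`, `beta_meta`, `se_meta`, `p_meta`, `q`, `df`,
#'   `i2`, `direction` (e.g. `"+-"`).
#' @export
ivw_meta <- function(betas, ses, labels = NULL) {
  stopifnot(length(betas) == length(ses))
  if (any(ses <= 0)) rlang::abort("all standard errors must be > 0.")
  k <- length(betas)
  direction <- paste(ifelse(betas >= 0, "+", "-"), collapse = "")
  if (k == 1L) {
    return(tibble::tibble(
      k = 1L, beta_meta = betas, se_meta = ses,
      p_meta = 2 * stats::pnorm(-abs(betas / ses)),
      q = NA_real_, df = 0L, i2 = NA_real_, direction = direction
    ))
  }
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (betas - beta)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  tibble::tibble(
    k = k, beta_meta = beta, se_meta = se,
    p_meta = 2 * stats::pnorm(-abs(beta / se)),
    q = q, df = k - 1L, i2 = i2, direction = direction
  )
}

#' Meta-analyse two per-stratum GWAS tables SNP-by-SNP
#'
#' Harmonises alleles onto the first table's coding, then applies
#' [ivw_meta()] per shared SNP.
#'
#' @param gwas_a,gwas_b Association tibbles from [mlma_scan()].
#' @param labels Stratum labels, used in the direction string.
#' @return Tibble keyed by `snp_id` with the [ivw_meta()] columns plus
#'   `ambiguous` and per-stratum betas/ses.
#' @export
meta_analyse_gwas <- function(gwas_a, gwas_b, labels = c("A", "B")) {
  shared <- intersect(gwas_a$snp_id, gwas_b$snp_id)
  rows <- lapply(shared, function(id) {
    ra <- gwas_a[gwas_a$snp_id == id, ][1, ]
    rb <- gwas_b[gwas_b$snp_id == id, ][1, ]
    h <- harmonise_alleles(ra, rb)
    if (h$excluded) return(NULL)
    m <- ivw_meta(c(h$a$beta, h$b$beta), c(h$a$se, h$b$se), labels)
    dplyr::bind_cols(
      tibble::tibble(snp_id = id, ambiguous = h$ambiguous,
                     beta_a = h$a$beta, se_a = h$a$se,
                     beta_b = h$b$beta, se_b = h$b$se),
      m
    )
  })
  dplyr::bind_rows(rows)
}
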