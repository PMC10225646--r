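#' QQ-plot data for an association scan
#'
#' Expected vs observed `-log10(p)` under the uniform null.
#'
#' @param records Association tibble with a `p` column.
#' @return Tibble: `expected`, `observed`, sorted.
#' @export
qq_data <- function(records) {
  p <- sort(records$p)
  n <- length(p)
  tibble::tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(p)
  )
}

#' QQ plot of association p-values
#'
#' @param records Association tibble from [mlma_scan()].
#' @return A ggplot.
#' @export
plot_qq <- function(records) {
  d <- qq_data(records)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a leave-one-out sensitivity analysis
#'
#' @param loo Tibble from [mr_leave_one_out()].
#' @param full Optional full-instrument `mr_estimate` drawn as a reference
#'   line.
#' @return A ggplot.
#' @export
plot_forest <- function(loo, full = NULL) {
  p <- ggplot2::ggplot(
    loo,
    ggplot2::aes(x = .data$beta_iv, y = .data$excluded_snp)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TSLS estimate (95% CI)", y = "Excluded SNP") +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(xintercept = full$beta_iv, colour = "steelblue")
  }
  p
}

#' Genotype PC scatter coloured by stratum
#'
#' @param pca Result of [genotype_pca()].
#' @param strata Character vector of stratum labels aligned with the scores.
#' @return A ggplot.
#' @export
plot_pca <- function(pca, strata) {
  d <- dplyr::mutate(pca$scores, stratum = strata)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$stratum)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
}
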