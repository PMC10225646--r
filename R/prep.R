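#' Mask IQR outliers in a metabolite series
#'
#' Tukey-fence outlier masking: values outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` become `NA`. Quartiles use type-7 linear
#' interpolation. Single pass: the fences are computed once from the input,
#' never re-estimated from the retained values. A constant series has zero
#' IQR, the fences collapse onto the constant, and nothing is masked (the
#' closed interval keeps exact equality).
#'
#' @param values Numeric vector (mmol/L); `NA`s are ignored and preserved.
#' @param multiplier Fence multiplier `k` (> 0); 1.5 is the standard fence,
#'   3 the stringent one.
#' @param anchor `"quartile"` for Tukey fences anchored at Q1/Q3 (default), or
#'   `"median"` for `median +/- k * IQR` bounds as used for the stringent
#'   composite-class screen.
#' @return List with `values` (input with outliers set `NA`), `n_masked`, and
#'   `bounds` (length-2 numeric).
#' @export
remove_outliers_iqr <- function(values, multiplier = 1.5,
                                anchor = c("quartile", "median")) {
  anchor <- match.arg(anchor)
  if (multiplier <= 0) rlang::abort("`multiplier` must be > 0.")
  ok <- !is.na(values)
  if (sum(ok) < 4) rlang::abort("need at least 4 non-missing values.")
  q <- stats::quantile(values[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  bounds <- switch(anchor,
    quartile = c(q[1] - multiplier * iqr, q[3] + multiplier * iqr),
    median   = c(q[2] - multiplier * iqr, q[2] + multiplier * iqr)
  )
  mask <- ok & (values < bounds[1] | values > bounds[2])
  values[mask] <- NA
  list(values = values, n_masked = sum(mask), bounds = bounds)
}

#' Normal-score (rank-based inverse normal) transform
#'
#' Maps rank `r` (ties get the average rank) to
#' `qnorm((r - 3/8) / (n + 1/4))` (Blom offsets), computed over the
#' non-missing values only.
#'
#' @param values Numeric vector.
#' @return Numeric vector of normal scores, `NA` where the input was `NA`.
#' @export
normal_score_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Distribution-normalising transform of a metabolite series
#'
#' Applies `log`, `sqrt` or the normal-score transform; `policy = "auto"`
#' picks whichever of the three (restricted to those applicable to the data's
#' sign) minimises the absolute sample skewness. Because the normal-score
#' transform makes the skewness essentially zero by construction, the
#' parametric transforms are preferred whenever they come within `skew_tol`
#' of the minimum — a log-normal metabolite is thus reported as `log`, and
#' the rank transform is reserved for shapes neither log nor sqrt can fix.
#' The selected transform is returned so a prep report can log it per
#' metabolite.
#'
#' @param values Numeric vector.
#' @param policy One of `"log"`, `"sqrt"`, `"nst"`, `"auto"`, `"none"`.
#' @param skew_tol Tolerance within which a parametric transform beats the
#'   rank-based one under `auto`.
#' @return List with `values`, `transform` (label actually applied) and
#'   `skewness` (after transformation).
#' @export
transform_metabolite <- function(values, policy = c("auto", "log", "sqrt", "nst", "none"),
                                 skew_tol = 0.05) {
  policy <- match.arg(policy)
  ok <- !is.na(values)
  apply_one <- function(tr) {
    switch(tr,
      log = {
        if (any(values[ok] <= 0)) {
          rlang::abort("log transform requires strictly positive values.")
        }
        log(values)
      },
      sqrt = {
        if (any(values[ok] < 0)) {
          rlang::abort("sqrt transform requires non-negative values.")
        }
        sqrt(values)
      },
      nst = normal_score_transform(values),
      none = values
    )
  }
  if (policy == "auto") {
    cands <- "nst"
    if (all(values[ok] >= 0)) cands <- c("sqrt", cands)
    if (all(values[ok] > 0)) cands <- c("log", cands)
    sk <- vapply(cands, function(tr) abs(sample_skewness(apply_one(tr))), numeric(1))
    policy <- cands[which(sk <= min(sk) + skew_tol)[1]]
  }
  out <- apply_one(policy)
  list(values = out, transform = policy, skewness = sample_skewness(out))
}

#' Prepare glucose outcomes: log-normalise and flag gestational diabetes
#'
#' Outcomes are natural-log transformed; the GDM flag follows the clinical
#' rule that a fasting glucose strictly above 6.1 mmol/L or a 2-hour
#' post-load glucose strictly above 7.8 mmol/L (75 g OGTT) indicates
#' gestational diabetes — values exactly at a threshold are not flagged.
#'
#' @param fasting,two_hour Positive numeric vectors (mmol/L).
#' @param fasting_thr,two_hour_thr Diagnostic thresholds in mmol/L.
#' @return Tibble: `log_fasting`, `log_two_hour`, `gdm` (logical).
#' @export
prepare_outcomes <- function(fasting, two_hour,
                             fasting_thr = 6.1, two_hour_thr = 7.8) {
  if (any(fasting <= 0, na.rm = TRUE) || any(two_hour <= 0, na.rm = TRUE)) {
    rlang::abort("glucose values must be positive for log-normalisation.")
  }
  tibble::tibble(
    log_fasting = log(fasting),
    log_two_hour = log(two_hour),
    gdm = (fasting > fasting_thr) | (two_hour > two_hour_thr)
  )
}

#' Prepare all metabolites of a phenotype table, per stratum
#'
#' For each metabolite column and each stratum separately: mask IQR outliers,
#' then apply the normalising transform. No statistic is ever pooled across
#' strata. Rows masked for one metabolite stay available for the others.
#'
#' @param phenotypes Tibble with `stratum` and the metabolite columns.
#' @param metabolite_cols Character vector of metabolite column names.
#' @param iqr_multiplier Fence multiplier for [remove_outliers_iqr()].
#' @param transform_policy Passed to [transform_metabolite()].
#' @param anchor Outlier-fence anchor, see [remove_outliers_iqr()].
#' @return List with `phenotypes` (same shape, metabolite columns replaced by
#'   their prepared versions) and `report` (tibble: stratum, metabolite,
#'   n_before, n_masked, transform, skewness).
#' @export
prep_metabolites <- function(phenotypes, metabolite_cols,
                             iqr_multiplier = 1.5,
                             transform_policy = "auto",
                             anchor = "quartile") {
  stopifnot("stratum" %in% names(phenotypes),
            all(metabolite_cols %in% names(phenotypes)))
  report <- list()
  out <- phenotypes
  for (st in unique(phenotypes$stratum)) {
    idx <- which(phenotypes$stratum == st)
    for (met in metabolite_cols) {
      v <- phenotypes[[met]][idx]
      masked <- remove_outliers_iqr(v, iqr_multiplier, anchor = anchor)
      tr <- transform_metabolite(masked$values, transform_policy)
      out[[met]][idx] <- tr$values
      report[[length(report) + 1L]] <- tibble::tibble(
        stratum = st, metabolite = met,
        n_before = sum(!is.na(v)), n_masked = masked$n_masked,
        transform = tr$transform, skewness = tr$skewness
      )
    }
  }
  list(phenotypes = out, report = dplyr::bind_rows(report))
}
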