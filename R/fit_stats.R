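#' Upper-tail chi-square probability
#'
#' @param chi2 chi-square statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return `P(X >= chi2)` for `X ~ chi-square(df)`.
#' @export
chi_square_p <- function(chi2, df) {
  stopifnot(all(chi2 >= 0), all(df >= 1))
  stats::pchisq(chi2, df, lower.tail = FALSE)
}

#' Structural-equation fit statistics of a factor solution
#'
#' Computes the likelihood-ratio chi-square `(n_effective - 1) * F_min`
#' (or `n * F` via `chi2_scale`), its df and p-value, and the standard
#' descriptive fit indices against the independence baseline
#' (`Sigma_b = I` for a correlation input, `F_b = -log|R|`,
#' `df_b = p(p-1)/2`):
#' * `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`
#' * `TLI = (chi2_b/df_b - chi2/df) / (chi2_b/df_b - 1)`
#' * `RMSEA = sqrt(max(chi2 - df, 0) / (df (n_effective - 1)))`
#' * `SRMR = sqrt(mean over i <= j of (r_ij - sigma_hat_ij)^2)`
#'
#' Any fit with `chi2 <= df` therefore reports `RMSEA = 0` and `CFI = 1`.
#' A solution with a uniqueness on the lower bound is flagged as a Heywood
#' case (`heywood = TRUE`). If `n_effective <= p` the test statistics are
#' reported as `NA` (the loadings remain usable).
#'
#' @param R the fitted [correlation_input()] (or matrix, in which case
#'   `n_effective` must be supplied).
#' @param model the converged `efa_model`.
#' @param mean_structure count indicator means among the free parameters?
#' @param n_effective effective sample size; defaults to the one carried
#'   by `R` or by the model.
#' @param chi2_scale `"n-1"` (default) or `"n"` multiplier for `F_min`.
#' @return object of class `fit_statistics`.
#' @export
fit_statistics <- function(R, model, mean_structure = FALSE,
                           n_effective = NULL, chi2_scale = c("n-1", "n")) {
  stopifnot(inherits(model, "efa_model"))
  chi2_scale <- match.arg(chi2_scale)
  Rm <- corr_matrix_of(R)
  p <- model$p; m <- model$m
  n_effective <- n_effective %||%
    (if (inherits(R, "correlation_input")) R$n_effective else model$n_effective)
  if (is.null(n_effective))
    stop_cogstruct("n_effective is required for test statistics",
                   "cogstruct_invalid_spec")

  df <- model_df(p, m)
  df_b <- p * (p - 1) / 2
  sigma_hat <- model$loadings %*% model$factor_corr %*% t(model$loadings) +
    diag(model$uniquenesses)
  resid <- Rm - sigma_hat
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  heywood <- any(model$uniquenesses <= model$psi_floor * (1 + 1e-6))
  n_free <- count_free_parameters(p, m, mean_structure)

  if (n_effective <= p) {
    return(structure(list(
      chi_square = NA_real_, df = df, p_value = NA_real_,
      cfi = NA_real_, tli = NA_real_, rmsea = NA_real_, srmr = srmr,
      n_free_params = n_free, heywood = heywood,
      n_effective = n_effective, baseline_chi_square = NA_real_,
      baseline_df = df_b,
      note = "n_effective <= p: test statistics undefined"
    ), class = "fit_statistics"))
  }

  scale_fac <- if (chi2_scale == "n-1") n_effective - 1 else n_effective
  chi2 <- scale_fac * model$discrepancy
  f_b <- -determinant(Rm, logarithm = TRUE)$modulus[1]
  chi2_b <- scale_fac * f_b

  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chi2_b / df_b
  tli <- (rb - chi2 / df) / (rb - 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n_effective - 1)))

  structure(list(
    chi_square = chi2, df = df, p_value = chi_square_p(chi2, df),
    cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr,
    n_free_params = n_free, heywood = heywood,
    n_effective = n_effective,
    baseline_chi_square = chi2_b, baseline_df = df_b,
    note = NULL
  ), class = "fit_statistics")
}

#' Qualitative label for a factor loading
#'
#' Bands the absolute loading by the conventional guideline cut points
#' 0.32, 0.45, 0.55, 0.63 and 0.71: below 0.45 "poor" (0.32 being the
#' minimum salient loading worth interpreting at all), then "fair",
#' "good", "very good", and "excellent" from 0.71 up. Sign is ignored.
#'
#' @param l numeric loading(s).
#' @return character vector of labels.
#' @export
loading_quality <- function(l) {
  cuts <- c(0.45, 0.55, 0.63, 0.71)
  labels <- c("poor", "fair", "good", "very good", "excellent")
  labels[findInterval(abs(l), cuts) + 1]
}

#' @export
print.fit_statistics <- function(x, ...) {
  if (!is.null(x$note)) cat("NOTE:", x$note, "\n")
  cat(sprintf("chi2(%d) = %.3f, p = %.4f | CFI %.3f TLI %.3f RMSEA %.3f SRMR %.3f\n",
              x$df, x$chi_square, x$p_value, x$cfi, x$tli, x$rmsea, x$srmr))
  cat(sprintf("free parameters: %d; Heywood case: %s; n_effective = %s\n",
              x$n_free_params, ifelse(x$heywood, "yes", "no"),
              format(x$n_effective)))
  invisible(x)
}
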