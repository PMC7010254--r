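#' Degrees of freedom of an exploratory factor model
#'
#' For `p` indicators and `m` factors the likelihood-ratio test of the
#' common-factor model against the saturated correlation structure has
#' `((p - m)^2 - (p + m)) / 2` degrees of freedom (distinct correlations
#' minus free loadings/uniquenesses plus the `m(m-1)/2` rotational
#' constraints). A negative value means the model is under-identified.
#'
#' @param p number of indicators.
#' @param m number of factors.
#' @return integer degrees of freedom.
#' @export
model_df <- function(p, m) {
  stopifnot(p >= m, m >= 1)
  df <- ((p - m)^2 - (p + m)) / 2
  if (df < 0)
    stop_cogstruct(sprintf("%d-factor model of %d indicators is under-identified (df = %s)",
                           m, p, format(df)), "cogstruct_underidentified")
  df
}

#' Free-parameter count of an oblique exploratory factor model
#'
#' `p(m + 1) - m(m - 1)/2` free parameters: `pm` loadings plus `p`
#' uniquenesses minus the rotational indeterminacy of an oblique solution
#' (`m(m-1)/2`; the factor correlations are absorbed by the rotation).
#' With a mean structure, the `p` indicator means are added.
#'
#' @param p number of indicators.
#' @param m number of factors.
#' @param mean_structure add `p` indicator means?
#' @return integer parameter count.
#' @export
count_free_parameters <- function(p, m, mean_structure = FALSE) {
  stopifnot(p >= m, m >= 1)
  p * (m + 1) - m * (m - 1) / 2 + if (mean_structure) p else 0
}

#' Correlation-matrix input for factor analysis
#'
#' Bundles a positive-definite unit-diagonal correlation matrix with the
#' effective sample size used for test statistics and (optionally) the
#' pairwise available-case counts it was computed from.
#'
#' @param matrix symmetric `p x p` correlation matrix (`p >= 3`).
#' @param n_effective sample size for chi-square statistics; must exceed
#'   `p` for test statistics to be defined.
#' @param source `"behavioral"` or `"neural"`.
#' @param available_n optional `p x p` pairwise-complete counts.
#' @return object of class `correlation_input`.
#' @export
correlation_input <- function(matrix, n_effective,
                              source = c("behavioral", "neural"),
                              available_n = NULL) {
  matrix <- as.matrix(matrix)
  p <- nrow(matrix)
  if (p < 3) stop_cogstruct("need at least 3 indicators", "cogstruct_invalid_spec")
  if (!is_symmetric(matrix, tol = 1e-7))
    stop_cogstruct("correlation matrix must be symmetric", "cogstruct_invalid_spec")
  if (max(abs(diag(matrix) - 1)) > 1e-8)
    stop_cogstruct("correlation matrix must have unit diagonal", "cogstruct_invalid_spec")
  structure(list(matrix = (matrix + t(matrix)) / 2,
                 n_effective = n_effective,
                 source = match.arg(source),
                 available_n = available_n),
            class = "correlation_input")
}

corr_matrix_of <- function(R) {
  if (inherits(R, "correlation_input")) R$matrix
  else if (inherits(R, "pair_correlation_matrix")) R$r
  else as.matrix(R)
}

# Profiled ML discrepancy: with Rs = Psi^{-1/2} R Psi^{-1/2} and
# eigenvalues gamma_1 >= ... >= gamma_p, the loadings maximizing the
# likelihood for fixed Psi leave F(Psi) = sum_{j>m} (gamma_j - log gamma_j - 1).
ml_objective <- function(psi, R, m) {
  p <- length(psi)
  sc <- 1 / sqrt(psi)
  g <- eigen(R * tcrossprod(sc), symmetric = TRUE, only.values = TRUE)$values
  tail_g <- g[(m + 1):p]
  sum(tail_g - log(tail_g) - 1)
}

ml_gradient <- function(psi, R, m) {
  p <- length(psi)
  sc <- 1 / sqrt(psi)
  e <- eigen(R * tcrossprod(sc), symmetric = TRUE)
  lam <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)] - 1, 0)), m)
  lam <- lam * sqrt(psi)
  diag(lam %*% t(lam) + diag(psi) - R) / psi^2
}

ml_loadings <- function(psi, R, m) {
  sc <- 1 / sqrt(psi)
  e <- eigen(R * tcrossprod(sc), symmetric = TRUE)
  lam <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)] - 1, 0)), m)
  lam <- lam * sqrt(psi)
  # sign convention: each factor's loading sum non-negative
  signs <- ifelse(colSums(lam) < 0, -1, 1)
  lam %*% diag(signs, m)
}

#' Maximum-likelihood factor extraction from a correlation matrix
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma| + tr(R Sigma^-1) - log|R| - p` with
#' `Sigma = Lambda Lambda' + Psi`, profiling the loadings out through the
#' eigendecomposition of `Psi^{-1/2} R Psi^{-1/2}` and optimizing the `p`
#' uniquenesses with a box-constrained quasi-Newton search
#' (`[psi_floor, 1]`). Several random restarts guard against local minima;
#' the best solution is kept. Uniquenesses that end on the lower bound mark
#' a Heywood (negative-residual-variance) solution and are flagged
#' downstream.
#'
#' @param R a [correlation_input()], `pair_correlation_matrix`, or plain
#'   positive-definite correlation matrix.
#' @param m number of factors.
#' @param psi_floor lower bound for uniquenesses (default 1e-3).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed for the restart perturbations.
#' @return object of class `efa_model` with unrotated `loadings`, identity
#'   `factor_corr`, `uniquenesses`, `discrepancy` (F at the optimum),
#'   `converged`, `n_restarts_used`, and the input matrix.
#' @export
extract_ml <- function(R, m, psi_floor = 1e-3, n_restarts = 10, seed = NULL) {
  Rm <- corr_matrix_of(R)
  p <- nrow(Rm)
  model_df(p, m)  # errors if under-identified
  if (min_eigenvalue(Rm) <= 0)
    stop_cogstruct("correlation matrix is not positive definite; repair it first (nearest_pd_repair)",
                   "cogstruct_not_pd")
  n_eff <- if (inherits(R, "correlation_input")) R$n_effective else NULL

  base_start <- (1 - 0.5 * m / p) / diag(solve(Rm))
  base_start <- pmin(pmax(base_start, psi_floor * 2), 1)
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1) base_start
      else pmin(pmax(base_start * exp(stats::runif(p, -0.7, 0.7)),
                     psi_floor * 2), 1)
    })
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, ml_objective, gradient = ml_gradient,
                    R = Rm, m = m,
                    lower = psi_floor, upper = 1,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop_cogstruct("no restart of the ML optimizer converged", "cogstruct_no_convergence")

  psi <- as.numeric(best$par)
  lam <- ml_loadings(psi, Rm, m)
  rownames(lam) <- rownames(Rm)
  colnames(lam) <- sprintf("F%d", seq_len(m))
  structure(list(
    loadings = lam, factor_corr = diag(m),
    uniquenesses = stats::setNames(psi, rownames(Rm)),
    unrotated_loadings = lam,
    rotation = "none", geomin_eps = NA_real_,
    converged = best$convergence == 0,
    n_restarts_used = n_restarts,
    discrepancy = best$objective,
    m = m, p = p, psi_floor = psi_floor,
    R = Rm, n_effective = n_eff
  ), class = "efa_model")
}

#' @export
print.efa_model <- function(x, digits = 3, cutoff = 0.32, ...) {
  cat(sprintf("%d-factor ML solution (%s rotation), F = %.6g%s\n",
              x$m, x$rotation, x$discrepancy,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  L <- round(x$loadings, digits)
  Lc <- format(L)
  Lc[abs(x$loadings) < cutoff] <- ""
  print(as.data.frame(Lc), right = TRUE)
  if (x$rotation != "none") {
    cat("Factor correlations:\n")
    print(round(x$factor_corr, digits))
  }
  cat("Uniquenesses:\n")
  print(round(x$uniquenesses, digits))
  invisible(x)
}
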