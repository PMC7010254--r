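# Geomin criterion and its gradient. For loadings L (p x m),
#   q(L) = sum_i ( prod_k (L_ik^2 + eps) )^{1/m}
# i.e. the row-wise geometric mean of squared loadings plus a small eps
# that keeps the criterion differentiable at zero loadings.
vgq_geomin <- function(L, eps) {
  m <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / m)
  list(f = sum(pro), Gq = (2 / m) * (L / L2) * pro)
}

# Gradient-projection descent over oblique rotations (columns of T kept at
# unit length), minimizing q(A T'^{-1}) with step halving/doubling.
gpa_oblique <- function(A, Tmat, eps, maxit = 2000, tol = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vgq_geomin(L, eps)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    # step halving: accept the first sufficient decrease, or the last
    # trial step after a bounded number of halvings (reference gradient-
    # projection behaviour; step size recovers by doubling next iteration)
    for (half in 1:25) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Tti <- try(solve(Tt), silent = TRUE)
      if (!inherits(Tti, "try-error")) {
        Lt <- A %*% t(Tti)
        vgt <- vgq_geomin(Lt, eps)
        if (vgt$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    if (inherits(Tti, "try-error")) break
    Tmat <- Tt; f <- vgt$f; L <- Lt
    G <- -t(t(L) %*% vgt$Gq %*% Tti)
  }
  list(loadings = L, Phi = crossprod(Tmat), Tmat = Tmat,
       f = f, iterations = iter, converged = s < tol)
}

random_rotation <- function(m) {
  qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
}

#' Geomin (oblique) rotation of an extracted factor solution
#'
#' Minimizes the geomin criterion -- the sum over indicators of the
#' geometric mean of squared loadings (plus `eps`) -- over oblique
#' rotations by gradient projection, from the identity start plus
#' `n_starts - 1` random orthonormal starts; the lowest criterion value is
#' kept (first-found on ties). The rotation leaves the model-implied
#' correlation matrix `Lambda Phi Lambda' + Psi` unchanged. A one-factor
#' model is returned as-is (rotation undefined).
#'
#' @param model an `efa_model` from [extract_ml()].
#' @param eps geomin epsilon (default 0.01).
#' @param n_starts number of starts (default 30).
#' @param seed integer seed for the random starts.
#' @param order_factors reorder factors by decreasing sum of squared
#'   loadings and sign-align each factor (loading sum non-negative)?
#' @return the model with rotated `loadings`, factor correlations
#'   `factor_corr`, `rotation = "geomin"`, `geomin_eps`, and
#'   `rotation_criterion` (best criterion value).
#' @export
rotate_geomin <- function(model, eps = 0.01, n_starts = 30, seed = NULL,
                          order_factors = TRUE) {
  stopifnot(inherits(model, "efa_model"))
  m <- model$m
  if (m == 1) return(model)
  A <- model$unrotated_loadings
  runs <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      Tmat <- if (i == 1) diag(m) else random_rotation(m)
      gpa_oblique(A, Tmat, eps = eps)
    })
  })
  any_converged <- any(vapply(runs, `[[`, TRUE, "converged"))
  best <- runs[[which.min(vapply(runs, `[[`, 0.0, "f"))]]
  if (!any_converged)
    stop_cogstruct("geomin rotation did not converge from any start",
                   "cogstruct_no_convergence")
  L <- best$loadings; Phi <- best$Phi
  if (order_factors) {
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]; Phi <- Phi[ord, ord, drop = FALSE]
    signs <- ifelse(colSums(L) < 0, -1, 1)
    L <- L %*% diag(signs, m)
    Phi <- diag(signs, m) %*% Phi %*% diag(signs, m)
  }
  dimnames(L) <- dimnames(model$unrotated_loadings)
  dimnames(Phi) <- list(colnames(L), colnames(L))
  model$loadings <- L
  model$factor_corr <- (Phi + t(Phi)) / 2
  model$rotation <- "geomin"
  model$geomin_eps <- eps
  model$rotation_criterion <- best$f
  model$rotation_starts <- n_starts
  model
}
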