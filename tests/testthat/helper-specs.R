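# Shared fixtures, all built in code.

battery <- function(n = 114, phi = 0.30, seed = NULL)
  cognitive_battery_spec(n_subjects = n, factor_corr_value = phi, seed = seed)

small_netspec <- function(grid = c(12, 12, 12), ...)
  network_template_spec(grid_shape = grid, ...)

# two disjoint box-corner blob templates on a tiny grid (for no-overlap cases)
disjoint_netspec <- function(grid = c(12, 12, 12)) {
  g <- as.integer(grid)
  t1 <- array(0, g); t1[2:4, 2:4, 2:4] <- 1
  t2 <- array(0, g); t2[9:11, 9:11, 9:11] <- 1
  zero <- array(0, g)
  doms <- battery_domains_for_test()
  network_template_spec(
    grid_shape = g,
    shared_template = zero,
    domain_templates = list(memory = t1, reasoning = t2,
                            speed = t1, vocabulary = t2),
    noise_sd = 0
  )
}

battery_domains_for_test <- function() {
  spec <- cognitive_battery_spec()
  attr(spec, "domains")
}

# an efa_model built directly from known loadings (bypassing extraction),
# for tests of rotation/assignment logic in isolation
fake_model <- function(L, Phi = diag(ncol(L)), psi = NULL, discrepancy = 0) {
  L <- as.matrix(L)
  psi <- psi %||% pmax(1 - diag(L %*% Phi %*% t(L)), 1e-3)
  rownames(L) <- rownames(L) %||% sprintf("task_%02d", seq_len(nrow(L)))
  colnames(L) <- colnames(L) %||% sprintf("F%d", seq_len(ncol(L)))
  structure(list(
    loadings = L, factor_corr = Phi,
    uniquenesses = stats::setNames(psi, rownames(L)),
    unrotated_loadings = L, rotation = "none", geomin_eps = NA_real_,
    converged = TRUE, n_restarts_used = 0, discrepancy = discrepancy,
    m = ncol(L), p = nrow(L), psi_floor = 1e-3,
    R = L %*% Phi %*% t(L) + diag(psi), n_effective = NULL
  ), class = "efa_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
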