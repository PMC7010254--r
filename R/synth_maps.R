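#' Network template specification for synthetic task maps
#'
#' Defines the spatial ground truth for the imaging generator: a shared
#' (domain-general) activation template plus one template per cognitive
#' domain, all binary unions of spherical blobs on a common voxel grid.
#' Task z-maps are composed as
#' `effect_scale * (shared + domain template) + smoothed Gaussian noise`,
#' so the three tasks of a domain share their network and their masked
#' spatial correlations exceed between-domain correlations in expectation.
#' The shared template emulates the domain-general posterior/inferior
#' activations seen across all tasks; the default blob geometry is defined
#' in relative coordinates, so any `grid_shape` yields the same layout.
#'
#' @param grid_shape integer length-3 voxel counts (default `c(24, 24, 24)`,
#'   the smallest grid on which masks hold hundreds of voxels).
#' @param task_domain named integer/character vector mapping the 12 tasks to
#'   their domain (3 tasks per domain); defaults to the canonical battery.
#' @param smoothing_fwhm Gaussian noise smoothness, voxels FWHM (default 2).
#' @param noise_sd marginal standard deviation of the smoothed noise field
#'   added to group z-maps.
#' @param effect_scale peak z-value of a noise-free task map (default 12;
#'   group-level task maps from samples of ~100 subjects peak well into
#'   the teens, and the activation masks then retain graded structure
#'   well above the 2.3 threshold).
#' @param coupling per-domain brain-behavior effect: the subject's domain
#'   factor score enters the subject's in-network beta with this weight.
#'   Default 0 (no planted coupling); see [calibrate_coupling()].
#' @param baseline_scale amplitude of the template signal in subject beta
#'   maps.
#' @param beta_subject_sd sd of the per-subject-per-task scalar fluctuation
#'   of network amplitude in beta maps.
#' @param beta_noise_sd sd of the smoothed voxel noise in beta maps.
#' @param shared_template,domain_templates optional explicit 3D arrays
#'   (non-negative, same grid) overriding the default blob layout;
#'   `domain_templates` must be a named list, one array per domain.
#' @param seed integer seed stored with the spec.
#' @return object of class `network_template_spec`.
#' @export
network_template_spec <- function(grid_shape = c(24, 24, 24),
                                  task_domain = NULL,
                                  smoothing_fwhm = 2, noise_sd = 1,
                                  effect_scale = 12, coupling = NULL,
                                  baseline_scale = 1,
                                  beta_subject_sd = 1, beta_noise_sd = 1,
                                  shared_template = NULL,
                                  domain_templates = NULL,
                                  seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  if (smoothing_fwhm < 0)
    stop_cogstruct("smoothing_fwhm must be >= 0", "cogstruct_invalid_spec")
  if (is.null(task_domain)) {
    doms <- battery_domains()
    task_domain <- stats::setNames(rep(names(doms), lengths(doms)),
                                   unlist(doms))
  }
  domains <- unique(unname(task_domain))
  # Default geometry: two domain-general blobs (posterior visual and
  # inferior/cerebellar) that every task activates, plus one blob per
  # domain placed so it partially overlaps the shared regions and its
  # neighbouring domains -- cross-domain intersection masks then contain
  # voxels where the two maps genuinely differ, as in real topographies,
  # so within-domain similarity exceeds between-domain similarity.
  if (is.null(shared_template))
    shared_template <- blob_union(grid_shape, list(
      list(center = c(0.50, 0.25, 0.30), radius = 0.13),
      list(center = c(0.50, 0.75, 0.28), radius = 0.10)))
  if (is.null(domain_templates)) {
    centers <- list(c(0.37, 0.33, 0.48), c(0.63, 0.33, 0.48),
                    c(0.37, 0.63, 0.45), c(0.63, 0.63, 0.45))
    stopifnot(length(domains) <= length(centers))
    domain_templates <- stats::setNames(lapply(seq_along(domains), function(d)
      blob_union(grid_shape, list(list(center = centers[[d]], radius = 0.22)))),
      domains)
  }
  stopifnot(all(dim(shared_template) == grid_shape))
  for (tm in domain_templates) stopifnot(all(dim(tm) == grid_shape))
  if (any(vapply(domain_templates, function(tm) sum(tm > 0), 0L) < 1))
    stop_cogstruct("each domain template needs at least one active voxel",
                   "cogstruct_invalid_spec")
  coupling <- coupling %||% stats::setNames(rep(0, length(domains)), domains)
  if (is.null(names(coupling))) names(coupling) <- domains
  structure(list(
    grid_shape = grid_shape,
    shared_template = shared_template,
    domain_templates = domain_templates,
    task_domain = task_domain,
    domains = domains,
    smoothing_fwhm = smoothing_fwhm, noise_sd = noise_sd,
    effect_scale = effect_scale, coupling = coupling,
    baseline_scale = baseline_scale,
    beta_subject_sd = beta_subject_sd, beta_noise_sd = beta_noise_sd,
    seed = seed
  ), class = "network_template_spec")
}

# Union of graded spherical blobs in relative (0-1) coordinates: each blob
# is a quadratic cap, 1 at the center falling to 0 at the radius, so
# template values vary spatially inside activation masks (a flat template
# would leave no within-mask signal variance for spatial correlations).
blob_union <- function(grid_shape, blobs) {
  g <- grid_shape
  ax <- lapply(1:3, function(k) (seq_len(g[k]) - 0.5) / g[k])
  out <- array(0, g)
  for (b in blobs) {
    d2 <- outer(outer((ax[[1]] - b$center[1])^2,
                      (ax[[2]] - b$center[2])^2, `+`),
                (ax[[3]] - b$center[3])^2, `+`)
    out <- pmax(out, pmax(1 - d2 / b$radius^2, 0))
  }
  out
}

# Separable 3D Gaussian smoothing (zero-padded borders). The convolution
# matrix along each axis is symmetric banded Toeplitz, so the operator is
# self-adjoint -- which mask_mean_noise_var() relies on.
smoothing_kernel <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth_gaussian3d <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  k <- smoothing_kernel(fwhm)
  r <- (length(k) - 1L) / 2L
  d <- dim(x)
  for (axis in 1:3) {
    n <- d[axis]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - r):(j + r)
      ok <- idx >= 1 & idx <= n
      K[idx[ok], j] <- k[ok]
    }
    K <- t(K)  # rows apply the kernel (zero-padded at edges)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    xp <- array(K %*% matrix(xp, nrow = n), dim(xp))
    x <- aperm(xp, order(perm))
  }
  x
}

# sd of an interior voxel of a smoothed white-noise field
smoothed_unit_sd <- function(fwhm) {
  if (fwhm <= 0) return(1)
  k <- smoothing_kernel(fwhm)
  sum(k^2)^(3 / 2)
}

# Smoothed Gaussian noise field with (interior) marginal sd `sd`.
noise_field <- function(grid_shape, sd, fwhm) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  smooth_gaussian3d(w, fwhm) * (sd / smoothed_unit_sd(fwhm))
}

# Exact variance of the mean over `mask` of one noise field: the smoothing
# operator S is self-adjoint, so Var = c^2 ||S 1_M||^2 / |M|^2.
mask_mean_noise_var <- function(spec, mask, sd = spec$beta_noise_sd) {
  m <- array(0, spec$grid_shape); m[mask] <- 1
  nm <- sum(mask)
  c0 <- sd / smoothed_unit_sd(spec$smoothing_fwhm)
  c0^2 * sum(smooth_gaussian3d(m, spec$smoothing_fwhm)^2) / nm^2
}

#' Generate group-level task z-maps
#'
#' One z-statistic map per task:
#' `effect_scale * (shared + domain template) + smoothed noise`. Tasks in
#' the same domain share their template, so their masked spatial
#' correlations exceed between-domain ones in expectation. Deterministic
#' under the seed.
#'
#' @param spec a [network_template_spec()].
#' @param seed integer; defaults to the spec's stored seed.
#' @return named list of [stat_map()] objects, one per task.
#' @export
generate_task_maps <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_template_spec"))
  seed <- seed %||% spec$seed
  tasks <- names(spec$task_domain)
  with_seed(seed, {
    out <- lapply(tasks, function(tk) {
      base <- spec$effect_scale *
        (spec$shared_template + spec$domain_templates[[spec$task_domain[[tk]]]])
      vals <- base
      if (spec$noise_sd > 0)
        vals <- vals + noise_field(spec$grid_shape, spec$noise_sd,
                                   spec$smoothing_fwhm)
      stat_map(vals, task_id = tk)
    })
    stats::setNames(out, tasks)
  })
}

#' Generate per-subject, per-task beta maps
#'
#' Subject beta maps share the latent draw of the behavioral generator:
#' for subject i and a task of domain d,
#' `beta = baseline_scale * (shared + template_d)
#'         + (coupling_d * f_id + eta_it) * template_d + voxel noise`,
#' with `eta_it ~ N(0, beta_subject_sd^2)`. The subject's in-network mean
#' beta is therefore `baseline + coupling_d * f_id + noise`, so a planted
#' brain-behavior correlation is recoverable by the pipeline.
#'
#' @param spec a [network_template_spec()].
#' @param factor_scores `N x m` matrix of domain factor scores, the
#'   `factor_scores` element returned by [generate_behavioral()] (one
#'   generative draw shared between behavior and betas). Columns must be
#'   named by domain.
#' @param tasks optional subset of task names to generate (default: all).
#' @param seed integer; defaults to the spec's stored seed.
#' @return object of class `beta_maps`: list with `maps` (per-subject named
#'   list of per-task 3D arrays), `subjects`, `tasks`, `grid_shape`.
#' @export
generate_subject_betas <- function(spec, factor_scores, tasks = NULL,
                                   seed = NULL) {
  stopifnot(inherits(spec, "network_template_spec"))
  seed <- seed %||% spec$seed
  tasks <- tasks %||% names(spec$task_domain)
  stopifnot(all(tasks %in% names(spec$task_domain)))
  f <- as.matrix(factor_scores)
  if (is.null(colnames(f)) || !all(spec$domains %in% colnames(f)))
    stop_cogstruct("factor_scores must have one named column per domain",
                   "cogstruct_grid_mismatch")
  n <- nrow(f)
  subjects <- sprintf("sub-%03d", seq_len(n))
  with_seed(seed, {
    maps <- lapply(seq_len(n), function(i) {
      per_task <- lapply(tasks, function(tk) {
        d <- spec$task_domain[[tk]]
        tmpl <- spec$domain_templates[[d]]
        eta <- stats::rnorm(1, 0, spec$beta_subject_sd)
        vals <- spec$baseline_scale * (spec$shared_template + tmpl) +
          (spec$coupling[[d]] * f[i, d] + eta) * tmpl
        if (spec$beta_noise_sd > 0)
          vals <- vals + noise_field(spec$grid_shape, spec$beta_noise_sd,
                                     spec$smoothing_fwhm)
        vals
      })
      stats::setNames(per_task, tasks)
    })
    structure(list(maps = stats::setNames(maps, subjects),
                   subjects = subjects, tasks = tasks,
                   grid_shape = spec$grid_shape),
              class = "beta_maps")
  })
}

#' Mean beta over a mask, per subject and task
#'
#' @param betas a `beta_maps` object.
#' @param mask an [activation_mask()] (or logical array) on the same grid.
#' @return numeric `subjects x tasks` matrix of in-mask means.
#' @export
extract_mask_means <- function(betas, mask) {
  stopifnot(inherits(betas, "beta_maps"))
  mk <- if (inherits(mask, "activation_mask")) mask$values else mask
  if (!all(dim(mk) == betas$grid_shape))
    stop_cogstruct("mask grid does not match beta maps",
                   "cogstruct_grid_mismatch")
  out <- t(vapply(betas$maps, function(per_task)
    vapply(per_task, function(v) mean(v[mk]), 0.0),
    numeric(length(betas$tasks))))
  dimnames(out) <- list(betas$subjects, betas$tasks)
  out
}

#' Calibrate the coupling weight for a target brain-behavior correlation
#'
#' Computes, in closed form under the generative model, the coupling value
#' for one domain such that the pipeline's measured correlation between
#' (i) the conjunction-mask mean beta averaged over the domain's three
#' tasks and (ii) the standardized three-task behavioral composite equals
#' `target_r` in population on the latent scale. The attenuation of the
#' behavioral composite (uniqueness noise) and of the neural mean (subject
#' scalar and smoothed voxel noise over the noise-free conjunction mask)
#' are both accounted for; the monotone observation transforms add only a
#' small rank-preserving distortion on top.
#'
#' @param spec a [network_template_spec()].
#' @param latent a [latent_model_spec()] with a `domains` attribute (e.g.
#'   [cognitive_battery_spec()]).
#' @param domain domain name to couple.
#' @param target_r desired population correlation.
#' @param z threshold defining the noise-free conjunction mask.
#' @return the coupling value, with attributes `rho_behavior` (behavioral
#'   attenuation) and `rho_neural` (required latent-neural correlation).
#' @export
calibrate_coupling <- function(spec, latent, domain, target_r, z = 2.3) {
  stopifnot(inherits(spec, "network_template_spec"),
            inherits(latent, "latent_model_spec"))
  doms <- attr(latent, "domains")
  if (is.null(doms) || !domain %in% names(doms))
    stop_cogstruct("latent spec must carry a 'domains' attribute naming this domain",
                   "cogstruct_invalid_spec")
  tasks <- doms[[domain]]
  j <- match(tasks, latent$task_names)
  d_idx <- match(domain, colnames(latent$loadings))
  sigma <- implied_correlation(latent)
  lp <- latent$loadings %*% latent$factor_corr
  # behavioral composite (mean of the domain's standardized indicators):
  # cov(mean(y_j), f_d) / sd(mean(y_j)) with cov(y, f) = Lambda Phi
  k <- length(j)
  rho_b <- (sum(lp[j, d_idx]) / k) / sqrt(sum(sigma[j, j]) / k^2)
  if (abs(target_r) >= abs(rho_b))
    stop_cogstruct(sprintf(
      "target_r (%.3f) exceeds the behavioral composite reliability bound (%.3f)",
      target_r, rho_b), "cogstruct_invalid_spec")
  # noise-free conjunction mask of the domain's tasks
  base <- spec$effect_scale * (spec$shared_template + spec$domain_templates[[domain]])
  mask <- base > z
  tbar <- mean(spec$domain_templates[[domain]][mask])
  n_tasks <- length(tasks)
  v_noise <- tbar^2 * spec$beta_subject_sd^2 / n_tasks +
    mask_mean_noise_var(spec, mask) / n_tasks
  rho_n <- target_r / rho_b
  coupling <- sqrt(rho_n^2 * v_noise / (1 - rho_n^2)) / tbar
  structure(coupling, rho_behavior = rho_b, rho_neural = rho_n,
            mask_voxels = sum(mask))
}

#' @export
print.network_template_spec <- function(x, ...) {
  cat(sprintf("Network template spec: grid %s, %d domains, %d tasks\n",
              paste(x$grid_shape, collapse = "x"),
              length(x$domains), length(x$task_domain)))
  cat(sprintf("effect_scale = %.2f, noise_sd = %.2f, FWHM = %.1f voxels\n",
              x$effect_scale, x$noise_sd, x$smoothing_fwhm))
  invisible(x)
}
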