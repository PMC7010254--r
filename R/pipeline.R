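#' Correlation input from a behavioral matrix
#'
#' Pearson correlations of the observed task scores under the chosen
#' missing-data policy. With `"pairwise"` (default) each correlation uses
#' the subjects observed on both tasks and the effective sample size for
#' test statistics is the median pairwise count; `"listwise"` keeps
#' complete rows only.
#'
#' @param data a `behavioral_matrix` from [generate_behavioral()] (or a
#'   data frame whose first column is `subject`).
#' @param missing `"pairwise"` or `"listwise"`.
#' @return a [correlation_input()] with `available_n` filled in.
#' @export
correlation_from_behavioral <- function(data, missing = c("pairwise", "listwise")) {
  missing <- match.arg(missing)
  scores <- if (inherits(data, "behavioral_matrix")) data$scores else data
  x <- as.matrix(scores[, setdiff(names(scores), "subject"), drop = FALSE])
  obs <- !is.na(x)
  avail <- crossprod(obs)
  if (missing == "listwise") {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    r <- stats::cor(x)
    n_eff <- sum(keep)
  } else {
    r <- stats::cor(x, use = "pairwise.complete.obs")
    n_eff <- stats::median(avail[upper.tri(avail)])
  }
  if (any(!is.finite(r)))
    stop_cogstruct("undefined correlations under the chosen missing-data policy",
                   "cogstruct_undefined_correlation")
  correlation_input(r, n_effective = n_eff, source = "behavioral",
                    available_n = avail)
}

fit_one_m <- function(corr_in, m, mean_structure, config) {
  model <- extract_ml(corr_in, m, psi_floor = config$psi_floor,
                      n_restarts = config$n_restarts, seed = config$seed)
  if (config$rotation == "geomin" && m > 1)
    model <- rotate_geomin(model, eps = config$geomin_eps,
                           n_starts = config$rotation_starts,
                           seed = config$seed)
  fit <- fit_statistics(corr_in, model, mean_structure = mean_structure,
                        chi2_scale = config$chi2_scale)
  list(model = model, fit = fit)
}

efa_config <- function(rotation = "geomin", geomin_eps = 0.01,
                       n_restarts = 10, rotation_starts = 30,
                       psi_floor = 1e-3, chi2_scale = "n-1",
                       rmsea_max = 0.06, srmr_max = 0.08, seed = NULL) {
  list(rotation = rotation, geomin_eps = geomin_eps,
       n_restarts = n_restarts, rotation_starts = rotation_starts,
       psi_floor = psi_floor, chi2_scale = chi2_scale,
       rmsea_max = rmsea_max, srmr_max = srmr_max, seed = seed)
}

run_efa_models <- function(corr_in, m_list, mean_structure, config, source) {
  fits <- list(); models <- list()
  for (m in m_list) {
    res <- tryCatch(fit_one_m(corr_in, m, mean_structure, config),
                    error = function(e)
                      stop_cogstruct(sprintf("m = %d: %s", m, conditionMessage(e)),
                                     class(e)[1]))
    models[[as.character(m)]] <- res$model
    fits[[as.character(m)]] <- res$fit
  }
  mc <- structure(list(
    m_list = m_list, models = models, fits = fits,
    corr_input = corr_in, source = source, config = config,
    selected_m = NA_integer_, selection_rationale = NULL
  ), class = "model_comparison")
  sel <- select_n_factors(fits, m_list, config$rmsea_max, config$srmr_max)
  mc$selected_m <- sel$selected_m
  mc$selection_rationale <- sel$rationale
  mc
}

#' Behavioral exploratory factor analysis across candidate factor counts
#'
#' Computes the task correlation matrix under the missing-data policy,
#' repairs it to positive definiteness if needed, then for each candidate
#' factor count runs ML extraction, geomin rotation and the fit-statistic
#' suite (with a mean structure counted among the free parameters, as for
#' raw-data input), and selects a model by the parsimony rule of
#' [compare_and_select()].
#'
#' @param data a `behavioral_matrix` (or subject-by-task data frame).
#' @param m_list candidate factor counts (default 3, 4, 5).
#' @param missing missing-data policy, see [correlation_from_behavioral()].
#' @param rotation `"geomin"` or `"none"`.
#' @param geomin_eps,n_restarts,rotation_starts,psi_floor,chi2_scale,seed
#'   engine settings, see [extract_ml()], [rotate_geomin()],
#'   [fit_statistics()].
#' @param rmsea_max,srmr_max selection thresholds, see [compare_and_select()].
#' @param repair repair a non-PD correlation matrix before fitting?
#' @return a `model_comparison` object.
#' @export
run_behavioral_efa <- function(data, m_list = c(3, 4, 5),
                               missing = "pairwise", rotation = "geomin",
                               geomin_eps = 0.01, n_restarts = 10,
                               rotation_starts = 30, psi_floor = 1e-3,
                               chi2_scale = "n-1", rmsea_max = 0.06,
                               srmr_max = 0.08, repair = TRUE, seed = NULL) {
  corr_in <- correlation_from_behavioral(data, missing = missing)
  if (repair && min_eigenvalue(corr_in$matrix) <= 0) {
    corr_in$matrix <- unclass(nearest_pd_repair(corr_in$matrix))
    attributes(corr_in$matrix)$repaired <- NULL
  }
  config <- efa_config(rotation, geomin_eps, n_restarts, rotation_starts,
                       psi_floor, chi2_scale, rmsea_max, srmr_max, seed)
  run_efa_models(corr_in, m_list, mean_structure = TRUE, config, "behavioral")
}

#' Neural exploratory factor analysis of the task-pair correlation matrix
#'
#' Same engine path as [run_behavioral_efa()] but on the matrix of masked
#' spatial correlations between task z-maps, without a mean structure.
#' The default effective sample size is the voxel count of the union of
#' all positive activation masks (carried by the matrix); pass
#' `n_effective` to override -- the appropriate value for a
#' spatial-similarity matrix is not well defined, so the chi-square scale
#' should be read with care.
#'
#' @param matrix a `pair_correlation_matrix` from [pairwise_matrix()] (or a
#'   plain correlation matrix).
#' @param m_list candidate factor counts.
#' @param n_effective effective sample size for test statistics.
#' @param repair apply [nearest_pd_repair()] first (default TRUE; pairwise
#'   masks can make the assembled matrix indefinite)? The repair floor is
#'   0.005, the conventional uniqueness lower bound: eigenvalues below
#'   what a factor model can represent would otherwise dominate the
#'   voxel-scale chi-square.
#' @inheritParams run_behavioral_efa
#' @return a `model_comparison` object.
#' @export
run_neural_efa <- function(matrix, m_list = c(3, 4, 5), n_effective = NULL,
                           rotation = "geomin", geomin_eps = 0.01,
                           n_restarts = 10, rotation_starts = 30,
                           psi_floor = 1e-3, chi2_scale = "n-1",
                           rmsea_max = 0.06, srmr_max = 0.08,
                           repair = TRUE, seed = NULL) {
  if (inherits(matrix, "pair_correlation_matrix")) {
    n_effective <- n_effective %||% matrix$n_union
    if (repair) matrix <- nearest_pd_repair(matrix, eig_floor = 0.005)
    Rm <- matrix$r
  } else {
    Rm <- as.matrix(matrix)
    if (repair && min_eigenvalue(Rm) <= 0.005)
      Rm <- unclass(nearest_pd_repair(Rm, eig_floor = 0.005))
    if (is.null(n_effective))
      stop_cogstruct("n_effective is required for a plain matrix input",
                     "cogstruct_invalid_spec")
  }
  corr_in <- correlation_input(Rm, n_effective = n_effective, source = "neural")
  config <- efa_config(rotation, geomin_eps, n_restarts, rotation_starts,
                       psi_floor, chi2_scale, rmsea_max, srmr_max, seed)
  run_efa_models(corr_in, m_list, mean_structure = FALSE, config, "neural")
}

select_n_factors <- function(fits, m_list, rmsea_max, srmr_max) {
  tab <- data.frame(
    m = m_list,
    rmsea = vapply(fits, function(f) f$rmsea, 0.0),
    srmr = vapply(fits, function(f) f$srmr, 0.0)
  )
  qualifies <- !is.na(tab$rmsea) & tab$rmsea <= rmsea_max & tab$srmr <= srmr_max
  if (any(qualifies)) {
    sel <- min(tab$m[qualifies])
    rule <- sprintf("smallest m with RMSEA <= %.3g and SRMR <= %.3g", rmsea_max, srmr_max)
  } else {
    sel <- tab$m[which.min(tab$rmsea)]
    rule <- "no model met both thresholds; smallest-RMSEA model retained"
  }
  rationale <- paste0(
    rule, ". Candidates: ",
    paste(sprintf("m=%d (RMSEA %.3f, SRMR %.3f%s)", tab$m, tab$rmsea, tab$srmr,
                  ifelse(qualifies, ", qualifies", "")), collapse = "; "), ".")
  list(selected_m = as.integer(sel), rationale = rationale)
}

#' Parsimony-based model selection across factor counts
#'
#' Selects the smallest factor count whose fit satisfies both
#' `RMSEA <= rmsea_max` and `SRMR <= srmr_max`; when no candidate
#' qualifies, the smallest-RMSEA model is retained. The rationale string
#' records the rule and every candidate, so alternatives stay visible.
#'
#' @param mc a `model_comparison`.
#' @param rmsea_max,srmr_max thresholds (defaults 0.06 and 0.08).
#' @return the `model_comparison` with `selected_m` and
#'   `selection_rationale` updated.
#' @export
compare_and_select <- function(mc, rmsea_max = 0.06, srmr_max = 0.08) {
  stopifnot(inherits(mc, "model_comparison"), length(mc$fits) >= 2)
  sel <- select_n_factors(mc$fits, mc$m_list, rmsea_max, srmr_max)
  mc$selected_m <- sel$selected_m
  mc$selection_rationale <- sel$rationale
  mc
}

#' Assign tasks to factors
#'
#' Under the `max_loading` rule each task goes to the factor on which it
#' has the largest absolute rotated loading (ties broken towards the lower
#' factor index, with a warning). Under `a_priori` the supplied
#' task-to-domain map is used and the winning loading reported is the
#' task's loading on its a-priori factor's column (matched by name when
#' possible). The two rules can disagree; reports should show both.
#'
#' @param model a rotated `efa_model`.
#' @param rule `"max_loading"` (default) or `"a_priori"`.
#' @param task_domain named vector task -> domain. Required for
#'   `a_priori`; under `max_loading` it is optional and, when given, each
#'   factor is relabelled by the modal a-priori domain of its tasks (so
#'   downstream stages can address factors by domain name).
#' @return object of class `domain_assignment`: list with `rule`,
#'   `factors` (tasks per factor) and `winning` (per-task factor and
#'   loading).
#' @export
assign_membership <- function(model, rule = c("max_loading", "a_priori"),
                              task_domain = NULL) {
  stopifnot(inherits(model, "efa_model"))
  rule <- match.arg(rule)
  L <- model$loadings
  tasks <- rownames(L) %||% sprintf("task_%02d", seq_len(nrow(L)))
  if (rule == "max_loading") {
    winner <- apply(abs(L), 1, function(row) {
      w <- which(row == max(row))
      if (length(w) > 1) warning("tied loadings; assigning to the lower factor index")
      w[1]
    })
    fac_names <- colnames(L) %||% sprintf("F%d", seq_len(ncol(L)))
    factors <- lapply(seq_len(ncol(L)), function(k) tasks[winner == k])
    names(factors) <- fac_names
    if (any(lengths(factors) == 0))
      warning("some factors received no task under the max-loading rule")
    if (!is.null(task_domain) && all(tasks %in% names(task_domain))) {
      labels <- vapply(seq_along(factors), function(k) {
        if (!length(factors[[k]])) return(names(factors)[k])
        tab <- table(task_domain[factors[[k]]])
        names(tab)[which.max(tab)]
      }, "")
      if (anyDuplicated(labels)) {
        warning("two factors share a modal domain; keeping generic factor labels")
      } else {
        names(factors) <- labels
        fac_names <- labels
      }
    }
    winning <- data.frame(task = tasks, factor = fac_names[winner],
                          loading = L[cbind(seq_along(tasks), winner)])
  } else {
    if (is.null(task_domain))
      stop_cogstruct("a_priori rule needs a task_domain map", "cogstruct_invalid_spec")
    stopifnot(all(tasks %in% names(task_domain)))
    doms <- unique(unname(task_domain[tasks]))
    factors <- lapply(doms, function(d) tasks[task_domain[tasks] == d])
    names(factors) <- doms
    col_of <- if (!is.null(colnames(L)) && all(doms %in% colnames(L)))
      match(task_domain[tasks], colnames(L)) else
        match(task_domain[tasks], doms)
    winning <- data.frame(task = tasks, factor = task_domain[tasks],
                          loading = L[cbind(seq_along(tasks), col_of)])
  }
  structure(list(rule = rule, factors = factors, winning = winning),
            class = "domain_assignment")
}

#' Brain-behavior coupling per cognitive domain
#'
#' For each domain: every subject's beta values are averaged over the
#' domain mask and across the domain's (up to three) tasks; the behavioral
#' domain score is the mean of the per-task standardized scores, with
#' reaction-time tasks sign-reflected before standardization so that
#' higher always means better. The two are correlated (Pearson, two-sided
#' p). Subjects whose mean beta lies more than `outlier_sd` group-SDs from
#' the group mean are reported as outliers and the correlation is
#' recomputed without them -- both versions are always returned.
#'
#' @param betas a `beta_maps` object (see [generate_subject_betas()]).
#' @param masks named list of domain [activation_mask()]s (typically the
#'   [domain_conjunction_mask()] of each domain's thresholded task maps).
#' @param behavior a `behavioral_matrix`.
#' @param assignment a `domain_assignment` whose factor names match
#'   `names(masks)`.
#' @param outlier_sd outlier rule in group standard deviations (default 4).
#' @return object of class `brain_behavior_result`: data frame `table`
#'   (domain, n, r, p, r_without_outliers, p_without_outliers,
#'   n_outliers) plus `outliers_removed` and the per-subject `scores`
#'   used.
#' @export
brain_behavior <- function(betas, masks, behavior, assignment,
                           outlier_sd = 4.0) {
  stopifnot(inherits(betas, "beta_maps"),
            inherits(behavior, "behavioral_matrix"),
            inherits(assignment, "domain_assignment"))
  scores <- behavior$scores
  subj <- intersect(betas$subjects, scores$subject)
  if (!length(subj))
    stop_cogstruct("no common subjects between betas and behavior",
                   "cogstruct_invalid_spec")
  # standardized behavioral scores, RT reflected so higher = better
  x <- as.matrix(scores[match(subj, scores$subject),
                        setdiff(names(scores), "subject"), drop = FALSE])
  refl <- behavior$measures[colnames(x)] == "rt"
  x[, refl] <- -x[, refl]
  xz <- scale(x)

  rows <- list(); outliers <- list(); detail <- list()
  for (d in names(masks)) {
    tasks <- intersect(assignment$factors[[d]], betas$tasks)
    if (!length(tasks))
      stop_cogstruct(sprintf("no beta maps for the tasks of domain '%s'", d),
                     "cogstruct_invalid_spec")
    if (masks[[d]]$voxel_count < 1)
      stop_cogstruct(sprintf("domain mask '%s' is empty", d),
                     "cogstruct_invalid_spec")
    mm <- extract_mask_means(betas, masks[[d]])[subj, tasks, drop = FALSE]
    neural <- rowMeans(mm)
    behav <- rowMeans(xz[, intersect(assignment$factors[[d]], colnames(xz)),
                         drop = FALSE], na.rm = TRUE)
    ok <- is.finite(neural) & is.finite(behav)
    res <- correlate_safely(neural[ok], behav[ok])
    ids <- subj[ok]
    dev <- abs(neural[ok] - mean(neural[ok]))
    out <- ids[dev > outlier_sd * stats::sd(neural[ok])]
    res2 <- if (length(out)) {
      keep <- !(ids %in% out)
      correlate_safely(neural[ok][keep], behav[ok][keep])
    } else res
    rows[[d]] <- data.frame(domain = d, n = sum(ok), r = res$r, p = res$p,
                            n_outliers = length(out),
                            r_without_outliers = res2$r,
                            p_without_outliers = res2$p)
    outliers[[d]] <- out
    detail[[d]] <- data.frame(subject = ids, mean_beta = neural[ok],
                              behavior = behav[ok])
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 outliers_removed = outliers, scores = detail,
                 outlier_sd = outlier_sd),
            class = "brain_behavior_result")
}

correlate_safely <- function(x, y) {
  n <- length(x)
  if (n <= 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = if (n > 1 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fit table of a model comparison
#'
#' One row per candidate factor count, shaped like a published SEM fit
#' table: parameter count, chi-square, df, p, CFI, TLI, RMSEA, SRMR and
#' the Heywood column.
#'
#' @param mc a `model_comparison`.
#' @return a data frame.
#' @export
fit_table <- function(mc) {
  stopifnot(inherits(mc, "model_comparison"))
  do.call(rbind, lapply(as.character(mc$m_list), function(ms) {
    f <- mc$fits[[ms]]
    data.frame(m = as.integer(ms), n_parameters = f$n_free_params,
               chi_square = f$chi_square, df = f$df, p_value = f$p_value,
               cfi = f$cfi, tli = f$tli, rmsea = f$rmsea, srmr = f$srmr,
               heywood = f$heywood)
  }))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("EFA model comparison (%s data, n_effective = %s)\n",
              x$source, format(x$corr_input$n_effective)))
  print(format(fit_table(x), digits = 4), row.names = FALSE)
  cat(sprintf("Selected m = %d\n%s\n", x$selected_m, x$selection_rationale))
  invisible(x)
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("Task-to-factor assignment (%s rule):\n", x$rule))
  for (k in names(x$factors))
    cat(sprintf("  %s: %s\n", k, paste(x$factors[[k]], collapse = ", ")))
  invisible(x)
}

#' @export
print.brain_behavior_result <- function(x, ...) {
  cat(sprintf("Brain-behavior coupling (outlier rule: %.1f SD):\n", x$outlier_sd))
  print(format(x$table, digits = 3), row.names = FALSE)
  for (d in names(x$outliers_removed))
    if (length(x$outliers_removed[[d]]))
      cat(sprintf("  %s outliers removed: %s\n", d,
                  paste(x$outliers_removed[[d]], collapse = ", ")))
  invisible(x)
}
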