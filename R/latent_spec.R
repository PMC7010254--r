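#' Specification of a common-factor model for a task battery
#'
#' Defines the generative latent model for synthetic behavioral data: a
#' `p x m` loading matrix `Lambda`, an `m x m` factor correlation matrix
#' `Phi` (unit diagonal, positive definite) and positive uniquenesses `Psi`.
#' The model lives in the standardized metric, so
#' `diag(Lambda Phi Lambda' + Psi) = 1` is enforced (tolerance 1e-8). When
#' `uniquenesses` is omitted it is completed as `1 - diag(Lambda Phi Lambda')`.
#'
#' @param loadings numeric `p x m` matrix of factor loadings.
#' @param factor_corr `m x m` factor correlation matrix; default identity.
#' @param uniquenesses optional length-`p` positive vector; completed from
#'   the standardized metric when `NULL`.
#' @param task_measures character vector of length `p`, each `"accuracy"` or
#'   `"rt"`; reaction-time tasks are transformed with a decreasing function
#'   by [generate_behavioral()] so better ability means shorter time.
#' @param task_names optional task identifiers (defaults to `task_01` ...).
#' @param n_subjects number of subjects the generator should draw.
#' @param seed integer seed stored with the spec; generators are pure
#'   functions of (spec, seed).
#' @return an object of class `latent_model_spec`.
#' @seealso [cognitive_battery_spec()] for the canonical 12-task battery.
#' @export
latent_model_spec <- function(loadings, factor_corr = NULL, uniquenesses = NULL,
                              task_measures = NULL, task_names = NULL,
                              n_subjects = 114, seed = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); m <- ncol(loadings)
  if (p < m) stop_cogstruct("need at least as many tasks as factors (p >= m)",
                            "cogstruct_invalid_spec")
  factor_corr <- factor_corr %||% diag(m)
  factor_corr <- as.matrix(factor_corr)
  if (!is_symmetric(factor_corr))
    stop_cogstruct("factor correlation matrix must be symmetric",
                   "cogstruct_invalid_spec")
  if (max(abs(diag(factor_corr) - 1)) > 1e-8)
    stop_cogstruct("factor correlation matrix must have unit diagonal",
                   "cogstruct_invalid_spec")
  if (min_eigenvalue(factor_corr) <= 0)
    stop_cogstruct("factor correlation matrix must be positive definite",
                   "cogstruct_invalid_spec")
  common <- diag(loadings %*% factor_corr %*% t(loadings))
  if (is.null(uniquenesses)) {
    uniquenesses <- 1 - common
  }
  if (any(uniquenesses <= 0))
    stop_cogstruct("uniquenesses must be strictly positive (communalities < 1)",
                   "cogstruct_invalid_spec")
  if (max(abs(common + uniquenesses - 1)) > 1e-8)
    stop_cogstruct("diag(Lambda Phi Lambda' + Psi) must equal 1 (standardized metric)",
                   "cogstruct_invalid_spec")
  task_names <- task_names %||% sprintf("task_%02d", seq_len(p))
  task_measures <- task_measures %||% rep("accuracy", p)
  stopifnot(length(task_names) == p, length(task_measures) == p)
  if (!all(task_measures %in% c("accuracy", "rt")))
    stop_cogstruct("task_measures entries must be 'accuracy' or 'rt'",
                   "cogstruct_invalid_spec")
  dimnames(loadings) <- list(task_names, sprintf("F%d", seq_len(m)))
  structure(list(
    n_tasks = p, n_factors = m,
    loadings = loadings, factor_corr = factor_corr,
    uniquenesses = stats::setNames(as.numeric(uniquenesses), task_names),
    task_measures = stats::setNames(task_measures, task_names),
    task_names = task_names,
    n_subjects = as.integer(n_subjects), seed = seed
  ), class = "latent_model_spec")
}

#' Model-implied correlation matrix
#'
#' Returns `Sigma = Lambda Phi Lambda' + diag(Psi)` for a latent model
#' specification: the population correlation matrix of the standardized
#' indicators under the common-factor model.
#'
#' @param spec a [latent_model_spec()].
#' @return a symmetric `p x p` matrix with unit diagonal.
#' @export
implied_correlation <- function(spec) {
  stopifnot(inherits(spec, "latent_model_spec"))
  sigma <- spec$loadings %*% spec$factor_corr %*% t(spec$loadings) +
    diag(spec$uniquenesses)
  dimnames(sigma) <- list(spec$task_names, spec$task_names)
  (sigma + t(sigma)) / 2
}

# The four cognitive domains and their tasks, in battery order.
battery_domains <- function() {
  list(
    memory     = c("word_order", "paired_associates", "logical_memory"),
    reasoning  = c("matrix_reasoning", "letter_sets", "paper_folding"),
    speed      = c("pattern_comparison", "letter_comparison", "digit_symbol"),
    vocabulary = c("synonyms", "antonyms", "picture_naming")
  )
}

#' Canonical 12-task, 4-domain cognitive battery specification
#'
#' The default study-scale generative model: 12 tasks in four oblique
#' domains (episodic memory retrieval, reasoning, processing speed,
#' vocabulary; three tasks each), simple structure with primary loadings
#' taken from the published 4-factor behavioral solution
#' (memory .884/.628/.416, reasoning .844/.852/.617, speed .826/.815/.805,
#' vocabulary .903/.677/.798), uniform inter-factor correlation and
#' uniquenesses completed from the standardized metric. The three speed
#' tasks are reaction-time measures; the rest are accuracies.
#'
#' @param n_subjects sample size (default 114, the study design).
#' @param factor_corr_value uniform off-diagonal of `Phi` (default 0.30,
#'   a moderate oblique structure under which the four domains remain
#'   identifiable at the default sample size).
#' @param seed integer seed stored with the spec.
#' @return a [latent_model_spec()] with a `domains` attribute naming the
#'   tasks of each domain.
#' @export
cognitive_battery_spec <- function(n_subjects = 114, factor_corr_value = 0.30,
                                   seed = NULL) {
  doms <- battery_domains()
  task_names <- unname(unlist(doms))
  lambda <- c(0.884, 0.628, 0.416,   # memory
              0.844, 0.852, 0.617,   # reasoning
              0.826, 0.815, 0.805,   # speed (RT measures)
              0.903, 0.677, 0.798)   # vocabulary
  L <- matrix(0, 12, 4)
  for (i in 1:12) L[i, (i - 1) %/% 3 + 1] <- lambda[i]
  phi <- matrix(factor_corr_value, 4, 4); diag(phi) <- 1
  measures <- rep(c("accuracy", "accuracy", "rt", "accuracy"), each = 3)
  spec <- latent_model_spec(
    loadings = L, factor_corr = phi,
    task_measures = measures, task_names = task_names,
    n_subjects = n_subjects, seed = seed
  )
  colnames(spec$loadings) <- names(doms)
  dimnames(spec$factor_corr) <- list(names(doms), names(doms))
  attr(spec, "domains") <- doms
  spec
}

#' @export
print.latent_model_spec <- function(x, ...) {
  cat(sprintf("Latent model spec: %d tasks, %d factors, N = %d\n",
              x$n_tasks, x$n_factors, x$n_subjects))
  cat("Loadings:\n"); print(round(x$loadings, 3))
  cat("Factor correlations:\n"); print(round(x$factor_corr, 3))
  invisible(x)
}
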