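#' Draw synthetic behavioral scores from a latent model
#'
#' Samples factor scores `f ~ MVN(0, Phi)` and unique errors
#' `e ~ MVN(0, diag(Psi))`, forms latent indicator scores `y = f Lambda' + e`
#' (so `cor(y) = Lambda Phi Lambda' + Psi` in population), then maps each
#' indicator to its observed scale with a strictly monotone transform:
#' accuracies through a logistic squash calibrated to a mean of about 0.75,
#' reaction times through a *decreasing* exponential scaled to seconds (so
#' better latent ability means shorter RT, reproducing the sign opposition
#' between speed and accuracy indicators). Because the downstream factor
#' analysis works on correlations, any strictly monotone transform preserves
#' the planted structure up to small rank-preserving distortion.
#'
#' @param spec a [latent_model_spec()].
#' @param missing_pattern `NULL` (complete data), the string `"session"`
#'   (the two-session study design, see [session_missing_pattern()]), or a
#'   logical `N x p` matrix, `TRUE` = observed. Every subject must retain at
#'   least 2 observed tasks.
#' @param accuracy_mean,accuracy_slope calibration of the logistic squash
#'   `plogis(qlogis(accuracy_mean) + accuracy_slope * y)`.
#' @param rt_scale,rt_slope calibration of the RT transform
#'   `rt_scale * exp(-rt_slope * y)` (seconds).
#' @param seed integer; defaults to the seed stored in `spec`. The same
#'   (spec, seed) always yields the identical draw.
#' @return an object of class `behavioral_matrix`: list with `scores` (data
#'   frame, `subject` column plus one column per task, `NA` = missing),
#'   `measures`, `factor_scores` (`N x m`, the latent draw shared with the
#'   imaging generator), `latent` (pre-transform indicator scores), and the
#'   generating `spec`.
#' @export
generate_behavioral <- function(spec, missing_pattern = NULL,
                                accuracy_mean = 0.75, accuracy_slope = 0.35,
                                rt_scale = 1.8, rt_slope = 0.25,
                                seed = NULL) {
  stopifnot(inherits(spec, "latent_model_spec"))
  seed <- seed %||% spec$seed
  n <- spec$n_subjects; p <- spec$n_tasks; m <- spec$n_factors
  if (n < p)
    warning("fewer subjects than tasks: factor analysis will be unstable")

  draw <- with_seed(seed, {
    f <- matrix(stats::rnorm(n * m), n, m) %*% chol(spec$factor_corr)
    e <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(spec$uniquenesses))
    obs_pattern <- if (identical(missing_pattern, "session"))
      session_missing_pattern(n, spec$task_names) else NULL
    list(f = f, e = e, obs = obs_pattern)
  })
  f <- draw$f
  y <- f %*% t(spec$loadings) + draw$e
  colnames(y) <- spec$task_names
  colnames(f) <- colnames(spec$loadings)

  x <- y
  acc <- spec$task_measures == "accuracy"
  x[, acc] <- stats::plogis(stats::qlogis(accuracy_mean) +
                              accuracy_slope * y[, acc])
  x[, !acc] <- rt_scale * exp(-rt_slope * y[, !acc])

  obs <- if (is.matrix(missing_pattern)) missing_pattern else draw$obs
  if (!is.null(obs)) {
    stopifnot(is.logical(obs), all(dim(obs) == c(n, p)))
    if (any(rowSums(obs) < 2))
      stop_cogstruct("missing pattern must leave >= 2 observed tasks per subject",
                     "cogstruct_invalid_spec")
    x[!obs] <- NA_real_
  }

  scores <- data.frame(subject = sprintf("sub-%03d", seq_len(n)), x,
                       check.names = FALSE)
  structure(list(
    scores = scores,
    measures = spec$task_measures,
    factor_scores = f,
    latent = y,
    spec = spec
  ), class = "behavioral_matrix")
}

#' Two-session missingness pattern of the study design
#'
#' Builds an observed-data indicator matrix shaped like the study's
#' acquisition design: tasks split into a memory/reasoning session and a
#' vocabulary/speed session (fixed within-session administration orders),
#' 72 of 114 subjects complete all 12 tasks and the rest miss tasks in
#' session-structured blocks (whole sessions, session plus the first task
#' of the other, or a few dropped tasks). This is by-design missingness,
#' not missing-completely-at-random. Every subject keeps at least two
#' tasks, so pairwise-complete correlations remain computable and every
#' task pair retains at least the 72 completers.
#'
#' @param n_subjects currently must be 114 (the design being emulated).
#' @param task_names the 12 battery task names.
#' @param seed optional seed for the randomly dropped tasks of partial
#'   completers.
#' @return logical `114 x 12` matrix, `TRUE` = observed.
#' @export
session_missing_pattern <- function(n_subjects = 114,
                                    task_names = cognitive_battery_spec()$task_names,
                                    seed = NULL) {
  if (n_subjects != 114)
    stop_cogstruct("the session-structured pattern is defined for the 114-subject design",
                   "cogstruct_invalid_spec")
  stopifnot(length(task_names) == 12)
  # fixed administration orders within each session
  sess_a <- c("logical_memory", "paper_folding", "word_order",
              "matrix_reasoning", "paired_associates", "letter_sets")
  sess_b <- c("synonyms", "digit_symbol", "antonyms",
              "letter_comparison", "picture_naming", "pattern_comparison")
  stopifnot(setequal(c(sess_a, sess_b), task_names))
  col <- function(tasks) match(tasks, task_names)

  with_seed(seed, {
    obs <- matrix(FALSE, 114, 12, dimnames = list(NULL, task_names))
    row <- 0
    add <- function(k, tasks) {
      for (i in seq_len(k)) {
        row <<- row + 1
        obs[row, col(tasks(i))] <<- TRUE
      }
    }
    all12 <- c(sess_a, sess_b)
    add(72, function(i) all12)                                   # completers
    add(10, function(i) sample(all12, 11))                       # miss 1
    add(4,  function(i) sample(all12, 10))                       # miss 2
    add(3,  function(i) sample(all12, 8))                        # miss 4
    add(1,  function(i) sample(all12, 5))                        # miss 7
    add(9,  function(i) c(sess_a, sess_b[1]))                    # A + first of B
    add(1,  function(i) c(sess_b, sess_a[1]))                    # B + first of A
    add(3,  function(i) sess_a)                                  # A only
    add(8,  function(i) sess_b)                                  # B only
    add(1,  function(i) c(sess_a[1:3], "synonyms"))              # partial A + 1 vocab
    add(1,  function(i) setdiff(sess_b, "picture_naming"))       # B minus naming
    add(1,  function(i) c("picture_naming", "synonyms"))         # near-single-task
    stopifnot(row == 114)
    obs
  })
}

#' @export
print.behavioral_matrix <- function(x, ...) {
  n <- nrow(x$scores); p <- length(x$measures)
  miss <- sum(is.na(x$scores[, -1]))
  cat(sprintf("Behavioral matrix: %d subjects x %d tasks (%d missing cells)\n",
              n, p, miss))
  cat(sprintf("Measures: %d accuracy, %d reaction-time\n",
              sum(x$measures == "accuracy"), sum(x$measures == "rt")))
  invisible(x)
}
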