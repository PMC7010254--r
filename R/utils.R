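# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cogstruct <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cogstruct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_symmetric <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

min_eigenvalue <- function(x) {
  min(eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Tucker's coefficient of factor congruence
#'
#' Column-by-column cosine similarity between two loading matrices,
#' `phi[j, k] = sum(a_j b_k) / sqrt(sum(a_j^2) sum(b_k^2))`. Used to match a
#' recovered factor solution to the loadings that generated the data.
#'
#' @param a,b numeric matrices with the same number of rows.
#' @return a `ncol(a)` x `ncol(b)` matrix of congruence coefficients.
#' @export
factor_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  num <- crossprod(a, b)
  den <- sqrt(outer(colSums(a^2), colSums(b^2)))
  num / den
}

# All permutations of 1..n (n small: factor counts).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Match recovered factors to reference factors
#'
#' Finds the column permutation and sign flips of `recovered` that maximise
#' the mean absolute Tucker congruence with `reference`, and returns the
#' per-factor congruence after matching (all factors sign-aligned so the
#' matched congruence is non-negative).
#'
#' @param recovered,reference loading matrices with equal dimensions.
#' @return list with `congruence` (per reference factor), `perm`, `signs`.
#' @export
match_factors <- function(recovered, reference) {
  phi <- factor_congruence(reference, recovered)
  m <- ncol(reference)
  stopifnot(ncol(recovered) == m)
  perms <- permutations(m)
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    pp <- perms[r, ]
    val <- sum(abs(phi[cbind(seq_len(m), pp)]))
    if (val > best_val) { best_val <- val; best <- pp }
  }
  cong <- abs(phi[cbind(seq_len(m), best)])
  signs <- sign(phi[cbind(seq_len(m), best)])
  signs[signs == 0] <- 1
  list(congruence = cong, perm = best, signs = signs)
}
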