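#' Statistic map and activation mask containers
#'
#' `stat_map()` wraps a 3D grid of voxelwise group-level z-statistics;
#' `activation_mask()` wraps a logical grid with the threshold and source
#' tasks that produced it. All maps entering one analysis must share a
#' grid; coordinates are voxel-index space (no affine resampling -- inputs
#' are assumed already spatially normalized upstream).
#'
#' @param values 3D numeric (finite) or logical array.
#' @param task_id task identifier(s).
#' @param threshold z threshold recorded with a mask.
#' @return object of class `stat_map` / `activation_mask`.
#' @export
stat_map <- function(values, task_id = "task") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values)))
    stop_cogstruct("stat map values must be finite", "cogstruct_invalid_map")
  structure(list(values = values, grid_shape = dim(values),
                 task_id = task_id), class = "stat_map")
}

#' @rdname stat_map
#' @export
activation_mask <- function(values, threshold = NA_real_, task_id = "mask") {
  stopifnot(is.array(values), length(dim(values)) == 3, is.logical(values))
  structure(list(values = values, grid_shape = dim(values),
                 threshold = threshold, task_id = task_id,
                 voxel_count = sum(values)), class = "activation_mask")
}

map_values <- function(x) {
  if (inherits(x, c("stat_map", "activation_mask"))) x$values else x
}

check_same_grid <- function(a, b) {
  if (!all(dim(map_values(a)) == dim(map_values(b))))
    stop_cogstruct("maps/masks are on different grids", "cogstruct_grid_mismatch")
}

#' Threshold a z-map into a positive activation mask
#'
#' Voxels with `value > z` (strict inequality: boundary voxels exactly at
#' the threshold are excluded) form the mask. Negative activations are
#' ignored throughout. Optionally, connected components (26-neighbour
#' connectivity) smaller than `min_cluster` voxels are pruned -- a simple
#' contiguity filter for users who want one; it is off by default and no
#' cluster-level inference is performed.
#'
#' @param map a [stat_map()] (or 3D array).
#' @param z threshold (default 2.3).
#' @param min_cluster minimum connected-component size; 0 disables pruning.
#' @return an [activation_mask()].
#' @export
threshold_mask <- function(map, z = 2.3, min_cluster = 0) {
  vals <- map_values(map)
  mk <- vals > z
  if (min_cluster > 0) {
    lab <- label_components_26(mk)
    keep <- which(tabulate(lab[mk]) >= min_cluster)
    mk <- array(lab %in% keep & mk, dim(mk))
  }
  activation_mask(mk, threshold = z,
                  task_id = if (inherits(map, "stat_map")) map$task_id else "map")
}

# 26-connectivity component labelling by flood fill.
label_components_26 <- function(mk) {
  d <- dim(mk)
  lab <- array(0L, d)
  idx <- which(mk)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start; lab[start] <- current
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, d)
      cand <- sweep(nbr, 2, as.numeric(co), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
      lin <- lin[mk[lin] & lab[lin] == 0L]
      lab[lin] <- current
      queue <- c(queue, lin)
    }
  }
  lab
}

#' Intersection of two activation masks
#'
#' Voxelwise logical AND; the voxel count can never exceed either input's.
#'
#' @param a,b [activation_mask()] objects on the same grid.
#' @return an [activation_mask()].
#' @export
intersection_mask <- function(a, b) {
  check_same_grid(a, b)
  activation_mask(map_values(a) & map_values(b),
                  threshold = a$threshold %||% NA_real_,
                  task_id = c(a$task_id, b$task_id))
}

#' Masked spatial correlation of two statistic maps
#'
#' Pearson correlation of the two maps' z-values over the masked voxels.
#' Fewer than `n_min` voxels, or zero variance of either map inside the
#' mask, make the correlation undefined and raise an error of class
#' `cogstruct_undefined_correlation` (propagated as a missing pair by
#' [pairwise_matrix()]).
#'
#' @param a,b [stat_map()] objects on a shared grid.
#' @param mask an [activation_mask()] on the same grid.
#' @param n_min minimum voxel count for a defined correlation (default 10;
#'   a Pearson r over fewer voxels is too unstable to report).
#' @return list with `r` and `n` (masked voxel count).
#' @export
spatial_correlation <- function(a, b, mask, n_min = 10) {
  check_same_grid(a, b); check_same_grid(a, mask)
  mk <- map_values(mask)
  n <- sum(mk)
  if (n < n_min)
    stop_cogstruct(sprintf("mask has %d voxels (< n_min = %d): correlation undefined",
                           n, n_min), "cogstruct_undefined_correlation")
  x <- map_values(a)[mk]; y <- map_values(b)[mk]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_cogstruct("zero variance within mask: correlation undefined",
                   "cogstruct_undefined_correlation")
  list(r = stats::cor(x, y), n = n)
}

#' Task-pair matrix of masked spatial correlations
#'
#' For every unordered pair of task maps, thresholds both maps at `z`,
#' intersects the positive activation masks, and computes the masked
#' spatial correlation of the two z-maps over that pairwise mask. For 12
#' tasks this yields 66 distinct pair correlations which, together with
#' the 12 unit self-correlations, fill the 78 distinct cells of the
#' symmetric 12 x 12 matrix. The diagonal of `n_voxels` records each
#' task's own mask size; `attr(, "n_union")` records the voxel count of
#' the union of all positive masks (a natural effective sample size for
#' factor analysis of the matrix).
#'
#' @param maps list of >= 2 [stat_map()] objects on a shared grid.
#' @param z threshold for the positive activation masks.
#' @param n_min minimum intersection size for a defined pair.
#' @param min_cluster optional contiguity pruning, see [threshold_mask()].
#' @return object of class `pair_correlation_matrix`: list with `tasks`,
#'   `r` (symmetric, unit diagonal), `n_voxels`, `repaired` flag,
#'   `threshold`.
#' @export
pairwise_matrix <- function(maps, z = 2.3, n_min = 10, min_cluster = 0) {
  p <- length(maps)
  if (p < 2) stop_cogstruct("need at least two maps", "cogstruct_invalid_map")
  tasks <- unname(vapply(maps, function(m) as.character(m$task_id)[1], ""))
  if (is.null(names(maps))) names(maps) <- tasks
  for (i in seq_len(p - 1)) check_same_grid(maps[[i]], maps[[i + 1]])
  masks <- lapply(maps, threshold_mask, z = z, min_cluster = min_cluster)
  r <- diag(1, p); nv <- matrix(0L, p, p)
  diag(nv) <- vapply(masks, function(m) m$voxel_count, 0L)
  failed <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    res <- tryCatch(
      spatial_correlation(maps[[i]], maps[[j]],
                          intersection_mask(masks[[i]], masks[[j]]),
                          n_min = n_min),
      cogstruct_undefined_correlation = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s~%s (%s)", tasks[i], tasks[j],
                                  conditionMessage(res)))
    } else {
      r[i, j] <- r[j, i] <- res$r
      nv[i, j] <- nv[j, i] <- res$n
    }
  }
  if (length(failed))
    stop_cogstruct(paste0("undefined pair correlations:\n  ",
                          paste(failed, collapse = "\n  ")),
                   "cogstruct_undefined_correlation")
  union_mask <- Reduce(`|`, lapply(masks, map_values))
  dimnames(r) <- dimnames(nv) <- list(tasks, tasks)
  structure(list(tasks = tasks, r = r, n_voxels = nv,
                 repaired = FALSE, threshold = z,
                 n_union = sum(union_mask)),
            class = "pair_correlation_matrix")
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Pairwise masks differ from pair to pair, so an assembled pair-correlation
#' matrix need not be positive semidefinite. This repairs it by alternating
#' eigenvalue clipping (eigenvalues floored at `eig_floor`) with rescaling
#' back to unit diagonal, iterated to convergence. The `repaired` flag is
#' set iff any clipping occurred; positive-definite input is returned
#' unchanged.
#'
#' @param x a `pair_correlation_matrix` or plain symmetric matrix.
#' @param eig_floor minimum eigenvalue of the output (default 1e-6).
#' @param maxit maximum clip/rescale sweeps.
#' @return same type as the input, positive definite with unit diagonal.
#' @export
nearest_pd_repair <- function(x, eig_floor = 1e-6, maxit = 200) {
  is_pcm <- inherits(x, "pair_correlation_matrix")
  m <- if (is_pcm) x$r else as.matrix(x)
  if (!is_symmetric(m, tol = 1e-7))
    stop_cogstruct("input must be symmetric", "cogstruct_invalid_spec")
  m <- (m + t(m)) / 2
  clipped <- FALSE
  for (it in seq_len(maxit)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= eig_floor * (1 - 1e-10)) break
    clipped <- TRUE
    vals <- pmax(e$values, eig_floor)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- 1 / sqrt(diag(m))
    m <- m * tcrossprod(d)
    m <- (m + t(m)) / 2
  }
  diag(m) <- 1
  if (is_pcm) {
    dimnames(m) <- dimnames(x$r)
    x$r <- m; x$repaired <- x$repaired || clipped
    x
  } else {
    structure(m, repaired = clipped)
  }
}

#' Conjunction mask of a domain's three task masks
#'
#' Voxelwise AND of the three thresholded positive activation masks of the
#' tasks constituting one cognitive domain -- the domain's pattern of
#' significant topographic overlap.
#'
#' @param masks list of exactly 3 [activation_mask()] objects on one grid.
#' @return an [activation_mask()].
#' @export
domain_conjunction_mask <- function(masks) {
  if (length(masks) != 3)
    stop_cogstruct("a domain conjunction takes exactly the domain's 3 task masks",
                   "cogstruct_invalid_spec")
  Reduce(intersection_mask, masks)
}

#' @export
print.pair_correlation_matrix <- function(x, ...) {
  p <- length(x$tasks)
  cat(sprintf("Pair correlation matrix: %d tasks, %d distinct values (z > %.2f)%s\n",
              p, p * (p + 1) / 2, x$threshold,
              if (x$repaired) ", PD-repaired" else ""))
  print(round(x$r, 3))
  invisible(x)
}

#' @export
print.activation_mask <- function(x, ...) {
  cat(sprintf("Activation mask: %d voxels on %s grid (z > %s)\n",
              x$voxel_count, paste(x$grid_shape, collapse = "x"),
              format(x$threshold)))
  invisible(x)
}
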