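#' Write / read a behavioral matrix as TSV with a JSON sidecar
#'
#' The TSV has a header row `subject` plus one column per task; empty
#' cells are missing. The sidecar (`<path>.json`) records each task's
#' measure type and, when available, the generating latent model
#' (loadings, factor correlations, uniquenesses, sample size, seed).
#'
#' @param x a `behavioral_matrix`.
#' @param path TSV path; the sidecar is written next to it.
#' @return `path`, invisibly (`write_behavioral`); a `behavioral_matrix`
#'   (`read_behavioral` -- without latent draws, which live only in the
#'   generating session).
#' @export
write_behavioral <- function(x, path) {
  stopifnot(inherits(x, "behavioral_matrix"))
  utils::write.table(x$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  sidecar <- list(task_measures = as.list(x$measures))
  if (!is.null(x$spec)) {
    sidecar$generating_spec <- list(
      loadings = unname(apply(x$spec$loadings, 1, as.numeric, simplify = FALSE)),
      factor_corr = unname(apply(x$spec$factor_corr, 1, as.numeric, simplify = FALSE)),
      uniquenesses = as.numeric(x$spec$uniquenesses),
      task_names = x$spec$task_names,
      n_subjects = x$spec$n_subjects,
      seed = x$spec$seed
    )
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_behavioral
#' @export
read_behavioral <- function(path) {
  scores <- utils::read.table(path, sep = "\t", header = TRUE,
                              na.strings = "", check.names = FALSE,
                              colClasses = c(subject = "character"))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  measures <- unlist(sidecar$task_measures)
  structure(list(scores = scores,
                 measures = measures[setdiff(names(scores), "subject")],
                 factor_scores = NULL, latent = NULL, spec = NULL),
            class = "behavioral_matrix")
}

#' Write / read statistic maps as NIfTI volumes
#'
#' One NIfTI-1 file per task (`task-<name>_zmap.nii.gz`), identity affine,
#' shared grid. Masks are written as uint8 volumes.
#'
#' @param maps named list of [stat_map()] objects.
#' @param dir output directory (created if needed).
#' @return character vector of file paths (write); named list of
#'   [stat_map()] (read).
#' @export
write_stat_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(maps, function(m) {
    path <- file.path(dir, sprintf("task-%s_zmap.nii.gz", m$task_id))
    RNifti::writeNifti(RNifti::asNifti(m$values), path)
    path
  }, "")
}

#' @rdname write_stat_maps
#' @export
read_stat_maps <- function(dir) {
  files <- list.files(dir, pattern = "^task-.*_zmap\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files))
    stop_cogstruct(sprintf("no task z-maps found in %s", dir),
                   "cogstruct_invalid_map")
  tasks <- sub("^task-(.*)_zmap\\.nii(\\.gz)?$", "\\1", basename(files))
  maps <- lapply(seq_along(files), function(i)
    stat_map(array(as.numeric(RNifti::readNifti(files[i])),
                   dim(RNifti::readNifti(files[i]))), task_id = tasks[i]))
  stats::setNames(maps, tasks)
}

#' Write an activation mask as a uint8 NIfTI volume
#'
#' @param mask an [activation_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "activation_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), mask$grid_shape),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a task-pair correlation matrix as TSV with a JSON sidecar
#'
#' The TSV holds the `p x p` matrix with task names as row/column labels;
#' the sidecar records the task order, per-pair intersection voxel counts,
#' the threshold and the repaired flag.
#'
#' @param x a `pair_correlation_matrix`.
#' @param path TSV path.
#' @return `path` invisibly (write); `pair_correlation_matrix` (read).
#' @export
write_pair_matrix <- function(x, path) {
  stopifnot(inherits(x, "pair_correlation_matrix"))
  utils::write.table(round(x$r, 10), path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(
    tasks = x$tasks,
    n_voxels = unname(apply(x$n_voxels, 1, as.integer, simplify = FALSE)),
    repaired = x$repaired, threshold = x$threshold,
    n_union = x$n_union
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  r <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nv <- if (is.matrix(meta$n_voxels)) meta$n_voxels else do.call(rbind, meta$n_voxels)
  dimnames(r) <- dimnames(nv) <- list(meta$tasks, meta$tasks)
  structure(list(tasks = meta$tasks, r = r, n_voxels = nv,
                 repaired = meta$repaired, threshold = meta$threshold,
                 n_union = meta$n_union),
            class = "pair_correlation_matrix")
}
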