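#' Construct a cohort of connectivity matrices with behavioural scores
#'
#' A cohort bundles one symmetric Fisher-z connectivity matrix per subject
#' with the behavioural score the model predicts (e.g. a clinician-rated
#' symptom-severity scale) and optional covariates and binary diagnosis
#' labels. All downstream CPM operations take a cohort.
#'
#' @param matrices list of symmetric `n_nodes x n_nodes` numeric matrices
#'   with zero diagonal (Fisher-z edge weights).
#' @param scores numeric vector, one finite score per subject.
#' @param covariates optional `data.frame` with any of the columns `age`
#'   (years), `sex` (factor/character), `mean_fd` (mm), one row per subject.
#' @param labels optional binary diagnosis indicator per subject (0/1,
#'   logical, or 2-level factor).
#' @param subject_ids character ids; defaults to `sub001`, `sub002`, ...
#' @return An object of class `cpm_cohort`: a list with elements
#'   `matrices`, `scores`, `covariates`, `labels`, `subject_ids`,
#'   `n_subjects`, `n_nodes`.
#' @export
cohort <- function(matrices, scores, covariates = NULL, labels = NULL,
                   subject_ids = NULL) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("`matrices` must be a non-empty list of square matrices",
         call. = FALSE)
  n <- length(matrices)
  if (length(scores) != n)
    stop("length(scores) must equal the number of matrices", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  dims <- vapply(matrices, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[2, ]) || length(unique(dims[1, ])) != 1L)
    stop("all matrices must be square with a common node count",
         call. = FALSE)
  n_nodes <- dims[1, 1]
  for (m in matrices) {
    if (max(abs(m - t(m))) > 1e-8)
      stop("connectivity matrices must be symmetric", call. = FALSE)
  }
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_len(n))
  if (anyDuplicated(subject_ids))
    stop("subject ids must be unique", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels must have one entry per subject", call. = FALSE)
    labels <- as.factor(labels)
    if (nlevels(labels) > 2L)
      stop("labels must be binary", call. = FALSE)
  }
  structure(
    list(matrices = matrices, scores = as.numeric(scores),
         covariates = covariates, labels = labels,
         subject_ids = as.character(subject_ids),
         n_subjects = n, n_nodes = n_nodes),
    class = "cpm_cohort"
  )
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat("CPM cohort:", x$n_subjects, "subjects,", x$n_nodes, "nodes (",
      x$n_nodes * (x$n_nodes - 1) / 2, "candidate edges )\n")
  cat("  scores: mean", round(mean(x$scores), 2), "sd",
      round(stats::sd(x$scores), 2), "range",
      paste(round(range(x$scores), 2), collapse = "-"), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(levels(x$labels), collapse = "/"),
        paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

# subset a cohort by subject index (used by LOOCV and k-fold loops)
cohort_subset <- function(x, keep) {
  cohort(x$matrices[keep], x$scores[keep],
         covariates = if (!is.null(x$covariates)) x$covariates[keep, , drop = FALSE],
         labels = if (!is.null(x$labels)) x$labels[keep],
         subject_ids = x$subject_ids[keep])
}
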