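# Plain-text formats: tab-separated matrices with a node-id header row, TSV
# tables for subjects/atlas/edge sets, JSON for nested result bundles.
# Delimited text keeps a 268 x 268 cohort diffable and language-neutral.

#' Read a connectivity matrix from delimited text
#'
#' Expects a square tab-separated matrix with a header row of node ids.
#' Asymmetry up to 1e-6 (from formatting round-trips) is repaired by
#' averaging with the transpose, with a message; larger asymmetry is an
#' error.
#'
#' @param path file path.
#' @return Symmetric numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m),
         ")", call. = FALSE)
  if (anyNA(m)) stop("matrix in ", path, " contains NA", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop("matrix in ", path, " is asymmetric beyond tolerance (max |m - t(m)| = ",
         signif(asym, 3), ")", call. = FALSE)
  if (asym > 0) {
    m <- (m + t(m)) / 2
    message("symmetrised ", basename(path), " (asymmetry ", signif(asym, 3), ")")
  }
  dimnames(m) <- NULL
  m
}

#' Write a cohort to a directory of delimited-text files
#'
#' One `<subject_id>.tsv` matrix per subject (node-id header row) plus a
#' `subjects.tsv` table with columns `subject_id`, `score`, any covariates,
#' and `label` if present.
#'
#' @param cohort a [cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(cohort$n_subjects)) {
    m <- cohort$matrices[[s]]
    colnames(m) <- paste0("n", seq_len(ncol(m)))
    utils::write.table(
      format(m, digits = 17, trim = TRUE, scientific = FALSE),
      file.path(dir, paste0(cohort$subject_ids[s], ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab <- data.frame(subject_id = cohort$subject_ids, score = cohort$scores)
  if (!is.null(cohort$covariates)) tab <- cbind(tab, cohort$covariates)
  if (!is.null(cohort$labels)) tab$label <- cohort$labels
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory of matrices plus a subject table
#'
#' Subjects are aligned by id between the score table and the matrix files;
#' a score-table row without a matrix file, or a matrix file for a subject
#' missing from the table, is an error naming the ids involved.
#'
#' @param dir directory holding `<subject_id>.tsv` matrix files.
#' @param scores_path subject table (TSV with `subject_id` and `score`
#'   columns, optional `age`/`sex`/`mean_fd`/`label`); defaults to
#'   `subjects.tsv` inside `dir`.
#' @return A [cohort].
#' @export
read_cohort <- function(dir, scores_path = file.path(dir, "subjects.tsv")) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  tab <- utils::read.delim(scores_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(tab)))
    stop("subject table needs `subject_id` and `score` columns",
         call. = FALSE)
  if (anyNA(tab$score))
    stop("NA score for subject(s): ",
         paste(tab$subject_id[is.na(tab$score)], collapse = ", "),
         call. = FALSE)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = FALSE)
  files <- setdiff(files, "subjects.tsv")
  ids_on_disk <- sub("\\.tsv$", "", files)
  missing_mat <- setdiff(tab$subject_id, ids_on_disk)
  if (length(missing_mat))
    stop("no matrix file for subject(s): ",
         paste(missing_mat, collapse = ", "), call. = FALSE)
  extra <- setdiff(ids_on_disk, tab$subject_id)
  if (length(extra))
    stop("matrix file(s) without a score-table row: ",
         paste(extra, collapse = ", "), call. = FALSE)
  mats <- lapply(tab$subject_id,
                 function(id) read_matrix(file.path(dir, paste0(id, ".tsv"))))
  covs <- tab[intersect(c("age", "sex", "mean_fd"), names(tab))]
  cohort(mats, tab$score,
         covariates = if (ncol(covs)) covs,
         labels = if ("label" %in% names(tab)) tab$label,
         subject_ids = tab$subject_id)
}

#' Write / read a node atlas table
#'
#' TSV with columns `node_id`, `region`, `network`, `x`, `y`, `z`.
#' @param atlas an atlas data frame.
#' @param path file path.
#' @return `path` / the atlas.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  at <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "region", "network")
  if (!all(need %in% names(at)))
    stop("atlas table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  class(at) <- c("cpm_atlas", "data.frame")
  at
}

#' Write a selected edge set as TSV
#'
#' Columns `node_i`, `node_j` (1-based atlas node ids, i < j), `rho`, `p`,
#' `tail`.
#'
#' @param selection a `cpm_edge_selection` from [select_edges()].
#' @param path file path.
#' @export
write_edges <- function(selection, path) {
  stopifnot(inherits(selection, "cpm_edge_selection"))
  idx <- edge_index(selection$n_nodes)
  rows <- function(e, tail) {
    if (length(e) == 0L) return(NULL)
    data.frame(node_i = idx[e, 1L], node_j = idx[e, 2L],
               rho = selection$rho[e], p = selection$p[e], tail = tail)
  }
  tab <- rbind(rows(selection$positive_edges, "positive"),
               rows(selection$negative_edges, "negative"))
  if (is.null(tab))
    tab <- data.frame(node_i = integer(), node_j = integer(),
                      rho = numeric(), p = numeric(), tail = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validated configuration for a full pipeline run
#'
#' @param cohort_dir directory of matrix files (see [read_cohort()]).
#' @param scores_path subject table path.
#' @param atlas_path optional atlas TSV.
#' @param out_dir output directory.
#' @param threshold edge-selection p-value in (0, 1).
#' @param n_perm permutation count.
#' @param seed integer seed, recorded in every output.
#' @param top_k nodes reported in the degree ranking.
#' @return List of class `cpm_run_config`.
#' @export
run_config <- function(cohort_dir, scores_path = file.path(cohort_dir, "subjects.tsv"),
                       atlas_path = NULL, out_dir = tempfile("cpm_run_"),
                       threshold = 0.05, n_perm = 1000, seed = 1L,
                       top_k = 10L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  structure(
    list(cohort_dir = cohort_dir, scores_path = scores_path,
         atlas_path = atlas_path, out_dir = out_dir,
         threshold = threshold, n_perm = as.integer(n_perm),
         seed = as.integer(seed), top_k = as.integer(top_k)),
    class = "cpm_run_config"
  )
}

#' Run the CPM pipeline end to end
#'
#' Loads a cohort, runs LOOCV prediction and the permutation test for both
#' tails, summarises the positive-tail contributing network anatomically (if
#' an atlas is given), and writes a JSON summary plus edge-set TSVs to the
#' output directory. Reruns with the same configuration and seed produce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly; written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cpm_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  coh <- stage("load", read_cohort(config$cohort_dir, config$scores_path))
  atlas <- if (!is.null(config$atlas_path))
    stage("load", read_atlas(config$atlas_path))
  perm <- stage("predict",
                cpm_permutation(coh, threshold = config$threshold,
                                n_perm = config$n_perm, seed = config$seed))
  fit <- perm$fit

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sel_full <- stage("predict", select_edges(coh, config$threshold))
  write_edges(sel_full, file.path(config$out_dir, "edges_full_sample.tsv"))

  summary <- list(
    package_version = as.character(utils::packageVersion("cpmr")),
    config = config[c("threshold", "n_perm", "seed", "top_k")],
    n_subjects = coh$n_subjects, n_nodes = coh$n_nodes,
    n_candidate_edges = coh$n_nodes * (coh$n_nodes - 1) / 2
  )
  for (tail in c("positive", "negative")) {
    ctb <- fit[[tail]]$contributing_edges
    summary[[tail]] <- list(
      rho_pred_obs = fit[[tail]]$rho_pred_obs,
      p_perm = perm[[tail]]$p_perm,
      n_contributing_edges = length(ctb),
      contributing_fraction_pct =
        100 * length(ctb) / summary$n_candidate_edges,
      n_empty_folds = fit[[tail]]$n_empty_folds
    )
  }
  if (!is.null(atlas)) {
    ctb <- fit$positive$contributing_edges
    deg <- node_degree(ctb, coh$n_nodes)
    summary$anatomy <- list(
      region_counts = stage("anatomy",
        region_edge_counts(ctb, atlas, "region"))$counts,
      network_counts = stage("anatomy",
        region_edge_counts(ctb, atlas, "network"))$counts,
      top_nodes = top_nodes(deg, min(config$top_k, coh$n_nodes), atlas)
    )
    utils::write.table(summary$anatomy$top_nodes,
                       file.path(config$out_dir, "top_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
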