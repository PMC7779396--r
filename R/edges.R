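#' Enumerate candidate edges of an undirected connectome
#'
#' Candidate edges are the upper-triangle node pairs (i < j) of a symmetric
#' node-by-node connectivity matrix, enumerated row-major:
#' (1,2), (1,3), ..., (1,N), (2,3), ... This fixed order is used everywhere an
#' edge set is stored or written to disk, so edge indices are reproducible
#' across runs and across files.
#'
#' @param n_nodes number of nodes (>= 2).
#' @return Integer matrix with columns `i`, `j` (1-based node indices,
#'   `i < j`) and `n_nodes * (n_nodes - 1) / 2` rows.
#' @examples
#' edge_index(4)
#' nrow(edge_index(268)) # 35778 candidate edges
#' @export
edge_index <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Extract the subject-by-edge weight matrix of a cohort
#'
#' Flattens each subject's symmetric connectivity matrix into the row-major
#' upper-triangle edge order of [edge_index()].
#'
#' @param cohort a [cohort] object.
#' @return Numeric matrix, `n_subjects` rows by `n_nodes*(n_nodes-1)/2`
#'   columns; rownames are subject ids.
#' @export
edge_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  idx <- edge_index(cohort$n_nodes)
  flat <- cbind(idx[, 1L], idx[, 2L])
  E <- t(vapply(cohort$matrices, function(m) m[flat],
                numeric(nrow(idx))))
  rownames(E) <- cohort$subject_ids
  E
}

# Map edge pairs (i, j) to their position in the row-major upper-triangle
# enumeration. Accepts a 2-column matrix; validates i < j after sorting.
edge_pos <- function(pairs, n_nodes) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  lo <- pmin(pairs[, 1L], pairs[, 2L])
  hi <- pmax(pairs[, 1L], pairs[, 2L])
  if (any(lo < 1L | hi > n_nodes | lo == hi))
    stop("edge node indices out of range for n_nodes = ", n_nodes,
         call. = FALSE)
  # edges preceding row lo: sum over r < lo of (n - r); offset within row
  (lo - 1L) * n_nodes - (lo * (lo - 1L)) %/% 2L + (hi - lo)
}
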