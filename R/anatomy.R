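# Anatomical summarisation of a predictive edge set: where in the brain the
# selected edges fall, at the macroscale-region or canonical-network level.

# normalise an edge argument: indices in edge_index() order, or node pairs
edges_as_pairs <- function(edges, n_nodes) {
  if (is.matrix(edges) && ncol(edges) == 2L) {
    pairs <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
  } else {
    idx <- edge_index(n_nodes)
    edges <- as.integer(edges)
    if (length(edges) && any(edges < 1L | edges > nrow(idx)))
      stop("edge index out of range", call. = FALSE)
    pairs <- idx[edges, , drop = FALSE]
  }
  storage.mode(pairs) <- "integer"
  pairs
}

#' Count predictive edges within and between anatomical groupings
#'
#' Builds the symmetric label-by-label matrix whose cell (A, B) counts the
#' edges with one endpoint in grouping A and the other in B; within-group
#' edges sit on the diagonal. The diagonal plus the upper triangle always
#' totals the number of input edges.
#'
#' @param edges integer edge indices (in [edge_index()] order) or a 2-column
#'   matrix of node pairs.
#' @param atlas a node atlas ([make_atlas()] or [read_atlas()]).
#' @param level `"region"` (macroscale regions) or `"network"` (canonical
#'   networks).
#' @return Object of class `cpm_region_counts`: list with `labels` (in
#'   atlas order) and `counts` (symmetric integer matrix).
#' @export
region_edge_counts <- function(edges, atlas, level = c("region", "network")) {
  level <- match.arg(level)
  pairs <- edges_as_pairs(edges, max(atlas$node_id))
  if (length(pairs) && any(!(pairs %in% atlas$node_id)))
    stop("edge references node ids absent from the atlas", call. = FALSE)
  labels <- unique(atlas[[level]])
  lab <- atlas[[level]][match(seq_len(max(atlas$node_id)), atlas$node_id)]
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(labels, labels))
  if (nrow(pairs)) {
    a <- match(lab[pairs[, 1L]], labels)
    b <- match(lab[pairs[, 2L]], labels)
    for (k in seq_along(a)) {
      counts[a[k], b[k]] <- counts[a[k], b[k]] + 1L
      if (a[k] != b[k]) counts[b[k], a[k]] <- counts[b[k], a[k]] + 1L
    }
  }
  structure(list(labels = labels, counts = counts, level = level),
            class = "cpm_region_counts")
}

#' @export
print.cpm_region_counts <- function(x, ...) {
  cat("Edge counts by", x$level, "(",
      sum(x$counts[upper.tri(x$counts, diag = TRUE)]), "edges )\n")
  print(x$counts)
  invisible(x)
}

#' Node degree within a predictive edge set
#'
#' The number of selected edges incident to each node; the standard
#' node-importance measure for a contributing network. Degrees always sum to
#' twice the number of edges.
#'
#' @param edges edge indices or 2-column node-pair matrix.
#' @param n_nodes total number of nodes.
#' @return Integer degree vector of length `n_nodes`.
#' @export
node_degree <- function(edges, n_nodes) {
  pairs <- edges_as_pairs(edges, n_nodes)
  if (length(pairs) && any(pairs > n_nodes))
    stop("edge node index exceeds n_nodes", call. = FALSE)
  tabulate(as.vector(pairs), nbins = n_nodes)
}

#' Highest-degree nodes of a predictive network
#'
#' Ranks nodes by degree; ties are broken deterministically by ascending
#' node index and flagged in the report (a tie at the cut means the k-th
#' node's degree also occurs beyond rank k).
#'
#' @param degrees degree vector (from [node_degree()]).
#' @param k number of nodes to report.
#' @param atlas optional atlas supplying region/network labels and
#'   coordinates.
#' @return `data.frame` with columns `rank`, `node_id`, `degree`, and, if an
#'   atlas is given, `region`, `network`, `x`, `y`, `z`; attribute
#'   `tie_at_cut` notes an ambiguous cut.
#' @export
top_nodes <- function(degrees, k = 10, atlas = NULL) {
  n <- length(degrees)
  if (k > n) stop("k exceeds the number of nodes", call. = FALSE)
  ord <- order(-degrees, seq_len(n))
  top <- ord[seq_len(k)]
  out <- data.frame(rank = seq_len(k), node_id = top,
                    degree = degrees[top])
  if (!is.null(atlas)) {
    at <- atlas[match(top, atlas$node_id), ]
    out$region <- at$region
    out$network <- at$network
    out$x <- at$x; out$y <- at$y; out$z <- at$z
  }
  tie <- k < n && degrees[ord[k]] == degrees[ord[k + 1L]]
  attr(out, "tie_at_cut") <- tie
  if (tie)
    message("degree tie at rank ", k,
            "; ties broken by ascending node index")
  out
}
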