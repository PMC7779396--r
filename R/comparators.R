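# Comparator models: linear-kernel support vector regression on
# CPM-selected edges, and linear support vector classification of binary
# diagnosis labels from all candidate edges.

# standardise training features; apply the same affine map to test rows.
# zero-variance features get unit scale so they pass through as constants.
scale_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu, check.margin = FALSE), 2L, sdv, "/"))
}

#' Support vector regression on CPM-selected edge features
#'
#' Within each leave-one-out fold, edges are selected exactly as in
#' [select_edges()] (both tails pooled), the per-edge Fisher-z weights (not
#' their sum) form the feature vector, features are standardised within the
#' fold, and a linear-kernel epsilon-SVR with cost 1 predicts the held-out
#' subject. Performance is the Spearman correlation of predicted vs observed
#' scores; folds with no selected edges predict the training mean.
#'
#' @param cohort a [cohort].
#' @param threshold edge-selection p-value threshold.
#' @param cost SVR regularisation constant.
#' @return List with `predicted`, `observed`, `rho_pred_obs`,
#'   `n_empty_folds`.
#' @export
svr_predict <- function(cohort, threshold = 0.05, cost = 1) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  if (cohort$n_subjects < 10L)
    stop("LOOCV needs at least 10 subjects", call. = FALSE)
  E <- edge_matrix(cohort)
  n <- cohort$n_subjects
  pre <- cpm_precompute(E, cache_bytes = 0)
  Rs <- rank(cohort$scores)
  score_ties <- anyDuplicated(cohort$scores) > 0L
  rho_crit <- spearman_rho_crit(threshold, n - 1L)
  pred <- numeric(n)
  n_empty <- 0L
  for (i in seq_len(n)) {
    Rk <- fold_rank_matrix(E, pre$R_full, i, pre$ties)
    sr <- fold_score_ranks(cohort$scores, Rs, i, score_ties)
    m <- n - 1L
    cs <- colSums(Rk); cq <- colSums(Rk^2)
    num <- drop(crossprod(Rk, sr)) - cs * (sum(sr) / m)
    den2 <- (cq - cs^2 / m) * (sum(sr^2) - sum(sr)^2 / m)
    rho <- ifelse(den2 > 0, num / sqrt(pmax(den2, 1e-300)), 0)
    sel <- which(abs(rho) > rho_crit)
    if (length(sel) == 0L) {
      pred[i] <- mean(cohort$scores[-i])
      n_empty <- n_empty + 1L
      next
    }
    sc <- scale_fold(E[-i, sel, drop = FALSE],
                     E[i, sel, drop = FALSE])
    fit <- e1071::svm(sc$train, cohort$scores[-i], kernel = "linear",
                      cost = cost, type = "eps-regression", scale = FALSE)
    pred[i] <- stats::predict(fit, sc$test)
  }
  if (n_empty > 0)
    message(n_empty, " fold(s) selected no edges; training mean predicted")
  list(predicted = pred, observed = cohort$scores,
       rho_pred_obs = safe_rho(pred, cohort$scores),
       n_empty_folds = n_empty)
}

# stratified fold assignment: each class is split as evenly as possible
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Linear SVM classification of cases vs controls from edge features
#'
#' Stratified k-fold cross-validated linear support vector classification on
#' all upper-triangle edge weights, with within-fold standardisation and
#' cost 1. Sensitivity and specificity come from the pooled out-of-fold
#' predictions (cases = second factor level); balanced accuracy is their
#' mean. The per-edge importance map is the mean absolute SVM weight across
#' folds, optionally aggregated to a region ranking through an atlas. An
#' optional permutation test shuffles the labels and recomputes the pooled
#' balanced accuracy.
#'
#' @param cohort a [cohort] with binary `labels` (>= 5 per class).
#' @param n_folds number of stratified folds.
#' @param seed integer seed (fold assignment and permutations).
#' @param n_perm label permutations for the p-value (0 = skip).
#' @param atlas optional atlas for the region ranking.
#' @param cost SVM regularisation constant.
#' @return Object of class `cpm_classification`: `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `p_perm` (or `NA`), `weight_map`
#'   (per-edge mean |w|), `node_importance`, `top_regions` (if atlas given),
#'   `predicted`, `labels`.
#' @export
svm_classify <- function(cohort, n_folds = 10, seed = 1L, n_perm = 0,
                         atlas = NULL, cost = 1) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  labels <- cohort$labels
  if (is.null(labels) || nlevels(droplevels(labels)) != 2L)
    stop("cohort must carry binary labels with both classes present",
         call. = FALSE)
  labels <- droplevels(labels)
  if (min(table(labels)) < 5L)
    stop("need at least 5 subjects per class", call. = FALSE)
  E <- edge_matrix(cohort)

  run_cv <- function(lab) {
    fold <- stratified_folds(lab, n_folds)
    pred <- factor(rep(NA_character_, length(lab)), levels = levels(lab))
    W <- matrix(0, n_folds, ncol(E))
    for (f in seq_len(n_folds)) {
      te <- fold == f
      sc <- scale_fold(E[!te, , drop = FALSE], E[te, , drop = FALSE])
      fit <- e1071::svm(sc$train, lab[!te], kernel = "linear", cost = cost,
                        type = "C-classification", scale = FALSE)
      pred[te] <- stats::predict(fit, sc$test)
      W[f, ] <- abs(drop(crossprod(fit$coefs, fit$SV)))
    }
    list(pred = pred, W = W)
  }
  metrics <- function(pred, lab) {
    pos <- levels(lab)[2L]
    sens <- mean(pred[lab == pos] == pos)
    spec <- mean(pred[lab != pos] != pos)
    c(bal = (sens + spec) / 2, sens = sens, spec = spec)
  }

  cv <- with_seed(seed, run_cv(labels))
  m <- metrics(cv$pred, labels)
  weight_map <- colMeans(cv$W)

  p_perm <- NA_real_
  if (n_perm > 0) {
    nulls <- with_seed(seed + 1L, vapply(seq_len(n_perm), function(b) {
      lab_b <- sample(labels)
      metrics(run_cv(lab_b)$pred, lab_b)[["bal"]]
    }, numeric(1)))
    p_perm <- (sum(nulls >= m[["bal"]]) + 1) / (n_perm + 1)
  }

  node_imp <- node_weight_sums(weight_map, cohort$n_nodes)
  top_regions <- NULL
  if (!is.null(atlas)) {
    reg <- atlas$region[match(seq_len(cohort$n_nodes), atlas$node_id)]
    agg <- tapply(node_imp, reg, mean)
    top_regions <- names(sort(agg, decreasing = TRUE))
  }
  structure(
    list(balanced_accuracy = unname(m[["bal"]]),
         sensitivity = unname(m[["sens"]]),
         specificity = unname(m[["spec"]]),
         p_perm = p_perm, weight_map = weight_map,
         node_importance = node_imp, top_regions = top_regions,
         predicted = cv$pred, labels = labels, n_folds = n_folds),
    class = "cpm_classification"
  )
}

# per-node sum of edge importances over incident edges
node_weight_sums <- function(weight_map, n_nodes) {
  idx <- edge_index(n_nodes)
  out <- numeric(n_nodes)
  for (col in 1:2) {
    s <- tapply(weight_map, idx[, col], sum)
    out[as.integer(names(s))] <- out[as.integer(names(s))] + s
  }
  out
}

#' @export
print.cpm_classification <- function(x, ...) {
  cat(sprintf(
    "Linear SVM (%d-fold): balanced accuracy %.1f%% (sens %.1f%%, spec %.1f%%)",
    x$n_folds, 100 * x$balanced_accuracy, 100 * x$sensitivity,
    100 * x$specificity))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}
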