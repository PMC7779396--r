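# Connectome-based predictive modeling: Spearman edge selection, signed
# network strength, linear models under leave-one-out cross-validation, and
# permutation inference.
#
# Edge selection repeats inside every cross-validation fold and every
# permutation, so the engine works on the subject-by-edge weight matrix with
# precomputed per-fold rank matrices: Spearman correlations reduce to one
# matrix-vector product per fold, and rank updates after removing one
# subject are O(1) per entry when the data are tie-free.

# two-sided p-value of a Spearman rho via the t-distribution approximation
# (average-rank ties); m = number of observations
spearman_p <- function(rho, m) {
  rho2 <- pmin(rho^2, 1 - 1e-15)
  t_stat <- abs(rho) * sqrt((m - 2) / (1 - rho2))
  2 * stats::pt(-t_stat, df = m - 2)
}

# |rho| that corresponds exactly to a two-sided t-approximation p-value of
# `threshold` at m observations; selection "p < threshold" == "|rho| > crit"
spearman_rho_crit <- function(threshold, m) {
  t_crit <- stats::qt(1 - threshold / 2, df = m - 2)
  t_crit / sqrt(m - 2 + t_crit^2)
}

#' Select score-correlated edges in a training cohort
#'
#' For every candidate (upper-triangle) edge, computes the Spearman rank
#' correlation between edge weights and behavioural scores across the
#' training subjects, with a two-sided p-value from the t-distribution
#' approximation. Edges with `p < threshold` are split by the sign of rho
#' into the positive and negative predictive networks; the two sets are
#' disjoint by construction.
#'
#' @param train a [cohort] with at least 5 subjects.
#' @param threshold selection p-value threshold in (0, 1); default 0.05.
#' @return Object of class `cpm_edge_selection`: list with
#'   `positive_edges` / `negative_edges` (integer indices into
#'   [edge_index()] order), `rho`, `p` (per-edge vectors over all candidate
#'   edges), `threshold`, `n_nodes`.
#' @export
select_edges <- function(train, threshold = 0.05) {
  stopifnot(inherits(train, "cpm_cohort"))
  if (train$n_subjects < 5L)
    stop("need at least 5 training subjects", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (stats::sd(train$scores) == 0)
    stop("behavioural scores are constant; selection is undefined",
         call. = FALSE)
  E <- edge_matrix(train)
  rho <- drop(suppressWarnings(
    stats::cor(E, train$scores, method = "spearman")))
  rho[is.na(rho)] <- 0 # constant edges carry no information
  p <- spearman_p(rho, train$n_subjects)
  sel <- p < threshold
  structure(
    list(positive_edges = which(sel & rho > 0),
         negative_edges = which(sel & rho < 0),
         rho = rho, p = p, threshold = threshold, n_nodes = train$n_nodes),
    class = "cpm_edge_selection"
  )
}

#' @export
print.cpm_edge_selection <- function(x, ...) {
  cat("CPM edge selection at p <", x$threshold, ":",
      length(x$positive_edges), "positive,",
      length(x$negative_edges), "negative of",
      length(x$rho), "candidate edges\n")
  invisible(x)
}

#' Network strength: summed edge weights over an edge set
#'
#' The single-subject summary the CPM linear model is fit on: the sum of
#' Fisher-z weights over the selected edges. An empty edge set has strength
#' 0 by convention.
#'
#' @param m symmetric connectivity matrix.
#' @param edges integer vector of edge indices in [edge_index()] order, or a
#'   2-column matrix of node pairs.
#' @return Scalar strength.
#' @export
network_strength <- function(m, edges) {
  n_nodes <- nrow(m)
  if (is.matrix(edges)) edges <- edge_pos(edges, n_nodes)
  if (length(edges) == 0L) return(0)
  idx <- edge_index(n_nodes)
  if (any(edges < 1L | edges > nrow(idx)))
    stop("edge index out of range", call. = FALSE)
  sum(m[idx[edges, , drop = FALSE]])
}

#' Ordinary least-squares line through strength/score pairs
#'
#' Degree-1 fit used to map network strength to a predicted score. If the
#' strengths are constant the slope is undefined; the fit falls back to
#' slope 0 with intercept at the mean score and flags it.
#'
#' @param strengths,scores numeric vectors of equal length >= 2.
#' @return List with `slope`, `intercept`, and `constant` (fallback flag).
#' @export
fit_linear <- function(strengths, scores) {
  if (length(strengths) != length(scores) || length(scores) < 2L)
    stop("need two aligned vectors of length >= 2", call. = FALSE)
  sx <- strengths - mean(strengths)
  sxx <- sum(sx^2)
  if (sxx == 0)
    return(list(slope = 0, intercept = mean(scores), constant = TRUE))
  slope <- sum(sx * scores) / sxx
  list(slope = slope, intercept = mean(scores) - slope * mean(strengths),
       constant = FALSE)
}

#' Spearman correlation between predicted and observed scores
#'
#' Model performance measure: Spearman rank correlation with average-rank
#' tie handling.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return Spearman rho.
#' @export
evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    stop("need two aligned vectors of length >= 3", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(predicted, observed, method = "spearman")
}

# ---- internal fast LOOCV engine ------------------------------------------

# Precompute, from the subject-by-edge matrix E, the per-fold (leave one
# subject out) column rank matrices plus their column sums/sums of squares.
# When no column has ties, fold ranks follow from the full-sample ranks by
# decrementing ranks above the removed subject's; with ties each fold is
# ranked directly. Cached matrices are reused across permutations.
cpm_precompute <- function(E, cache_bytes = 1.5e9) {
  n <- nrow(E); p <- ncol(E); m <- n - 1L
  R_full <- apply(E, 2L, rank)
  ties <- any(apply(E, 2L, anyDuplicated) > 0L)
  # the cache only serves the R fallback path; tie-free data go through the
  # compiled engine, which derives fold ranks from R_full directly
  cache <- ties && (as.double(n) * m * p * 8) < cache_bytes
  fold_ranks <- if (cache) vector("list", n)
  csum <- css <- NULL
  if (cache) {
    csum <- matrix(0, n, p); css <- matrix(0, n, p)
    for (i in seq_len(n)) {
      Rk <- fold_rank_matrix(E, R_full, i, ties)
      fold_ranks[[i]] <- Rk
      csum[i, ] <- colSums(Rk)
      css[i, ] <- colSums(Rk^2)
    }
  }
  list(E = E, n = n, p = p, R_full = R_full, ties = ties, cache = cache,
       fold_ranks = fold_ranks, csum = csum, css = css)
}

fold_rank_matrix <- function(E, R_full, i, ties) {
  m <- nrow(E) - 1L
  if (!ties) {
    Rk <- R_full[-i, , drop = FALSE]
    Rk - (Rk > matrix(R_full[i, ], m, ncol(E), byrow = TRUE))
  } else {
    apply(E[-i, , drop = FALSE], 2L, rank)
  }
}

# ranks of scores within fold -i, given full-sample ranks (tie-free scores)
fold_score_ranks <- function(scores, Rs, i, ties) {
  if (!ties) {
    r <- Rs[-i]
    r - (r > Rs[i])
  } else {
    rank(scores[-i])
  }
}

# One complete LOOCV pass. Returns per-tail predictions, per-fold edge sets
# (unless `light`), and fold model coefficients. `pre` is a cpm_precompute()
# result for the cohort's edge matrix. Tie-free data run through the
# compiled engine; tied columns or tied scores fall back to the R path,
# which ranks each fold with average-rank tie handling.
loocv_engine <- function(pre, scores, threshold, light = FALSE) {
  n <- pre$n; p <- pre$p; m <- n - 1L
  Rs <- rank(scores)
  score_ties <- anyDuplicated(scores) > 0L
  rho_crit <- spearman_rho_crit(threshold, m)
  if (!pre$ties && !score_ties) {
    out <- .cpp_loocv(pre$E, pre$R_full, Rs, scores, rho_crit, !light)
    colnames(out$pred) <- c("pos", "neg")
    if (light) out$pos_sets <- out$neg_sets <- NULL
    return(out)
  }
  pred <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("pos", "neg")))
  empty <- matrix(FALSE, n, 2L)
  pos_sets <- neg_sets <- if (!light) vector("list", n)
  slopes <- intercepts <- matrix(NA_real_, n, 2L)

  for (i in seq_len(n)) {
    if (pre$cache) {
      Rk <- pre$fold_ranks[[i]]
      cs <- pre$csum[i, ]; cq <- pre$css[i, ]
    } else {
      Rk <- fold_rank_matrix(pre$E, pre$R_full, i, pre$ties)
      cs <- colSums(Rk); cq <- colSums(Rk^2)
    }
    sr <- fold_score_ranks(scores, Rs, i, score_ties)
    ssum <- sum(sr); ssq <- sum(sr^2)
    num <- drop(crossprod(Rk, sr)) - cs * (ssum / m)
    den2 <- (cq - cs^2 / m) * (ssq - ssum^2 / m)
    rho <- ifelse(den2 > 0, num / sqrt(pmax(den2, 1e-300)), 0)
    pos <- which(rho > rho_crit)
    neg <- which(rho < -rho_crit)
    train_scores <- scores[-i]
    for (tail in 1:2) {
      sel <- if (tail == 1L) pos else neg
      if (length(sel) == 0L) {
        pred[i, tail] <- mean(train_scores)
        empty[i, tail] <- TRUE
        slopes[i, tail] <- 0
        intercepts[i, tail] <- mean(train_scores)
      } else {
        s_all <- rowSums(pre$E[, sel, drop = FALSE])
        fit <- fit_linear(s_all[-i], train_scores)
        pred[i, tail] <- fit$intercept + fit$slope * s_all[i]
        slopes[i, tail] <- fit$slope
        intercepts[i, tail] <- fit$intercept
      }
    }
    if (!light) {
      pos_sets[[i]] <- pos
      neg_sets[[i]] <- neg
    }
  }
  list(pred = pred, empty = empty, pos_sets = pos_sets,
       neg_sets = neg_sets, slopes = slopes, intercepts = intercepts)
}

# Spearman rho of predictions vs observed, returning 0 (not an error) for
# degenerate constant predictions, which arise under permuted scores when no
# edges survive selection in any fold.
safe_rho <- function(predicted, observed) {
  if (stats::sd(predicted) == 0) return(0)
  stats::cor(predicted, observed, method = "spearman")
}

#' Leave-one-out cross-validated CPM prediction
#'
#' For each subject in turn: edges are selected on the remaining subjects at
#' the given threshold, a linear model is fit per tail (positive and
#' negative predictive network) on summed network strength, and the held-out
#' subject's score is predicted from its own strength. Folds in which a tail
#' selects no edges predict the training-mean score and are counted in
#' `n_empty_folds`. The contributing network of a tail is the set of edges
#' selected in *every* fold.
#'
#' @param cohort a [cohort] with at least 10 subjects.
#' @param threshold edge-selection p-value threshold.
#' @param keep_fold_edges store per-fold edge sets and coefficients (needed
#'   for the contributing network; disable only for speed in nulls).
#' @return Object of class `cpm_result`: a list with one element per tail
#'   (`positive`, `negative`), each containing `predicted`, `observed`,
#'   `rho_pred_obs`, `contributing_edges`, `per_fold_edges`, `coefs`,
#'   `n_empty_folds`; plus `threshold`, `n_nodes`.
#' @examples
#' cfg <- sim_config(n_subjects = 30, n_nodes = 8,
#'                   planted_positive_edges = list(c(1, 2)),
#'                   effect_size = 0.8, seed = 2)
#' res <- cpm_loocv(simulate_cohort(cfg))
#' res$positive$rho_pred_obs
#' @export
cpm_loocv <- function(cohort, threshold = 0.05, keep_fold_edges = TRUE) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  if (cohort$n_subjects < 10L)
    stop("LOOCV needs at least 10 subjects", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (stats::sd(cohort$scores) == 0)
    stop("behavioural scores are constant", call. = FALSE)
  E <- edge_matrix(cohort)
  pre <- cpm_precompute(E, cache_bytes = 0) # single pass: no cache needed
  eng <- loocv_engine(pre, cohort$scores, threshold,
                      light = !keep_fold_edges)
  tail_result <- function(k, sets) {
    list(predicted = unname(eng$pred[, k]), observed = cohort$scores,
         rho_pred_obs = safe_rho(eng$pred[, k], cohort$scores),
         contributing_edges = if (keep_fold_edges)
           Reduce(intersect, sets),
         per_fold_edges = if (keep_fold_edges) sets,
         coefs = cbind(slope = eng$slopes[, k],
                       intercept = eng$intercepts[, k]),
         n_empty_folds = sum(eng$empty[, k]))
  }
  structure(
    list(positive = tail_result(1L, eng$pos_sets),
         negative = tail_result(2L, eng$neg_sets),
         threshold = threshold, n_nodes = cohort$n_nodes,
         n_subjects = cohort$n_subjects),
    class = "cpm_result"
  )
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("CPM LOOCV over", x$n_subjects, "subjects (threshold p <",
      x$threshold, ")\n")
  for (tail in c("positive", "negative")) {
    t <- x[[tail]]
    cat(sprintf("  %s tail: rho(pred, obs) = %.3f", tail, t$rho_pred_obs))
    if (!is.null(t$contributing_edges))
      cat(",", length(t$contributing_edges), "contributing edges")
    if (t$n_empty_folds > 0)
      cat(",", t$n_empty_folds, "empty folds")
    cat("\n")
  }
  invisible(x)
}

#' Permutation test for cross-validated prediction performance
#'
#' Breaks the correspondence between scores and connectivity matrices by
#' shuffling the scores `n_perm` times and re-running the complete LOOCV
#' (including within-fold edge selection) on each shuffle. The p-value per
#' tail is `(#{null rho >= observed rho} + 1) / (n_perm + 1)`, one-sided
#' toward positive prediction performance, whose smallest attainable value
#' at 1,000 shuffles is 1/1001, printed as 0.001.
#'
#' @param cohort a [cohort].
#' @param threshold edge-selection p-value threshold.
#' @param n_perm number of shuffles (>= 100).
#' @param seed integer seed for the shuffles.
#' @return Object of class `cpm_permutation`: per tail, `observed_rho`,
#'   `null_rhos`, `p_perm`; plus the [cpm_loocv()] result as `fit`.
#' @export
cpm_permutation <- function(cohort, threshold = 0.05, n_perm = 1000,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  if (n_perm < 100L)
    stop("n_perm must be at least 100", call. = FALSE)
  fit <- cpm_loocv(cohort, threshold)
  E <- edge_matrix(cohort)
  pre <- cpm_precompute(E)
  nulls <- matrix(NA_real_, n_perm, 2L,
                  dimnames = list(NULL, c("pos", "neg")))
  perms <- with_seed(seed, replicate(n_perm, sample.int(cohort$n_subjects),
                                     simplify = FALSE))
  for (b in seq_len(n_perm)) {
    sc <- cohort$scores[perms[[b]]]
    eng <- loocv_engine(pre, sc, threshold, light = TRUE)
    nulls[b, 1L] <- safe_rho(eng$pred[, 1L], sc)
    nulls[b, 2L] <- safe_rho(eng$pred[, 2L], sc)
  }
  tail_res <- function(k, obs) {
    list(observed_rho = obs, null_rhos = nulls[, k],
         p_perm = (sum(nulls[, k] >= obs) + 1) / (n_perm + 1))
  }
  structure(
    list(positive = tail_res(1L, fit$positive$rho_pred_obs),
         negative = tail_res(2L, fit$negative$rho_pred_obs),
         fit = fit, n_perm = n_perm, seed = seed),
    class = "cpm_permutation"
  )
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat("CPM permutation test,", x$n_perm, "shuffles\n")
  for (tail in c("positive", "negative"))
    cat(sprintf("  %s tail: rho = %.3f, p = %.4g\n", tail,
                x[[tail]]$observed_rho, x[[tail]]$p_perm))
  invisible(x)
}

#' Screen behavioural scores against nuisance covariates
#'
#' Reports the Pearson correlation of scores with age and with mean
#' framewise displacement, and a Wilcoxon rank-sum comparison of scores
#' between sexes. Covariates that are absent (or degenerate, e.g. a
#' single-sex cohort) are omitted with a warning.
#'
#' @param cohort a [cohort] with a `covariates` data frame.
#' @return Named list with any of `rho_age`, `p_age`, `rho_fd`, `p_fd`,
#'   `sex_test_p`.
#' @export
covariate_screen <- function(cohort) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  cov <- cohort$covariates
  if (is.null(cov)) stop("cohort has no covariates", call. = FALSE)
  out <- list()
  if (!is.null(cov$age)) {
    ct <- stats::cor.test(cohort$scores, cov$age)
    out$rho_age <- unname(ct$estimate); out$p_age <- ct$p.value
  } else warning("no age covariate; skipped", call. = FALSE)
  if (!is.null(cov$mean_fd)) {
    ct <- stats::cor.test(cohort$scores, cov$mean_fd)
    out$rho_fd <- unname(ct$estimate); out$p_fd <- ct$p.value
  } else warning("no mean_fd covariate; skipped", call. = FALSE)
  if (!is.null(cov$sex) && length(unique(cov$sex)) == 2L) {
    out$sex_test_p <- stats::wilcox.test(
      cohort$scores ~ factor(cov$sex))$p.value
  } else warning("sex comparison skipped (missing or single-sex cohort)",
                 call. = FALSE)
  out
}
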