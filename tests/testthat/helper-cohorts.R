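# shared fixtures, all generated in code

# small cohort with hand-set edge weights: matrices built from a
# subject-by-edge matrix in edge_index() order
cohort_from_edges <- function(E, scores, n_nodes, ...) {
  idx <- edge_index(n_nodes)
  mats <- lapply(seq_len(nrow(E)), function(s) {
    m <- matrix(0, n_nodes, n_nodes)
    m[idx] <- E[s, ]
    m + t(m)
  })
  cohort(mats, scores, ...)
}

# random tie-free cohort for oracle-equivalence checks
random_cohort <- function(n_subjects, n_nodes, seed) {
  set.seed(seed)
  p <- n_nodes * (n_nodes - 1) / 2
  E <- matrix(rnorm(n_subjects * p), n_subjects, p)
  cohort_from_edges(E, rnorm(n_subjects, 50, 20), n_nodes)
}

# brute-force LOOCV oracle: per fold, rank-then-Pearson Spearman per edge,
# t-approximation p-value, lm() fit on summed strengths
brute_loocv <- function(coh, threshold = 0.05) {
  n <- coh$n_subjects
  E <- edge_matrix(coh)
  pred <- matrix(NA_real_, n, 2)
  pos_sets <- neg_sets <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n - 1
    rho <- apply(E[-i, , drop = FALSE], 2, function(e)
      cor(rank(e), rank(coh$scores[-i])))
    p <- 2 * pt(-abs(rho) * sqrt((m - 2) / (1 - rho^2)), m - 2)
    for (k in 1:2) {
      sel <- which(p < threshold & (if (k == 1) rho > 0 else rho < 0))
      if (k == 1) pos_sets[[i]] <- sel else neg_sets[[i]] <- sel
      if (length(sel) == 0) {
        pred[i, k] <- mean(coh$scores[-i])
      } else {
        s <- rowSums(E[, sel, drop = FALSE])
        f <- lm(coh$scores[-i] ~ s[-i])
        pred[i, k] <- sum(coef(f) * c(1, s[i]))
      }
    }
  }
  list(pred = pred, pos_sets = pos_sets, neg_sets = neg_sets)
}
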