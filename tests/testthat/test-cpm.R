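test_that("perfectly monotone edges are selected with rho = +/-1", {
  set.seed(1)
  scores <- sample(seq(10, 90, length.out = 20))
  E <- matrix(rnorm(20 * 10, 0.3, 0.01), 20, 10)
  E[, 1] <- rank(scores) # perfect monotone increasing
  E[, 2] <- -scores      # perfect antitone
  coh <- cohort_from_edges(E, scores, 5)
  sel <- select_edges(coh, 0.05)
  expect_true(1 %in% sel$positive_edges)
  expect_true(2 %in% sel$negative_edges)
  expect_equal(sel$rho[1], 1)
  expect_equal(sel$rho[2], -1)
  expect_true(all(sel$p[sel$positive_edges] < 0.05))
  expect_length(intersect(sel$positive_edges, sel$negative_edges), 0)
})

test_that("selection validates its inputs", {
  coh <- random_cohort(4, 5, seed = 2)
  expect_error(select_edges(coh), "at least 5")
  coh2 <- random_cohort(10, 5, seed = 2)
  coh2$scores <- rep(5, 10)
  expect_error(select_edges(coh2), "constant")
  expect_error(select_edges(random_cohort(10, 5, 1), threshold = 1.5),
               "threshold")
})

test_that("positive and negative selections never overlap", {
  for (s in 1:5) {
    sel <- select_edges(random_cohort(15, 8, seed = s), 0.2)
    expect_length(intersect(sel$positive_edges, sel$negative_edges), 0)
    expect_true(all(sel$rho[sel$positive_edges] > 0))
    expect_true(all(sel$rho[sel$negative_edges] < 0))
  }
})

test_that("network strength sums selected z-weights", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.3
  m[2, 3] <- m[3, 2] <- -0.2
  expect_equal(network_strength(m, rbind(c(1, 2), c(2, 3))), 0.1)
  expect_equal(network_strength(m, integer(0)), 0)
  # strength over all candidate edges equals the upper-triangle sum
  set.seed(4)
  m2 <- matrix(rnorm(25), 5, 5); m2 <- m2 + t(m2); diag(m2) <- 0
  expect_equal(network_strength(m2, seq_len(10)),
               sum(m2[upper.tri(m2)]))
})

test_that("linear fit matches exact lines and the normal-equations oracle", {
  f <- fit_linear(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  f2 <- fit_linear(c(0, 1), c(5, 5))
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 5)
  f3 <- fit_linear(c(2, 2, 2), c(1, 5, 9)) # constant strengths: fallback
  expect_true(f3$constant)
  expect_equal(f3$intercept, 5)
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  f4 <- fit_linear(x, y)
  beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(f4$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f4$slope, beta[2], tolerance = 1e-10)
})

test_that("evaluation is Spearman with average-rank ties", {
  x <- c(10, 20, 30, 40)
  expect_equal(evaluate(x, x), 1)
  expect_equal(evaluate(x, rev(x)), -1)
  set.seed(7)
  a <- sample(1:5, 30, replace = TRUE) # heavy ties
  b <- a + rnorm(30)
  expect_equal(evaluate(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(evaluate(rep(1, 5), 1:5), "constant")
})

test_that("LOOCV has one prediction and edge set per subject", {
  coh <- random_cohort(10, 5, seed = 9)
  res <- cpm_loocv(coh, threshold = 0.2)
  expect_length(res$positive$predicted, 10)
  expect_length(res$positive$per_fold_edges, 10)
  expect_length(res$negative$per_fold_edges, 10)
  expect_equal(res$positive$contributing_edges,
               Reduce(intersect, res$positive$per_fold_edges))
  expect_error(cpm_loocv(random_cohort(8, 5, 1)), "at least 10")
})

test_that("LOOCV predictions match the brute-force oracle to 1e-10", {
  for (s in 1:3) {
    coh <- random_cohort(20, 10, seed = 40 + s)
    res <- cpm_loocv(coh, threshold = 0.1)
    oracle <- brute_loocv(coh, threshold = 0.1)
    expect_equal(res$positive$predicted, oracle$pred[, 1],
                 tolerance = 1e-10)
    expect_equal(res$negative$predicted, oracle$pred[, 2],
                 tolerance = 1e-10)
    expect_identical(lapply(res$positive$per_fold_edges, as.integer),
                     lapply(oracle$pos_sets, as.integer))
  }
})

test_that("compiled and R rank engines agree exactly", {
  coh <- random_cohort(18, 7, seed = 77)
  E <- edge_matrix(coh)
  pre <- cpmr:::cpm_precompute(E)
  expect_false(pre$ties)
  fast <- cpmr:::loocv_engine(pre, coh$scores, 0.1)
  pre$ties <- TRUE # force the R fallback
  slow <- cpmr:::loocv_engine(pre, coh$scores, 0.1)
  expect_equal(unname(fast$pred), unname(slow$pred), tolerance = 1e-12)
  expect_identical(lapply(fast$pos_sets, as.integer),
                   lapply(slow$pos_sets, as.integer))
})

test_that("tied edge weights are handled by the average-rank fallback", {
  set.seed(12)
  E <- matrix(round(rnorm(14 * 6, 0.3, 0.15), 1), 14, 6) # many ties
  scores <- rnorm(14, 50, 20)
  coh <- cohort_from_edges(E, scores, 4)
  res <- cpm_loocv(coh, threshold = 0.2)
  oracle <- brute_loocv(coh, threshold = 0.2)
  expect_equal(res$positive$predicted, oracle$pred[, 1], tolerance = 1e-10)
  expect_equal(res$negative$predicted, oracle$pred[, 2], tolerance = 1e-10)
})

test_that("planted positive edges drive out-of-sample prediction", {
  cfg <- sim_config(n_subjects = 120, n_nodes = 10,
                    planted_positive_edges = list(c(1, 2)),
                    effect_size = 0.8, seed = 13)
  res <- cpm_loocv(simulate_cohort(cfg))
  expect_gt(res$positive$rho_pred_obs, 0.5)
  expect_true(1 %in% res$positive$contributing_edges)
})

test_that("folds with no selected edges predict the training mean", {
  coh <- random_cohort(12, 5, seed = 14)
  res <- cpm_loocv(coh, threshold = 1e-8) # nothing survives selection
  expect_equal(res$positive$n_empty_folds, 12)
  expected <- vapply(1:12, function(i) mean(coh$scores[-i]), numeric(1))
  expect_equal(res$positive$predicted, expected)
})

test_that("permutation p-value uses the add-one estimator and is seeded", {
  cfg <- sim_config(n_subjects = 40, n_nodes = 6,
                    planted_positive_edges = list(c(1, 2), c(3, 4)),
                    effect_size = 0.9, seed = 15)
  coh <- simulate_cohort(cfg)
  pt <- cpm_permutation(coh, n_perm = 100, seed = 5)
  # observed beats every null: smallest attainable p is 1/(n_perm + 1)
  expect_equal(pt$positive$p_perm, 1 / 101)
  expect_equal(pt$positive$p_perm,
               (sum(pt$positive$null_rhos >= pt$positive$observed_rho) + 1) /
                 101)
  pt2 <- cpm_permutation(coh, n_perm = 100, seed = 5)
  expect_identical(pt$positive$null_rhos, pt2$positive$null_rhos)
  expect_error(cpm_permutation(coh, n_perm = 50), "at least 100")
})

test_that("covariate screen reports correlations and sex comparison", {
  coh <- random_cohort(30, 4, seed = 16)
  coh$covariates <- data.frame(
    age = coh$scores, # perfectly collinear with the score
    mean_fd = rnorm(30, 0.1, 0.02),
    sex = rep(c("m", "f"), 15)
  )
  rep <- covariate_screen(coh)
  expect_equal(rep$rho_age, 1, tolerance = 1e-12)
  expect_true(rep$p_fd > 0.001)
  expect_true(!is.null(rep$sex_test_p))

  coh$covariates$sex <- rep("f", 30)
  expect_warning(rep2 <- covariate_screen(coh), "single-sex")
  expect_null(rep2$sex_test_p)
})

test_that("independent covariates are usually non-significant", {
  cfg <- sim_config(n_subjects = 200, n_nodes = 4, seed = 17)
  coh <- simulate_cohort(cfg)
  rep <- covariate_screen(coh)
  expect_gt(rep$p_age, 0.01)
  expect_gt(rep$p_fd, 0.01)
})
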