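test_that("truncated behavioural scores hit the target mean and support", {
  s <- simulate_behavior(10000, mean = 40.1, sd = 22.3, lo = 3, hi = 95,
                         seed = 42)
  expect_true(abs(mean(s) - 40.1) < 1.0)
  expect_true(all(s >= 3 & s <= 95))
})

test_that("degenerate spread collapses scores onto the mean", {
  s <- simulate_behavior(5, mean = 40, sd = 1e-9, lo = 3, hi = 95, seed = 1)
  expect_equal(s, rep(40, 5), tolerance = 1e-6)
})

test_that("score generation is deterministic in the seed and validates input", {
  a <- simulate_behavior(50, 40, 20, 3, 95, seed = 7)
  b <- simulate_behavior(50, 40, 20, 3, 95, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_behavior(50, 40, 20, 3, 95, seed = 8)))
  expect_error(simulate_behavior(0, 40, 20, 3, 95), "positive count")
  expect_error(simulate_behavior(10, 40, -1, 3, 95), "positive")
  expect_error(simulate_behavior(10, 40, 20, 95, 3), "below")
})

test_that("skewed scores stay inside the support", {
  s <- simulate_behavior(2000, 40.1, 22.3, 3, 95, skew = 3, seed = 5)
  expect_true(all(s >= 3 & s <= 95))
  # positive skew: mean above median
  expect_gt(mean(s), median(s))
})

test_that("simulated cohorts have symmetric zero-diagonal matrices", {
  cfg <- sim_config(n_subjects = 3, n_nodes = 4, seed = 1)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$n_subjects, 3)
  for (m in coh$matrices) {
    expect_equal(dim(m), c(4, 4))
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(0, 4))
  }
})

test_that("planted edges carry the requested score correlation", {
  cfg <- sim_config(n_subjects = 200, n_nodes = 6,
                    planted_positive_edges = list(c(1, 2)),
                    effect_size = 0.8, seed = 3)
  coh <- simulate_cohort(cfg)
  w <- vapply(coh$matrices, function(m) m[1, 2], numeric(1))
  rho <- cor(w, coh$scores, method = "spearman")
  expect_true(rho > 0.6 && rho < 0.9)
})

test_that("generator calibration: mean planted-edge correlation tracks the effect size", {
  for (eff in c(0.3, 0.8)) {
    r <- vapply(1:50, function(s) {
      cfg <- sim_config(n_subjects = 200, n_nodes = 3,
                        planted_positive_edges = list(c(1, 2)),
                        effect_size = eff, seed = s)
      coh <- simulate_cohort(cfg)
      cor(vapply(coh$matrices, function(m) m[1, 2], numeric(1)), coh$scores)
    }, numeric(1))
    expect_lt(abs(mean(r) - eff), 0.05)
  }
})

test_that("negative planted edges anticorrelate with the score", {
  cfg <- sim_config(n_subjects = 150, n_nodes = 5,
                    planted_negative_edges = list(c(2, 3)),
                    effect_size = 0.7, seed = 9)
  coh <- simulate_cohort(cfg)
  w <- vapply(coh$matrices, function(m) m[2, 3], numeric(1))
  expect_lt(cor(w, coh$scores), -0.5)
})

test_that("null cohorts select edges at the nominal type-I rate", {
  hits <- total <- 0
  for (s in 1:100) {
    cfg <- sim_config(n_subjects = 30, n_nodes = 8, effect_size = 0,
                      seed = 1000 + s)
    sel <- select_edges(simulate_cohort(cfg), 0.05)
    hits <- hits + length(sel$positive_edges) + length(sel$negative_edges)
    total <- total + length(sel$rho)
  }
  expect_lt(abs(hits / total - 0.05), 0.015)
})

test_that("cohort simulation is deterministic and validates planted edges", {
  cfg <- sim_config(n_subjects = 5, n_nodes = 4, seed = 11)
  expect_identical(simulate_cohort(cfg)$matrices,
                   simulate_cohort(cfg)$matrices)
  expect_error(sim_config(n_subjects = 5, n_nodes = 4,
                          planted_positive_edges = list(c(1, 9))),
               "out of range")
  expect_error(sim_config(n_subjects = 5, n_nodes = 4,
                          planted_positive_edges = list(c(1, 2)),
                          planted_negative_edges = list(c(2, 1))),
               "disjoint")
  expect_error(sim_config(effect_size = 1), "effect_size")
})

test_that("time-series cohorts plant score-coupled node pairs", {
  cfg <- sim_config(n_subjects = 200, n_nodes = 6, n_timepoints = 150,
                    planted_positive_edges = list(c(1, 2)),
                    effect_size = 0.8, spike_fraction = 0, seed = 21)
  sim <- simulate_timeseries_cohort(cfg)
  z12 <- vapply(sim$timeseries, function(ts) connectivity(ts)[1, 2],
                numeric(1))
  expect_gt(cor(z12, sim$scores, method = "spearman"), 0.4)
})

test_that("null time-series cohorts show no edge-score association", {
  cfg <- sim_config(n_subjects = 100, n_nodes = 4, n_timepoints = 100,
                    planted_positive_edges = list(c(1, 2)),
                    effect_size = 0, spike_fraction = 0, seed = 22)
  sim <- simulate_timeseries_cohort(cfg)
  z12 <- vapply(sim$timeseries, function(ts) connectivity(ts)[1, 2],
                numeric(1))
  expect_lt(abs(cor(z12, sim$scores, method = "spearman")), 0.25)
})

test_that("synthetic FD traces carry the requested spike fraction", {
  cfg <- sim_config(n_subjects = 2, n_nodes = 3, n_timepoints = 100,
                    spike_fraction = 0.1, seed = 4)
  sim <- simulate_timeseries_cohort(cfg)
  expect_equal(sum(sim$timeseries[[1]]$fd > 0.5), 10)
  expect_equal(sim$timeseries[[1]]$fd[1], 0)
  expect_error(simulate_timeseries_cohort(
    sim_config(n_timepoints = 10, n_nodes = 3)), ">= 20")
})

test_that("block atlas assignment respects counts and rejects mismatches", {
  atlas <- make_atlas(default_region_counts(), default_network_counts())
  expect_equal(nrow(atlas), 268)
  expect_equal(as.vector(table(atlas$region)[names(default_region_counts())]),
               unname(default_region_counts()))
  small <- make_atlas(c(A = 2, B = 1), c(X = 3))
  expect_equal(small$region, c("A", "A", "B"))
  expect_equal(small$network, rep("X", 3))
  expect_error(make_atlas(c(A = 10), c(X = 9)), "same node total")
})
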