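test_that("scrubbing removes exactly the volumes above threshold", {
  ts <- time_series(matrix(1:9, 3, 3), fd = c(0.0, 0.6, 0.2))
  out <- scrub(ts, 0.5)
  expect_equal(nrow(out$data), 2)
  expect_equal(out$data, ts$data[c(1, 3), ])
  expect_equal(out$fd, c(0.0, 0.2))

  quiet <- time_series(matrix(1:9, 3, 3), fd = c(0, 0.5, 0.3))
  expect_identical(scrub(quiet, 0.5)$data, quiet$data) # 0.5 is kept: strict >

  wild <- time_series(matrix(1:9, 3, 3), fd = c(0.6, 0.7, 0.9))
  expect_error(scrub(wild, 0.5), "every volume")
})

test_that("motion exclusion uses strict thresholds on all three criteria", {
  base <- matrix(rnorm(30), 10, 3)
  expect_true(motion_exclude(time_series(base, rotation_max = 2.5)))
  expect_true(motion_exclude(time_series(base, translation_max = 2.1)))
  expect_true(motion_exclude(time_series(base, fd = rep(0.2, 10))))
  # boundary values are kept
  expect_false(motion_exclude(time_series(base, fd = rep(0.15, 10),
                                          rotation_max = 2,
                                          translation_max = 2)))
  expect_false(motion_exclude(time_series(base)))
})

test_that("detrending annihilates a linear ramp", {
  ramp <- time_series(outer(1:50, c(1, -2, 0.5)))
  out <- clean(ramp, band = NULL, detrend = TRUE)
  expect_lt(max(abs(out$data)), 1e-10)
})

test_that("nuisance regression projects out supplied regressors", {
  set.seed(1)
  nuis <- rnorm(60)
  ts <- time_series(cbind(3 * nuis, -1.5 * nuis + 2))
  out <- clean(ts, nuisance = nuis, band = NULL, detrend = FALSE)
  expect_lt(max(abs(out$data)), 1e-10)
})

test_that("band-pass keeps in-band sinusoids and attenuates out-of-band", {
  t <- seq_len(512) * 2 # tr = 2 s
  in_band <- sin(2 * pi * 0.05 * t)
  out_band <- sin(2 * pi * 0.2 * t)
  ts <- time_series(cbind(in_band, out_band), tr = 2)
  out <- clean(ts, band = c(0.01, 0.1), detrend = FALSE)
  # compare RMS amplitude over the central section (away from edge effects)
  mid <- 100:412
  gain <- function(k) sd(out$data[mid, k]) / sd(ts$data[mid, k])
  expect_gt(gain(1), 0.9)
  expect_lt(gain(2), 0.2)
  expect_equal(nrow(out$data), 512)
})

test_that("infeasible bands are rejected", {
  ts <- time_series(matrix(rnorm(60), 20, 3), tr = 2) # Nyquist 0.25 Hz
  expect_error(clean(ts, band = c(0.01, 0.3)), "Nyquist")
  expect_error(clean(ts, band = c(0.1, 0.05)), "Nyquist")
})

test_that("connectivity matches closed-form Fisher transforms", {
  # exact sample correlation 0.5 from orthogonal unit vectors
  set.seed(2)
  a <- scale(sin(seq_len(40)))[, 1]
  b <- residuals(lm(rnorm(40) ~ a))
  b <- b / sd(b) * sd(a)
  y <- 0.5 * a + sqrt(0.75) * b
  z <- connectivity(time_series(cbind(a, y)))
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-10)

  # proportional series: r = 1, clipped before the transform
  z1 <- connectivity(time_series(cbind(1:10, 2 * (1:10) + 3)))
  expect_equal(z1[1, 2], atanh(1 - 1e-7), tolerance = 1e-12)
  expect_equal(z1[1, 2], 8.4059, tolerance = 1e-3)
})

test_that("independent long series yield near-zero edge weights", {
  set.seed(8)
  z <- connectivity(time_series(matrix(rnorm(3000), 1000, 3)))
  expect_lt(max(abs(z[upper.tri(z)])), 0.15)
})

test_that("zero-variance nodes warn and zero their edges without dropping", {
  x <- cbind(rnorm(30), rep(1, 30), rnorm(30))
  expect_warning(z <- connectivity(time_series(x)), "zero-variance")
  expect_equal(z[2, c(1, 3)], c(0, 0))
  expect_false(z[1, 3] == 0)
})

test_that("connectivity is invariant to affine node rescaling and odd in r", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4)
  z0 <- connectivity(time_series(x))
  x2 <- x
  x2[, 2] <- 5 * x[, 2] - 7
  expect_equal(unclass(connectivity(time_series(x2))), unclass(z0),
               tolerance = 1e-12, ignore_attr = TRUE)
  x3 <- x
  x3[, 1] <- -x[, 1] # sign flip negates node-1 edges: z(-r) = -z(r)
  z3 <- connectivity(time_series(x3))
  expect_equal(z3[1, -1], -z0[1, -1], tolerance = 1e-12)
  expect_equal(z3[-1, -1], z0[-1, -1], tolerance = 1e-12)
})

test_that("scrub-then-connect equals connectivity on row-deleted data", {
  set.seed(5)
  x <- matrix(rnorm(120), 30, 4)
  fd <- runif(30, 0, 1)
  fd[1] <- 0
  ts <- time_series(x, fd = fd)
  direct <- connectivity(scrub(ts, 0.5))
  manual <- connectivity(time_series(x[fd <= 0.5, ]))
  expect_equal(unclass(direct), unclass(manual), ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  expect_error(connectivity(time_series(matrix(rnorm(4), 2, 2))),
               "3 time points")
  expect_error(connectivity(time_series(matrix(rnorm(10), 10, 1))),
               "2 nodes")
})

test_that("build_cohort runs the full path and honours exclusion", {
  cfg <- sim_config(n_subjects = 12, n_nodes = 5, n_timepoints = 120,
                    spike_fraction = 0.05, seed = 31)
  sim <- simulate_timeseries_cohort(cfg)
  coh <- build_cohort(sim$timeseries, sim$scores, band = c(0.01, 0.1))
  excluded <- vapply(sim$timeseries, motion_exclude, logical(1))
  expect_equal(coh$n_subjects, sum(!excluded))
  expect_equal(coh$n_nodes, 5)
})
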