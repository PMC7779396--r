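# Synthetic cohorts with planted score-correlated edges.
#
# The generator emulates the statistical structure the CPM analysis assumes:
# per-subject symmetric Fisher-z connectivity matrices, a continuous
# clinical score with a clinician-rating-scale-like distribution, and a
# small set of edges whose weights correlate with the score at a chosen
# effect size. It makes no attempt at spatial structure or hemodynamics.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# normalise a planted edge specification (list of pairs or 2-col matrix)
as_edge_pairs <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(0), ncol = 2L))
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.integer(x), ncol = 2L)
  cbind(pmin(x[, 1L], x[, 2L]), pmax(x[, 1L], x[, 2L]))
}

#' Simulation configuration for synthetic connectome cohorts
#'
#' Defaults reproduce the study conditions the analysis was designed for:
#' 122 subjects, a 268-node parcellation, 190 retained volumes at TR = 2 s,
#' and a symptom score with mean 40.1, SD 22.3, truncated to the
#' instrument's observed range 3-95. Null (non-planted) edge weights are
#' Normal(0.3, 0.15) on the Fisher-z scale, a plausible magnitude for
#' resting-state functional connectivity.
#'
#' @param n_subjects,n_nodes,n_timepoints cohort dimensions.
#' @param score_mean,score_sd,score_min,score_max target moments and support
#'   of the truncated-normal behavioural score.
#' @param planted_positive_edges,planted_negative_edges node pairs (list of
#'   length-2 vectors, or a 2-column matrix) whose weights correlate
#'   positively/negatively with the score. Must be disjoint.
#' @param effect_size Pearson correlation magnitude in `[0, 1)` between a
#'   planted edge weight and the score, in expectation.
#' @param noise_sd marginal SD of edge weights on the Fisher-z scale.
#' @param baseline_mean mean Fisher-z weight of every edge.
#' @param skew optional skew-normal shape parameter for the score
#'   distribution (0 = symmetric).
#' @param spike_fraction fraction of volumes given framewise displacement
#'   above the 0.5 mm scrubbing threshold in simulated time series.
#' @param label_frac fraction of subjects labelled as cases (highest
#'   scores), mirroring a severity-based diagnosis.
#' @param seed integer master seed; all randomness derives from it.
#' @return A list of class `cpm_sim_config`.
#' @export
sim_config <- function(n_subjects = 122, n_nodes = 268, n_timepoints = 190,
                       score_mean = 40.1, score_sd = 22.3,
                       score_min = 3, score_max = 95,
                       planted_positive_edges = NULL,
                       planted_negative_edges = NULL,
                       effect_size = 0, noise_sd = 0.15,
                       baseline_mean = 0.3, skew = 0,
                       spike_fraction = 0.05, label_frac = 64 / 122,
                       seed = 1L) {
  pos <- as_edge_pairs(planted_positive_edges)
  neg <- as_edge_pairs(planted_negative_edges)
  if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (effect_size < 0 || effect_size >= 1)
    stop("effect_size must be in [0, 1)", call. = FALSE)
  if (score_min >= score_max)
    stop("score_min must be below score_max", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (nrow(pos) && any(pos[, 2L] > n_nodes) ||
      nrow(neg) && any(neg[, 2L] > n_nodes))
    stop("planted edge index out of range", call. = FALSE)
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (length(intersect(key(pos), key(neg))))
    stop("planted positive and negative edge lists must be disjoint",
         call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         score_mean = score_mean, score_sd = score_sd,
         score_min = score_min, score_max = score_max,
         planted_positive_edges = pos, planted_negative_edges = neg,
         effect_size = effect_size, noise_sd = noise_sd,
         baseline_mean = baseline_mean, skew = skew,
         spike_fraction = spike_fraction, label_frac = label_frac,
         seed = as.integer(seed)),
    class = "cpm_sim_config"
  )
}

#' Draw behavioural scores from a truncated (skew-)normal distribution
#'
#' Samples by rejection from a normal (or skew-normal if `skew != 0`)
#' distribution truncated to `[lo, hi]`. For the symmetric case the parent
#' location is solved numerically so that the mean of the *truncated*
#' distribution equals `mean`; `sd` is the parent scale, so asymmetric
#' truncation shrinks the realised spread somewhat below `sd`.
#'
#' @param n number of scores.
#' @param mean,sd target mean and parent SD, in score units.
#' @param lo,hi truncation bounds (inclusive support).
#' @param skew skew-normal shape parameter; 0 gives a symmetric normal.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @examples
#' s <- simulate_behavior(1000, mean = 40.1, sd = 22.3, lo = 3, hi = 95,
#'                        seed = 1)
#' range(s)
#' @export
simulate_behavior <- function(n, mean, sd, lo, hi, skew = 0, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  if (mean <= lo || mean >= hi)
    stop("`mean` must lie strictly inside [lo, hi]", call. = FALSE)
  n <- as.integer(n)

  if (skew == 0) {
    # location mu of the parent normal whose [lo, hi]-truncated mean is
    # `mean`; the truncated mean is strictly increasing in mu
    trunc_mean <- function(mu) {
      a <- (lo - mu) / sd; b <- (hi - mu) / sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    }
    mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                         lower = lo - 6 * sd, upper = hi + 6 * sd,
                         tol = 1e-10)$root
    draw <- function(k) stats::rnorm(k, mu, sd)
  } else {
    # skew-normal via the delta representation, location/scale set so the
    # untruncated draw has the requested mean and sd
    delta <- skew / sqrt(1 + skew^2)
    omega <- sd / sqrt(1 - 2 * delta^2 / pi)
    xi <- mean - omega * delta * sqrt(2 / pi)
    draw <- function(k) {
      z1 <- abs(stats::rnorm(k)); z2 <- stats::rnorm(k)
      xi + omega * (delta * z1 + sqrt(1 - delta^2) * z2)
    }
  }

  with_seed(seed, {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n) {
      x <- draw(max(2L * n, 100L))
      out <- c(out, x[x >= lo & x <= hi])
      tries <- tries + 1L
      if (tries > 1000L)
        stop("rejection sampling failed: truncation bounds capture almost ",
             "no mass of the parent distribution", call. = FALSE)
    }
    out[seq_len(n)]
  })
}

# per-subject seeds derived once from the master seed, so each subject's
# draws are independent of the order in which subjects are generated
subject_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n + 2L))
}

#' Simulate a cohort of connectivity matrices with planted effects
#'
#' Every edge has Fisher-z weight `baseline_mean + noise_sd * e` where for
#' null edges `e` is standard normal noise, and for a planted edge
#' `e = rho * s + sqrt(1 - rho^2) * noise` with `s` the standardised score
#' and `rho = effect_size` (sign flipped for negative edges). The population
#' Pearson correlation between a planted edge and the score is therefore
#' `effect_size` in expectation, and the marginal edge-weight SD is
#' `noise_sd` for planted and null edges alike.
#'
#' Covariates (age, sex, mean framewise displacement) are drawn
#' independently of the score; binary labels flag the top `label_frac`
#' fraction of scores as cases.
#'
#' @param config a [sim_config()].
#' @return A [cohort] with covariates and labels.
#' @examples
#' cfg <- sim_config(n_subjects = 20, n_nodes = 10,
#'                   planted_positive_edges = list(c(1, 2)),
#'                   effect_size = 0.8, seed = 7)
#' simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cpm_sim_config"))
  n <- config$n_subjects
  N <- config$n_nodes
  seeds <- subject_seeds(config$seed, n)
  scores <- simulate_behavior(n, config$score_mean, config$score_sd,
                              config$score_min, config$score_max,
                              skew = config$skew, seed = seeds[n + 1L])
  s_std <- as.numeric(scale(scores))
  idx <- edge_index(N)
  p <- nrow(idx)
  pos <- edge_pos(config$planted_positive_edges, N)
  neg <- edge_pos(config$planted_negative_edges, N)
  eff <- config$effect_size
  mix <- sqrt(1 - eff^2)

  matrices <- vector("list", n)
  for (s in seq_len(n)) {
    e <- with_seed(seeds[s], stats::rnorm(p))
    if (length(pos)) e[pos] <- eff * s_std[s] + mix * e[pos]
    if (length(neg)) e[neg] <- -eff * s_std[s] + mix * e[neg]
    z <- config$baseline_mean + config$noise_sd * e
    m <- matrix(0, N, N)
    m[cbind(idx[, 1L], idx[, 2L])] <- z
    m <- m + t(m)
    matrices[[s]] <- m
  }

  cov_seed <- seeds[n + 2L]
  covariates <- with_seed(cov_seed, data.frame(
    age = round(pmin(pmax(stats::rnorm(n, 43.0, 10.3), 20), 67), 1),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(36, 86) / 122),
    mean_fd = round(abs(stats::rnorm(n, 0.08, 0.04)) + 0.01, 4)
  ))
  labels <- factor(ifelse(
    rank(scores, ties.method = "first") > n * (1 - config$label_frac),
    "case", "control"), levels = c("control", "case"))

  cohort(matrices, scores, covariates = covariates, labels = labels)
}

#' Simulate node time series whose coupling tracks the behavioural score
#'
#' Each planted node pair shares a latent signal with subject-specific
#' mixing weight `0.3 + sign * 0.2 * effect_size * s`, `s` the standardised
#' score, so the pair's population correlation increases (positive edges) or
#' decreases (negative edges) with symptom severity. All other nodes are
#' independent white noise. A synthetic framewise-displacement trace carries
#' `spike_fraction` of volumes above the 0.5 mm scrubbing threshold.
#'
#' A node may appear in at most one planted pair on this path.
#'
#' @param config a [sim_config()]; `n_timepoints` must be at least 20.
#' @return List with `timeseries` (list of [time_series] objects) and
#'   `scores`.
#' @export
simulate_timeseries_cohort <- function(config) {
  stopifnot(inherits(config, "cpm_sim_config"))
  if (config$n_timepoints < 20L)
    stop("n_timepoints must be >= 20", call. = FALSE)
  pairs <- rbind(config$planted_positive_edges,
                 config$planted_negative_edges)
  signs <- rep(c(1, -1), c(nrow(config$planted_positive_edges),
                           nrow(config$planted_negative_edges)))
  if (anyDuplicated(as.vector(pairs)))
    stop("a node may appear in at most one planted pair for the ",
         "time-series generator", call. = FALSE)
  n <- config$n_subjects
  N <- config$n_nodes
  TT <- config$n_timepoints
  seeds <- subject_seeds(config$seed, n)
  scores <- simulate_behavior(n, config$score_mean, config$score_sd,
                              config$score_min, config$score_max,
                              skew = config$skew, seed = seeds[n + 1L])
  s_std <- as.numeric(scale(scores))

  ts_list <- vector("list", n)
  for (s in seq_len(n)) {
    ts_list[[s]] <- with_seed(seeds[s], {
      x <- matrix(stats::rnorm(TT * N), TT, N)
      for (k in seq_len(nrow(pairs))) {
        w <- 0.3 + signs[k] * 0.2 * config$effect_size * s_std[s]
        w <- min(max(w, 0.02), 0.9)
        u <- stats::rnorm(TT)
        x[, pairs[k, 1L]] <- sqrt(w) * u + sqrt(1 - w) * x[, pairs[k, 1L]]
        x[, pairs[k, 2L]] <- sqrt(w) * u + sqrt(1 - w) * x[, pairs[k, 2L]]
      }
      fd <- stats::runif(TT, 0, 0.15)
      fd[1L] <- 0
      n_spike <- round(config$spike_fraction * TT)
      if (n_spike > 0) {
        at <- sample(2:TT, n_spike)
        fd[at] <- stats::runif(n_spike, 0.6, 1.5)
      }
      time_series(x, fd = fd, tr = 2,
                  subject_id = sprintf("sub%03d", s),
                  rotation_max = stats::runif(1, 0, 1.5),
                  translation_max = stats::runif(1, 0, 1.5))
    })
  }
  list(timeseries = ts_list, scores = scores)
}

#' Region counts of the 268-node parcellation's macroscale lobes
#'
#' Ten anatomically defined macroscale regions and their node counts in the
#' 268-node functional parcellation.
#' @return Named integer vector summing to 268.
#' @export
default_region_counts <- function() {
  c(prefrontal = 46L, cerebellum = 41L, temporal = 39L, limbic = 36L,
    parietal = 27L, occipital = 25L, motor = 21L, subcortical = 17L,
    brainstem = 9L, insula = 7L)
}

#' Canonical-network counts for the synthetic default atlas
#'
#' The eight canonical functional networks used to summarise predictive
#' edges. The network names are fixed by convention; the per-network node
#' counts are *synthetic* (the true node-to-network assignment is not a
#' plain-text table), chosen to sum to 268 with a dominant
#' subcortical-cerebellum network as in functional parcellations of this
#' family.
#' @return Named integer vector summing to 268.
#' @export
default_network_counts <- function() {
  c(medial_frontal = 29L, frontoparietal = 34L, default_mode = 20L,
    subcortical_cerebellum = 90L, motor = 27L, visual_I = 25L,
    visual_II = 22L, visual_association = 21L)
}

#' Build a node atlas by block assignment
#'
#' Assigns node indices `1..N` to macroscale region and canonical network
#' labels in contiguous blocks of the stated sizes, in the order the counts
#' are given. This is a synthetic stand-in for a real lookup table mapping
#' parcellation nodes to anatomy; any atlas read from a TSV with the same
#' columns can be used in its place.
#'
#' @param region_counts named integer vector: region label -> node count.
#' @param network_counts named integer vector: network label -> node count.
#'   Must sum to the same total as `region_counts`.
#' @return A `data.frame` of class `cpm_atlas` with columns `node_id`,
#'   `region`, `network`, `x`, `y`, `z` (coordinates `NA` for synthetic
#'   atlases).
#' @examples
#' atlas <- make_atlas(default_region_counts(), default_network_counts())
#' nrow(atlas) # 268
#' @export
make_atlas <- function(region_counts, network_counts) {
  region_counts <- round(unlist(region_counts))
  network_counts <- round(unlist(network_counts))
  if (is.null(names(region_counts)) || is.null(names(network_counts)))
    stop("count vectors must be named by label", call. = FALSE)
  if (any(region_counts < 0) || any(network_counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (sum(region_counts) != sum(network_counts))
    stop("region and network counts must sum to the same node total (",
         sum(region_counts), " vs ", sum(network_counts), ")",
         call. = FALSE)
  n <- sum(region_counts)
  atlas <- data.frame(
    node_id = seq_len(n),
    region = rep(names(region_counts), region_counts),
    network = rep(names(network_counts), network_counts),
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("cpm_atlas", "data.frame")
  atlas
}
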