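#!/usr/bin/env Rscript
# Exercise the time-series path on a reduced cohort: simulate node time
# courses with a planted score-coupled node pair and synthetic motion,
# scrub, clean (detrend + global-mean regression + 0.01-0.1 Hz band-pass),
# estimate Fisher-z connectivity, and check the planted edge survives the
# whole path.
#
# Finding (seed 19): motion exclusion removes the expected handful of
# high-FD subjects, scrubbing deletes ~5% of volumes, and the planted
# edge-score Spearman correlation is clearly positive after preprocessing.

source("analysis/00_config.R")

cfg <- sim_config(n_subjects = 60, n_nodes = 20, n_timepoints = 190,
                  planted_positive_edges = list(c(1, 2)),
                  effect_size = 0.8, spike_fraction = 0.05, seed = 19)
sim <- simulate_timeseries_cohort(cfg)

excluded <- vapply(sim$timeseries, motion_exclude, logical(1))
scrub_frac <- vapply(sim$timeseries, function(ts) mean(ts$fd > 0.5),
                     numeric(1))
cat("subjects:", length(sim$timeseries),
    "| excluded for motion:", sum(excluded),
    "| mean scrubbed fraction:", round(mean(scrub_frac), 3), "\n")

coh <- build_cohort(sim$timeseries, sim$scores, band = c(0.01, 0.1))
z12 <- vapply(coh$matrices, function(m) m[1, 2], numeric(1))
rho <- cor(z12, coh$scores, method = "spearman")
cat("planted edge (1,2) Spearman rho with score after preprocessing:",
    round(rho, 3), "\n")

tab <- data.frame(
  n_input = length(sim$timeseries),
  n_excluded = sum(excluded),
  n_retained = coh$n_subjects,
  mean_scrub_frac = round(mean(scrub_frac), 4),
  planted_edge_rho = round(rho, 4)
)
write.table(tab, file.path(RESULTS_DIR, "02_preprocessing.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
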