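# Shared configuration for the analysis scripts: the emulated study cohort.
#
# 122 subjects, a 268-node parcellation, and a severity score with mean
# 40.1, SD 22.3 on [3, 95]. A positive predictive network of 60 edges is
# planted among occipital, cerebellar, and limbic nodes (the block ranges of
# the default atlas), with per-edge effect size 0.35 — chosen once to give
# whole-cohort prediction performance of the order reported in severity-
# prediction studies (rho ~ 0.3) after dilution by fold-intersection noise.

library(cpmr)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_atlas <- function() {
  make_atlas(default_region_counts(), default_network_counts())
}

# node index blocks of the default atlas
atlas_block <- function(region) {
  at <- study_atlas()
  at$node_id[at$region == region]
}

study_planted_edges <- function() {
  occ <- atlas_block("occipital")
  cer <- atlas_block("cerebellum")
  lim <- atlas_block("limbic")
  set.seed(20260926)
  pairs <- rbind(
    cbind(sample(occ, 30, replace = TRUE), sample(cer, 30, replace = TRUE)),
    cbind(sample(lim, 15, replace = TRUE), sample(cer, 15, replace = TRUE)),
    cbind(sample(lim, 15, replace = TRUE), sample(occ, 15, replace = TRUE)))
  unique(t(apply(pairs, 1, sort)))
}

study_config <- function(seed = 7) {
  sim_config(n_subjects = 122, n_nodes = 268,
             planted_positive_edges = study_planted_edges(),
             effect_size = 0.35, seed = seed)
}

study_cohort <- function(seed = 7) simulate_cohort(study_config(seed))
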