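# Shared simulation helpers for caller-level tests.

# The standard study conditions: 2 Mb genome, centered viewpoint,
# ~2,200 valid fragments, NB dispersion 5, 2 replicates.
study_config <- function(seed, planted = list()) {
  sim_config(seed = seed, planted_interactions = planted)
}

three_planted <- function(fold = 8) {
  list(list(center = 6e5, half_width = 10, fold = fold),
       list(center = 1.15e6, half_width = 10, fold = fold),
       list(center = 1.6e6, half_width = 10, fold = fold))
}

# run simulator + caller end to end; returns calls, pCREs, truth, fmap
run_sim_call <- function(seed, planted = list(), config = caller_config()) {
  cfg <- study_config(seed, planted)
  g <- simulate_genome(cfg)
  fmap <- digest(g)
  fmap <- filter_fragments(fmap, cfg$viewpoint_pos)
  sim <- simulate_4c_counts(fmap, cfg)
  profs <- suppressMessages(lapply(seq_along(sim$counts), function(r) {
    prepare_profile(sim$counts[[r]], fmap, replicate = paste0("rep", r))
  }))
  cl <- call_fragments(profs, config = config)
  list(calls = cl, pcres = merge_to_pcres(cl, cell_line = "sim"),
       truth = sim$truth, fmap = fmap, profiles = profs, sim = sim,
       sim_cfg = cfg)
}

# small genome + profile fixture for fast unit tests
small_fixture <- function(seed = 7, genome_length = 4e5, planted = list()) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    viewpoint_pos = genome_length / 2,
                    planted_interactions = planted)
  g <- simulate_genome(cfg)
  fmap <- digest(g)
  fmap <- filter_fragments(fmap, cfg$viewpoint_pos)
  sim <- simulate_4c_counts(fmap, cfg)
  list(cfg = cfg, genome = g, fmap = fmap, sim = sim)
}
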