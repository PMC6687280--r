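# Shared fixtures: small simulated bundles built in code at test time.

small_config <- function(seed = 42, ...) {
  sim_config(n_sites = 6, n_campaigns = 8, n_families = 15,
             dominant_shares = c(0.333, 0.263, 0.186, 0.046),
             seed = seed, ...)
}

small_bundle <- function(seed = 42, ...) {
  cfg <- small_config(seed = seed, ...)
  stressors <- generate_stressors(cfg)
  traits <- make_trait_table(cfg$n_families, cfg$frac_at_risk, seed = seed)
  abundance <- generate_community(stressors, traits, cfg)
  list(config = cfg, stressors = stressors, traits = traits,
       abundance = abundance)
}

lc50_fixture <- function() {
  read.csv(system.file("extdata", "lc50_daphnia_synthetic.csv",
                       package = "streamstress"))
}

# study-shaped dataset (13 sites x 20 campaigns, 57 families), cached per run
study_bundle <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) {
      cfg <- sim_config(seed = seed)
      stressors <- generate_stressors(cfg)
      traits <- make_trait_table(cfg$n_families, cfg$frac_at_risk, seed = seed)
      abundance <- generate_community(stressors, traits, cfg)
      indices <- suppressWarnings(community_indices(abundance, traits))
      merged <- merge(indices, stressors, by = c("site", "campaign"))
      merged$log_abundance <- log(merged$abundance + 1)
      cache <<- list(config = cfg, stressors = stressors, traits = traits,
                     abundance = abundance, indices = indices,
                     merged = merged)
    }
    cache
  }
})
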