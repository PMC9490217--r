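# Compact study configuration used across tests: 4 goats + 4 pigs, two of
# each cohoused, 80 polymorphic positions per strain.
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_strains = 12, n_goats = 4, n_pigs = 4,
    n_cohoused_goats = 2, n_cohoused_pigs = 2,
    timepoints = "t1", n_positions_per_strain = 80,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Run the scoring stages of the pipeline on a generated study.
score_study <- function(study, ...) {
  called <- call_alleles_table(study$pileup)
  screened <- presence_filter(study$coverage)
  score_transmission(called$calls, called$covered, screened, study$metadata, ...)
}

# Independent brute-force oracle for the pair likelihoods: per-allele
# term-by-term accumulation with explicit branching, no shared code with
# overlap_likelihood().
brute_force_overlap <- function(classes, f) {
  L_obs <- 0
  L_min <- 0
  for (i in seq_along(classes)) {
    p11 <- f[i] * f[i]
    p00 <- (1 - f[i]) * (1 - f[i])
    p10 <- f[i] * (1 - f[i])
    p01 <- (1 - f[i]) * f[i]
    if (classes[i] == "11") {
      L_obs <- L_obs + log(p11)
    } else if (classes[i] == "00") {
      L_obs <- L_obs + log(p00)
    } else if (classes[i] == "10") {
      L_obs <- L_obs - log(p10)
    } else {
      L_obs <- L_obs - log(p01)
    }
    L_min <- L_min + min(log(p11), log(p00))
  }
  list(L_obs = L_obs, L_min = L_min, P_raw = L_obs / L_min)
}

# One-row metadata stubs for event classification.
meta_row <- function(host_id, host_species, gut_site) {
  list(host_id = host_id, host_species = host_species, gut_site = gut_site)
}
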