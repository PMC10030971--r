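# Shared fixtures.  Heavy study runs are cached across test files (the suite
# runs in one process), so the acceptance checks, the stability property and
# the experiment bookkeeping all reuse the same two n = 30 studies.

.study_cache <- new.env(parent = emptyenv())

cached_experiment <- function(tradeoff, n_combos = 30, seed = 42) {
  key <- paste(tradeoff, n_combos, seed, sep = "_")
  if (is.null(.study_cache[[key]])) {
    cfg <- experiment_config(
      sampler = sampler_config(tradeoff = tradeoff, seed = seed),
      compute_stability = (tradeoff == "none")
    )
    .study_cache[[key]] <- suppressWarnings(reduced_run(cfg, n_combos))
  }
  .study_cache[[key]]
}

# one consumer, one resource: closed-form chemostat algebra applies
single_consumer_spec <- function(mu = 1.5, ks = 0.5, m = 0.2, S = 1) {
  model_spec(trait_set(matrix(mu), matrix(ks)),
             mortality_rate = m, supply_concentration = S)
}

# two specialists on two resources; coexists under continuous supply
two_species_spec <- function(m = 0.2) {
  model_spec(
    trait_set(mu_max = matrix(c(1.2, 0.3, 0.3, 1.2), 2, 2),
              k_s = matrix(0.1, 2, 2)),
    mortality_rate = m, supply_concentration = 1
  )
}

# minimal stand-in for a simulation result, for metric-level tests
fake_sim <- function(abundances, interval_h = NA, converged = TRUE,
                     init_density = 0.01) {
  regime <- if (is.na(interval_h)) supply_regime("continuous") else
    supply_regime("pulsed", interval_h = interval_h)
  structure(
    list(final_composition = abundances,
         final_resources = c(res1 = 0.1),
         converged = converged, failed = FALSE, regime = regime,
         init_density = init_density, trajectory = NULL),
    class = "crm_sim"
  )
}

# wrap the pure R right-hand sides for deSolve (reference implementation)
r_rhs_continuous <- function(t, y, spec) {
  nc <- spec$traits$n_consumers
  st <- system_state(pmax(y[seq_len(nc)], 0), pmax(y[-seq_len(nc)], 0))
  d <- rhs_continuous(st, spec)
  list(c(d$consumers, d$resources))
}

r_rhs_batch <- function(t, y, parms) {
  nc <- parms$spec$traits$n_consumers
  st <- system_state(pmax(y[seq_len(nc)], 0), pmax(y[-seq_len(nc)], 0))
  d <- rhs_batch(st, parms$spec, mortality = parms$mortality)
  list(c(d$consumers, d$resources))
}
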