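test_that("pulse events implement flux-matched input and transfer survival", {
  spec <- single_consumer_spec(m = 0.1, S = 1)
  spec$dilution_rate <- 0.1
  st <- system_state(1, 0.5)

  reg24 <- supply_regime("pulsed", interval_h = 24)
  out <- apply_pulse(st, spec, reg24)
  expect_equal(out$consumers, exp(-2.4), tolerance = 1e-12)  # survival
  expect_equal(out$resources, exp(-2.4) * 0.5 + 0.1 * 1 * 24)

  reg2 <- supply_regime("pulsed", interval_h = 2, pulse_dialect = "additive")
  out2 <- apply_pulse(st, spec, reg2)
  expect_equal(out2$resources - st$resources, 0.2)  # D S T
  expect_equal(out2$consumers, exp(-0.2) * 1)

  cm <- supply_regime("pulsed", interval_h = 2, mortality_mode = "continuous")
  out3 <- apply_pulse(st, spec, cm)
  expect_equal(out3$consumers, st$consumers)  # no cell dilution
  expect_equal(out3$resources, st$resources + 0.2)

  expect_error(apply_pulse(st, spec, supply_regime("continuous")), "pulsed")
  expect_error(supply_regime("pulsed", interval_h = -1), "positive")
})

test_that("compiled and reference right-hand sides integrate to the same trajectory", {
  spec <- two_species_spec()
  y0 <- c(sp1 = 0.01, sp2 = 0.02, res1 = 1, res2 = 1)
  times <- seq(0, 50, by = 0.5)

  compiled <- deSolve::lsoda(
    y0, times, func = "crm_derivs",
    parms = pulseCR:::pack_parms(spec, supply_on = 1, mortality_on = 1),
    dllname = "pulseCR", initfunc = "crm_init", rtol = 1e-10, atol = 1e-12
  )
  reference <- deSolve::lsoda(y0, times, func = r_rhs_continuous, parms = spec,
                              rtol = 1e-10, atol = 1e-12)
  expect_equal(unclass(compiled)[, -1], unclass(reference)[, -1],
               tolerance = 1e-7)
})

test_that("an empty community relaxes resources to the supply point", {
  spec <- single_consumer_spec(m = 0.2, S = 1)
  sim <- simulate_community(spec, supply_regime("continuous"),
                            init = system_state(0, 0.2), horizon_h = 400)
  expect_equal(as.numeric(sim$final_resources), 1, tolerance = 1e-6)
  comp <- community_composition(sim, threshold = 1e-6)
  expect_equal(richness(comp), 0)
})

test_that("within-cycle fluctuation amplitude grows with the pulsing interval", {
  spec <- single_consumer_spec()
  ratios <- vapply(c(0.5, 1, 2, 4, 12, 24), function(T) {
    sim <- simulate_community(
      spec, supply_regime("pulsed", interval_h = T), horizon_h = 2000,
      controls = solver_controls(keep_trajectory = TRUE, thin = 1L)
    )
    tr <- sim$trajectory
    last_cycle <- tr[tr$time > max(tr$time) - T, ]
    max(last_cycle$sp1) / min(last_cycle$sp1)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # intermittent mortality: the within-cycle collapse tracks the transfer
  # dilution e^(mT) (finite output spacing clips the exact extrema)
  expect_gte(ratios[6], exp(0.2 * 24) * 0.8)
})

test_that("steady-state detection accepts constants and pulse-period limit cycles, rejects drift", {
  tt <- seq(0, 400, by = 0.5)
  flat <- data.frame(time = tt, a = rep(1, length(tt)))
  expect_true(detect_steady_state(flat, window_h = 96))

  decay <- data.frame(time = tt, a = exp(-0.01 * tt))
  expect_false(detect_steady_state(decay, window_h = 96))
  expect_error(detect_steady_state(flat, window_h = 300), "two windows")

  spec <- single_consumer_spec()
  sim <- simulate_community(spec, supply_regime("pulsed", interval_h = 4),
                            horizon_h = 3000,
                            controls = solver_controls(keep_trajectory = TRUE,
                                                       thin = 1L))
  expect_true(sim$converged)
  tr <- as.data.frame(sim$trajectory[, c("time", "sp1")])
  tail_tr <- tr[tr$time >= max(tr$time) - (2 * 48 + 1), ]
  expect_true(detect_steady_state(tail_tr, window_h = 48))
})

test_that("simulations are deterministic and report convergence metadata", {
  spec <- two_species_spec()
  a <- simulate_community(spec, supply_regime("pulsed", interval_h = 2),
                          horizon_h = 2000)
  b <- simulate_community(spec, supply_regime("pulsed", interval_h = 2),
                          horizon_h = 2000)
  expect_identical(a$final_composition, b$final_composition)
  expect_true(a$converged)
  expect_false(a$failed)
  expect_s3_class(a, "crm_sim")
  expect_error(
    simulate_community(spec, supply_regime("continuous"),
                       init = system_state(0.01, 1)),
    "dimensions"
  )
})
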