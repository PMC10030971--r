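test_that("Monod response matches closed-form values and bounds", {
  expect_equal(monod_rate(1, 1, 1), 0.5)            # half saturation
  expect_equal(monod_rate(2, 0.5, 0), 0)            # no resource, no growth
  expect_equal(monod_rate(1.98, 0.1, 10), 1.98 * 10 / 10.1)
  expect_error(monod_rate(1, 1, -0.1), "negative resource")
  expect_error(monod_rate(-1, 1, 0.5), "positive")

  r <- exp(seq(log(1e-4), log(1e4), length.out = 50))
  v <- monod_rate(1.7, 0.3, r)
  expect_true(all(v >= 0 & v < 1.7))
  expect_true(all(diff(v) > 0)) # monotone in resource concentration
})

test_that("growth rate sums over substitutable resources and takes the Liebig minimum", {
  tr <- trait_set(mu_max = matrix(c(0.6, 0.8), 1, 2),
                  k_s = matrix(1, 1, 2))
  # resources chosen so the two Monod terms are 0.3 and 0.4
  expect_equal(growth_rate(tr, c(1, 1), "substitutable"),
               c(sp1 = 0.7), tolerance = 1e-12)
  expect_equal(growth_rate(tr, c(1, 1), "essential"),
               c(sp1 = 0.3), tolerance = 1e-12)

  tr1 <- trait_set(matrix(1.4), matrix(0.2))
  expect_equal(growth_rate(tr1, 0.7, "substitutable"),
               growth_rate(tr1, 0.7, "essential")) # rules coincide for k = 1
  expect_error(growth_rate(tr, c(1, 1), "liebig"))
})

test_that("growth rate is non-decreasing in every resource under both rules", {
  set.seed(301)
  for (i in 1:20) {
    tr <- trait_set(matrix(runif(6, 0.1, 2), 2, 3),
                    matrix(exp(runif(6, log(0.05), log(5))), 2, 3))
    r <- runif(3, 0, 2)
    j <- sample(3, 1)
    r2 <- r
    r2[j] <- r[j] + runif(1, 0.01, 1)
    for (rule in c("substitutable", "essential")) {
      expect_true(all(growth_rate(tr, r2, rule) >= growth_rate(tr, r, rule)))
    }
  }
})

test_that("chemostat RHS vanishes at the closed-form equilibrium", {
  spec <- single_consumer_spec(mu = 1.5, ks = 0.5, m = 0.2, S = 1)
  eq <- chemostat_equilibrium(spec)
  expect_equal(eq$resources, 0.5 * 0.2 / (1.5 - 0.2))
  d <- rhs_continuous(system_state(eq$consumers, eq$resources), spec)
  expect_equal(d$consumers, 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d$resources, 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("chemostat RHS handles empty communities and is symmetric in identical consumers", {
  spec <- single_consumer_spec(m = 0.2, S = 1)
  d0 <- rhs_continuous(system_state(0, 0.3), spec)
  expect_equal(d0$consumers, 0, ignore_attr = TRUE)
  expect_equal(d0$resources, 0.2 * (1 - 0.3), ignore_attr = TRUE)

  twin <- model_spec(trait_set(matrix(1.2, 2, 1), matrix(0.4, 2, 1)),
                     mortality_rate = 0.2)
  d <- rhs_continuous(system_state(c(0.5, 0.5), 0.6), twin)
  expect_equal(d$consumers[1], d$consumers[2], ignore_attr = TRUE)
})

test_that("batch-phase RHS conserves quota-weighted mass and respects mortality mode", {
  spec <- single_consumer_spec()
  st <- system_state(0.4, 0.7)
  d <- rhs_batch(st, spec)
  expect_equal(spec$traits$quota[1, 1] * d$consumers + d$resources, 0,
               tolerance = 1e-14, ignore_attr = TRUE)

  starved <- system_state(0.4, 0)
  expect_equal(rhs_batch(starved, spec)$consumers, 0, ignore_attr = TRUE)
  expect_equal(rhs_batch(starved, spec, mortality = "continuous")$consumers,
               -0.2 * 0.4, ignore_attr = TRUE)
})

test_that("trait sets validate inputs and round-trip through CSV", {
  expect_error(trait_set(matrix(1), matrix(-1)), "positive")
  expect_error(trait_set(matrix(1), matrix(c(1, 1), 2, 1)), "dimensions")
  expect_error(trait_set(matrix(c(1, NA), 1, 2), matrix(1, 1, 2)), "positive")

  tr <- trait_set(matrix(c(1, 2, 3, 4), 2, 2),
                  matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2), quota = 2)
  expect_equal(affinity(tr), tr$mu_max / tr$k_s)
  expect_equal(min_doubling_time(tr, "sum"), 60 * log(2) / rowSums(tr$mu_max),
               ignore_attr = TRUE)
  expect_equal(min_doubling_time(tr, "min"),
               60 * log(2) / apply(tr$mu_max, 1, min), ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".csv")
  write_traits(tr, path)
  back <- read_traits(path)
  expect_equal(back$mu_max, tr$mu_max)
  expect_equal(back$k_s, tr$k_s)
  expect_equal(back$quota, tr$quota)
})

test_that("model specifications validate and round-trip through JSON", {
  tr <- trait_set(matrix(c(1.1, 0.9), 2, 1), matrix(c(0.2, 0.05), 2, 1))
  expect_error(model_spec(tr, mortality_rate = 0), "positive")
  expect_error(model_spec(tr, supply_concentration = -1), "positive")

  spec <- model_spec(tr, resource_rule = "essential", mortality_rate = 0.15,
                     supply_concentration = 2, dilution_rate = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$traits$mu_max, spec$traits$mu_max)
  expect_equal(back$resource_rule, "essential")
  expect_equal(back$dilution_rate, 0.3)
  expect_equal(back$supply_concentration, spec$supply_concentration)
})

test_that("R* orders competitors and flags non-persisters", {
  expect_equal(rstar(1.5, 0.5, 0.2), 0.5 * 0.2 / 1.3)
  expect_equal(rstar(0.1, 0.5, 0.2), Inf)
  # higher affinity at equal mu_max means lower R*
  expect_lt(rstar(1.5, 0.1, 0.2), rstar(1.5, 0.5, 0.2))
})
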