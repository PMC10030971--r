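test_that("every draw respects the 21-52 min doubling-time constraint", {
  for (trd in c("none", "strict", "weak")) {
    cfg <- sampler_config(tradeoff = trd, seed = 101)
    dt <- vapply(seq_len(3000), function(i) {
      min_doubling_time(sample_traits(cfg, seed = i), "sum")
    }, numeric(cfg$n_consumers))
    expect_true(all(dt >= 21 & dt <= 52),
                label = paste("doubling times in range,", trd))
  }
  # essential-resource convention: the limiting rate sets the doubling time
  cfg_min <- sampler_config(rate_convention = "min", seed = 101)
  dt <- vapply(seq_len(500), function(i) {
    min_doubling_time(sample_traits(cfg_min, seed = i), "min")
  }, numeric(5))
  expect_true(all(dt >= 21 & dt <= 52))
})

test_that("sampling is a pure function of the seed", {
  cfg <- sampler_config(seed = 7)
  a <- sample_traits(cfg)
  b <- sample_traits(cfg)
  expect_identical(a, b)
  expect_false(identical(a, sample_traits(cfg, seed = 8)))

  # drawing must not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(sample_traits(cfg))
  expect_identical(runif(1), before)
})

test_that("the strict trade-off enforces a perfect negative mu_max-affinity ranking", {
  cfg <- sampler_config(tradeoff = "strict", seed = 5)
  study <- sample_study(cfg, n_combos = 50)
  cell_rho <- vapply(study$traits, function(tr) {
    cor(as.vector(tr$mu_max), as.vector(affinity(tr)), method = "spearman")
  }, numeric(1))
  expect_true(all(cell_rho == -1))

  # resource-averaged (consumer-level) traits: the ranking is still strongly
  # negative, though Dirichlet splits keep it from being exactly -1 with
  # only five consumers per combo
  consumer_rho <- vapply(study$traits, function(tr) {
    cor(rowMeans(tr$mu_max), rowMeans(affinity(tr)), method = "spearman")
  }, numeric(1))
  expect_lte(mean(consumer_rho), -0.5)
  expect_lte(median(consumer_rho), -0.7)
})

test_that("weak and absent trade-offs bracket the strict one", {
  weak <- sample_study(sampler_config(tradeoff = "weak", seed = 5), 100)
  rho_w <- mean(vapply(weak$traits, function(tr) {
    cor(as.vector(tr$mu_max), as.vector(affinity(tr)), method = "spearman")
  }, numeric(1)))
  expect_lt(rho_w, 0)
  expect_gt(rho_w, -1)

  # without a trade-off, mu_max and K_s are sampled independently, so their
  # correlation is centred at zero (mu_max vs affinity = mu/K_s is weakly
  # positive by construction and is not the free quantity here)
  none <- sample_study(sampler_config(tradeoff = "none", n_combos = 200,
                                      seed = 5))
  rho_n <- mean(vapply(none$traits, function(tr) {
    cor(rowMeans(tr$mu_max), rowMeans(tr$k_s), method = "spearman")
  }, numeric(1)))
  expect_lt(abs(rho_n), 0.15)
})

test_that("trade-off Monod curves of a gleaner and an opportunist cross", {
  # theta = 1, c = 1: mu_max 2 -> affinity 0.5, K_s 4; mu_max 1 -> K_s 1
  tr <- trait_set(matrix(c(2, 1), 2, 1), matrix(c(4, 1), 2, 1))
  expect_equal(affinity(tr)[, 1], c(sp1 = 0.5, sp2 = 1))
  r <- seq(0.01, 20, by = 0.01)
  gap <- monod_rate(2, 4, r) - monod_rate(1, 1, r)
  expect_true(min(gap) < 0 && max(gap) > 0) # a crossing exists
  # analytic crossing at R = 2
  expect_equal(monod_rate(2, 4, 2), monod_rate(1, 1, 2))

  cfg <- sampler_config(tradeoff = "strict", tradeoff_exponent = 1,
                        tradeoff_scale = 1, seed = 3)
  tr2 <- sample_traits(cfg)
  expect_equal(tr2$k_s, tr2$mu_max^2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("studies are reproducible, prefix-stable and validate sizes", {
  cfg <- sampler_config(n_combos = 10, seed = 21)
  s1 <- sample_study(cfg)
  s2 <- sample_study(cfg)
  expect_identical(s1$seeds, s2$seeds)
  expect_identical(s1$traits, s2$traits)

  s5 <- sample_study(cfg, n_combos = 5)
  expect_identical(s5$traits, s1$traits[1:5])

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traits(s1$traits[[1]], p1)
  write_traits(s2$traits[[1]], p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  expect_error(sample_study(cfg, n_combos = 0), "at least 1")
  expect_error(sample_study(cfg, n_combos = 11), "exceeds")
  expect_error(sampler_config(tradeoff_exponent = -1), ">= 0")
  expect_error(sampler_config(doubling_min_min = 52, doubling_min_max = 21),
               "ordered")
  expect_error(sampler_config(k_s_log_range = c(2, 1)), "increasing")
})
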