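test_that("Jaccard similarity counts persistence sets", {
  cc <- function(...) community_composition(c(...), threshold = 0.5)
  a <- cc(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 0, sp5 = 0)
  b <- cc(sp1 = 0, sp2 = 1, sp3 = 1, sp4 = 1, sp5 = 0)
  expect_equal(jaccard(a, b), 0.5)        # {1,2,3} vs {2,3,4}
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(cc(sp1 = 1, sp2 = 0), cc(sp1 = 0, sp2 = 1)), 0)
  expect_equal(jaccard(cc(sp1 = 0, sp2 = 0), cc(sp1 = 0, sp2 = 0)), 1)
  expect_equal(jaccard(a, b), jaccard(b, a))

  mis <- community_composition(c(x = 1, y = 1), threshold = 0.5)
  expect_error(jaccard(a, mis), "universe")
})

test_that("extinction thresholds define persistence and richness", {
  sim <- fake_sim(c(sp1 = 0.5, sp2 = 2e-6, sp3 = 5e-7))
  comp <- community_composition(sim) # default: 1e-4 x init density 0.01
  expect_identical(unname(comp$persistent), c(TRUE, TRUE, FALSE))
  expect_equal(richness(comp), 2)

  # richness is invariant to rescaling abundances above the threshold
  scaled <- community_composition(fake_sim(c(sp1 = 50, sp2 = 2e-4, sp3 = 5e-7) / 100))
  expect_equal(richness(scaled), 2)
  expect_error(community_composition(c(1, 2)), "named")
})

test_that("weighted trait means follow abundance weights", {
  tr <- trait_set(mu_max = matrix(c(1, 2, 1, 2), 2, 2),
                  k_s = matrix(c(0.5, 4, 0.5, 4), 2, 2))
  # per-consumer resource-averaged traits: mu (1, 2); affinity (2, 0.5)
  single <- community_composition(c(sp1 = 1, sp2 = 0), threshold = 0.1)
  expect_equal(weighted_trait_means(single, tr),
               c(affinity = 2, mu_max = 1))

  equal <- community_composition(c(sp1 = 1, sp2 = 1), threshold = 0.1)
  expect_equal(weighted_trait_means(equal, tr)[["mu_max"]], 1.5)

  skewed <- community_composition(c(sp1 = 0.9, sp2 = 0.1), threshold = 0.01)
  expect_equal(weighted_trait_means(skewed, tr)[["mu_max"]], 1.1)
  expect_equal(weighted_trait_means(skewed, tr)[["affinity"]],
               0.9 * 2 + 0.1 * 0.5)

  empty <- community_composition(c(sp1 = 0, sp2 = 0), threshold = 0.1)
  expect_true(all(is.na(weighted_trait_means(empty, tr))))
})

test_that("study summaries score pulsed runs against their continuous baseline", {
  cfg <- sampler_config(n_combos = 2, seed = 31)
  study <- sample_study(cfg)
  ab <- c(sp1 = 1, sp2 = 0.5, sp3 = 0, sp4 = 0, sp5 = 0)
  shifted <- c(sp1 = 0, sp2 = 0.5, sp3 = 1, sp4 = 0, sp5 = 0)
  results <- list(
    list(continuous = fake_sim(ab),
         pulsed = list(`2` = fake_sim(ab, 2), `24` = fake_sim(shifted, 24))),
    list(continuous = fake_sim(ab),
         pulsed = list(`2` = fake_sim(ab, 2),
                       `24` = fake_sim(ab, 24, converged = FALSE)))
  )
  tab <- summarise_study(results, study)
  expect_equal(nrow(tab$combo_summary), 6)
  expect_equal(nrow(tab$runs), 6 * 5)

  s2 <- tab$interval_summary[tab$interval_summary$regime == "2", ]
  expect_equal(s2$mean_jaccard, 1)
  expect_equal(s2$n_used, 2)

  s24 <- tab$interval_summary[tab$interval_summary$regime == "24", ]
  # combo 1: {1,2} vs {2,3} -> 1/3; combo 2 excluded as non-converged
  expect_equal(s24$mean_jaccard, 1 / 3)
  expect_equal(s24$n_used, 1)
  expect_equal(s24$n_excluded, 1)

  # mean over one combo at J = 1 and one at J = 0 is 0.5
  disjoint <- c(sp1 = 0, sp2 = 0, sp3 = 0, sp4 = 1, sp5 = 1)
  res2 <- list(
    list(continuous = fake_sim(ab), pulsed = list(`2` = fake_sim(ab, 2))),
    list(continuous = fake_sim(ab), pulsed = list(`2` = fake_sim(disjoint, 2)))
  )
  tab2 <- summarise_study(res2, study)
  expect_equal(tab2$interval_summary$mean_jaccard[
    tab2$interval_summary$regime == "2"], 0.5)

  expect_error(summarise_study(list(list(pulsed = list())), study),
               "continuous")
})
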