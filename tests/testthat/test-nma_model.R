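test_that("a single large trial reproduces its frequentist log odds ratio", {
  arms <- rbind(bin_arm("BIG", "placebo", 1000, 200),
                bin_arm("BIG", "topiramate", 1000, 300))
  cfg <- quick_cfg(seed = 21, iterations = 8000, burnin = 3000,
                   tau_prior_upper = 0.01)
  post <- suppressWarnings(fit_nma(arms, 9, cfg))
  freq <- study_effect_binary(arms[1, ], arms[2, ])
  expect_equal(median(relative_effect(post, "placebo", "topiramate")$draws),
               freq$effect, tolerance = 0.05)
})

test_that("the sampler recovers known network effects", {
  sim <- simulate_network(triangle_scenario(seed = 11))
  post <- suppressWarnings(fit_nma(sim$arms, 9,
                                   quick_cfg(seed = 5, iterations = 8000,
                                             burnin = 3000)))
  med <- vapply(c(topiramate = "topiramate", propranolol = "propranolol"),
                function(t) median(relative_effect(post, "placebo", t)$draws),
                1.0)
  expect_equal(unname(med), c(-0.5, -1.0), tolerance = 0.15)
  # indirect-by-additivity contrast between the two active arms
  re23 <- relative_effect(post, "topiramate", "propranolol")
  expect_equal(median(re23$draws), -0.5, tolerance = 0.15)
  expect_error(fit_nma(sim$arms[0, ], 9, quick_cfg()), "empty")
})

test_that("contrasts are consistent by construction for every draw", {
  sim <- simulate_network(triangle_scenario(seed = 3, trials = 3))
  post <- suppressWarnings(fit_nma(sim$arms, 9, quick_cfg(seed = 2,
                                                          iterations = 3000,
                                                          burnin = 1000)))
  ab <- relative_effect(post, "placebo", "topiramate")$draws
  bc <- relative_effect(post, "topiramate", "propranolol")$draws
  ac <- relative_effect(post, "placebo", "propranolol")$draws
  expect_equal(max(abs(ab + bc - ac)), 0, tolerance = 1e-12)
  # antisymmetry draw-wise
  ba <- relative_effect(post, "topiramate", "placebo")$draws
  expect_identical(ba, -ab)
  # self-contrast is the exact null
  self <- relative_effect(post, "placebo", "placebo")
  expect_identical(self$median, 1)  # OR scale
})

test_that("runs are bit-identical under a fixed seed", {
  sim <- simulate_network(triangle_scenario(seed = 13, trials = 3))
  cfg <- quick_cfg(seed = 77, iterations = 2000, burnin = 500)
  p1 <- suppressWarnings(fit_nma(sim$arms, 9, cfg))
  p2 <- suppressWarnings(fit_nma(sim$arms, 9, cfg))
  expect_identical(p1$d, p2$d)
  expect_identical(p1$tau, p2$tau)
})

test_that("convergence diagnostics flag a crippled sampler and pass a healthy one", {
  sim <- simulate_network(triangle_scenario(seed = 19, trials = 5))
  good <- suppressWarnings(fit_nma(sim$arms, 9,
                                   quick_cfg(seed = 4, chains = 4,
                                             iterations = 8000, burnin = 3000)))
  expect_true(all(good$convergence$rhat < 1.05))
  expect_true(all(good$convergence$rhat >= 1))
  expect_true(all(good$convergence$ess > 0))

  # gigantic frozen proposals: chains stay near their starting points
  bad_cfg <- quick_cfg(seed = 4, iterations = 2000, burnin = 500,
                       adapt = FALSE, init_proposal_scale = 1e6)
  expect_warning(bad <- fit_nma(sim$arms, 9, bad_cfg), "did not converge")
  expect_false(bad$converged)
  expect_gt(max(bad$convergence$rhat), 1.05)
})

test_that("league tables obey the reciprocal and diagonal identities", {
  sim <- simulate_network(triangle_scenario(seed = 23, trials = 5))
  post <- suppressWarnings(fit_nma(sim$arms, 9, quick_cfg(seed = 6,
                                                          iterations = 4000,
                                                          burnin = 1500)))
  lt <- league_table(post)
  K <- length(lt$treatments)
  expect_equal(dim(lt$median), c(K, K))
  expect_equal(nrow(lt$long), K * (K - 1))
  expect_true(all(diag(lt$median) == 1))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    expect_equal(lt$median[i, j] * lt$median[j, i], 1, tolerance = 1e-12)
  }
})

test_that("few spurious significant contrasts arise under the null", {
  set.seed(13)
  flagged <- 0L; total <- 0L
  for (r in 1:20) {
    sc <- triangle_scenario(seed = 130 + r, tau = 0, n_per_arm = 200,
                            trials = 4,
                            true_d = c(placebo = 0, topiramate = 0,
                                       propranolol = 0))
    sim <- simulate_network(sc)
    post <- suppressWarnings(fit_nma(sim$arms, 9,
                                     quick_cfg(seed = 1300 + r,
                                               iterations = 3000,
                                               burnin = 1000)))
    lt <- league_table(post)
    up <- upper.tri(lt$significant)
    flagged <- flagged + sum(lt$significant[up])
    total <- total + sum(up)
  }
  expect_lte(flagged / total, 0.10)
})

test_that("configuration invariants are enforced", {
  expect_error(nma_config(chains = 1))
  expect_error(nma_config(iterations = 100, burnin = 200))
  expect_error(nma_config(thin = 0))
})
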