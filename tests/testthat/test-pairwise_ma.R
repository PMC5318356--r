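test_that("study-level odds ratios match hand-computed 2x2 values", {
  same <- study_effect_binary(bin_arm("S1", "placebo", 20, 10),
                              bin_arm("S1", "topiramate", 20, 10))
  expect_equal(same$effect, 0)
  expect_equal(same$se, sqrt(0.4))

  big <- study_effect_binary(bin_arm("S1", "placebo", 20, 5),
                             bin_arm("S1", "topiramate", 20, 15))
  expect_equal(big$effect, log(9))
  expect_equal(big$se, sqrt(1 / 15 + 1 / 5 + 1 / 5 + 1 / 15))

  # zero cell: 0.5 added to all four cells
  zero <- study_effect_binary(bin_arm("S1", "placebo", 10, 5),
                              bin_arm("S1", "topiramate", 10, 0))
  expect_equal(zero$effect, log((0.5 * 5.5) / (10.5 * 5.5)))
  expect_equal(zero$se, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5))
  # no correction when no zero cell
  expect_equal(big$effect, log((15 * 15) / (5 * 5)))
})

test_that("mean differences and their antisymmetry are exact", {
  null <- study_effect_continuous(cont_arm("S1", "placebo", 50, 5, 2),
                                  cont_arm("S1", "topiramate", 50, 5, 2))
  expect_equal(null$effect, 0)
  expect_equal(null$se, 0.4)

  md <- study_effect_continuous(cont_arm("S1", "placebo", 36, 6, 3),
                                cont_arm("S1", "topiramate", 36, 4, 3))
  expect_equal(md$effect, -2)
  expect_equal(md$se, sqrt(0.5))
  flipped <- study_effect_continuous(cont_arm("S1", "topiramate", 36, 4, 3),
                                     cont_arm("S1", "placebo", 36, 6, 3))
  expect_equal(flipped$effect, 2)
})

make_eff <- function(y, se) {
  lapply(seq_along(y), function(i) {
    list(study_id = paste0("S", i), comparison = c("placebo", "topiramate"),
         effect = y[i], se = se[i], scale = "logOR")
  })
}

test_that("DerSimonian-Laird pooling matches the closed form", {
  dup <- pool_dl(make_eff(c(0.5, 0.5), c(0.2, 0.2)))
  expect_equal(dup$Q, 0)
  expect_equal(dup$tau2, 0)
  expect_equal(dup$pooled, 0.5)
  expect_equal(dup$se, 0.2 / sqrt(2))

  one <- pool_dl(make_eff(1.0, 0.3))
  expect_equal(one$pooled, 1.0)
  expect_equal(one$tau2, 0)
  expect_equal(round(one$ci_low, 3), 0.412)
  expect_equal(round(one$ci_high, 3), 1.588)

  # hand-derived: w = 25 each, Q = 12.5, C = 25, tau2 = 11.5/25
  het <- pool_dl(make_eff(c(0, 1), c(0.2, 0.2)))
  expect_equal(het$Q, 12.5)
  expect_equal(het$tau2, 0.46)
  expect_equal(het$pooled, 0.5)
  expect_equal(het$se, 0.5)
  expect_equal(het$I2, 92)

  expect_error(pool_dl(list()), "no effects")
})

test_that("pooling is antisymmetric, convex and reduces to fixed effect when homogeneous", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    y <- rnorm(k); se <- runif(k, 0.1, 0.5)
    p <- pool_dl(make_eff(y, se))
    pneg <- pool_dl(make_eff(-y, se))
    expect_equal(pneg$pooled, -p$pooled)
    expect_equal(pneg$ci_low, -p$ci_high)
    expect_equal(pneg$ci_high, -p$ci_low)
    expect_gte(p$pooled, min(y) - 1e-12)
    expect_lte(p$pooled, max(y) + 1e-12)
    if (p$tau2 == 0) {
      # independent fixed-effect inverse-variance oracle
      w <- 1 / se^2
      expect_equal(p$pooled, sum(w * y) / sum(w))
      expect_equal(p$se, sqrt(1 / sum(w)))
    }
  }
})

test_that("pooling agrees with the metafor reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(7)
  y <- rnorm(6, 0.4, 0.5); se <- runif(6, 0.1, 0.4)
  ours <- pool_dl(make_eff(y, se))
  ref <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(ours$pooled, unname(ref$beta[1, 1]), tolerance = 1e-10)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
  expect_equal(ours$I2, ref$I2, tolerance = 1e-6)
})

test_that("confidence interval coverage is nominal for homogeneous studies", {
  set.seed(99)
  theta <- 0.3
  hits <- 0L
  for (r in 1:500) {
    se <- runif(50, 0.08, 0.35)
    y <- rnorm(50, theta, se)
    p <- pool_dl(make_eff(y, se))
    if (p$ci_low <= theta && theta <= p$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.91)
  expect_lte(hits / 500, 0.99)
})

test_that("pairwise tables cover every direct comparison and calibrate under the null", {
  sim <- simulate_network(make_paper_like_scenario(seed = 6))
  suppressWarnings({
    tab <- pairwise_table(sim$arms, 9)
    dc <- direct_comparisons(build_network(sim$arms, 9))
  })
  expect_equal(nrow(tab), nrow(dc))
  expect_setequal(paste(tab$ref, tab$alt), paste(dc$t1, dc$t2))
  expect_true(all(tab$scale == "OR"))

  # single contributing study
  one <- rbind(bin_arm("S1", "placebo", 50, 5), bin_arm("S1", "topiramate", 50, 9))
  t1 <- pairwise_table(one, 9)
  expect_equal(t1$k, 1L)

  # null simulation: large trials, no heterogeneity
  sc <- triangle_scenario(seed = 7, tau = 0, n_per_arm = 1000, trials = 20,
                          true_d = c(placebo = 0, topiramate = 0, propranolol = 0))
  nullsim <- simulate_network(sc)
  nulltab <- pairwise_table(nullsim$arms, 9)
  expect_true(all(abs(log(nulltab$effect)) < 0.15))
})
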