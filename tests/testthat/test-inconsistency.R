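test_that("the WLS network fit matches hand-solvable cases", {
  # saturated single-design fit
  f1 <- wls_network_fit(list(list(treats = c("placebo", "topiramate"), y = 0.5)))
  expect_equal(unname(f1$H), matrix(1, 1, 1))
  expect_equal(unname(f1$theta), 0.5)

  # two designs on the same comparison with equal weights: 50/50 contributions
  nh2 <- net_heat(list(list(treats = c("placebo", "topiramate"), y = 0.4),
                       list(treats = c("placebo", "topiramate"), y = 0.6)))
  expect_equal(unname(nh2$contribution), matrix(0.5, 2, 2))

  # noise-free consistent triangle reproduces its inputs exactly
  tri <- list(list(treats = c("placebo", "topiramate"), y = 0.5),
              list(treats = c("topiramate", "propranolol"), y = 0.7),
              list(treats = c("placebo", "propranolol"), y = 1.2))
  f3 <- wls_network_fit(tri)
  expect_equal(unname(f3$fitted), c(0.5, 0.7, 1.2))
  expect_equal(max(abs(f3$residuals)), 0, tolerance = 1e-12)
  # hat matrix is idempotent on the column space of X
  expect_equal(f3$H %*% f3$X, f3$X, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the WLS solution equals the brute-force normal equations", {
  set.seed(31)
  for (r in 1:10) {
    y <- rnorm(3, c(0.5, 0.7, 1.2), 0.3)
    w <- runif(3, 0.5, 4)
    designs <- list(
      list(treats = c("placebo", "topiramate"), y = y[1], W = matrix(w[1])),
      list(treats = c("topiramate", "propranolol"), y = y[2], W = matrix(w[2])),
      list(treats = c("placebo", "propranolol"), y = y[3], W = matrix(w[3])))
    fit <- wls_network_fit(designs)
    X <- rbind(c(1, 0), c(-1, 1), c(0, 1))
    W <- diag(w)
    oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    expect_equal(unname(fit$theta), drop(oracle), tolerance = 1e-10)
    expect_equal(fit$H %*% fit$X, fit$X, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("disconnected design sets are rejected with their components", {
  designs <- list(list(treats = c("placebo", "topiramate"), y = 0.5),
                  list(treats = c("propranolol", "gabapentin"), y = 0.2))
  expect_error(wls_network_fit(designs), "rank deficient")
})

test_that("the Q decomposition is additive and responds to injected inconsistency", {
  # simulated binary network: identity checked at machine precision
  for (seed in c(41, 42, 43)) {
    sim <- simulate_network(triangle_scenario(seed = seed, tau = 0.3,
                                              trials = 6))
    dcx <- design_contrasts(sim$arms, 9)
    q <- q_decomposition(dcx)
    expect_lt(abs(q$Q_total - q$Q_het - q$Q_inc), 1e-9)
    expect_gte(q$Q_het, 0)
    expect_gte(q$Q_inc, -1e-12)
  }

  # noise-free consistent triangle: no inconsistency
  tri <- list(list(treats = c("placebo", "topiramate"), y = 0.5),
              list(treats = c("topiramate", "propranolol"), y = 0.7),
              list(treats = c("placebo", "propranolol"), y = 1.2))
  expect_equal(q_decomposition(tri)$Q_inc, 0, tolerance = 1e-12)

  # duplicated identical studies: all heterogeneity vanishes
  arms <- rbind(bin_arm("S1", "placebo", 100, 20), bin_arm("S1", "topiramate", 100, 30),
                bin_arm("S2", "placebo", 100, 20), bin_arm("S2", "topiramate", 100, 30),
                bin_arm("S3", "placebo", 100, 25), bin_arm("S3", "propranolol", 100, 35),
                bin_arm("S4", "topiramate", 100, 25), bin_arm("S4", "propranolol", 100, 30))
  q2 <- q_decomposition(design_contrasts(arms, 9))
  expect_equal(q2$Q_het, 0, tolerance = 1e-12)

  # perturbing one design away from additivity strictly increases Q_inc
  tri_bad <- tri
  tri_bad[[3]]$y <- 1.2 + 2.0
  expect_gt(q_decomposition(tri_bad)$Q_inc, q_decomposition(tri)$Q_inc)
})

test_that("net heat rows are normalised and localise injected inconsistency", {
  tri <- list(list(treats = c("placebo", "topiramate"), y = 0.5),
              list(treats = c("topiramate", "propranolol"), y = 0.7),
              list(treats = c("placebo", "propranolol"), y = 1.2))
  nh <- net_heat(tri)
  expect_equal(unname(rowSums(nh$contribution)), rep(1, 3), tolerance = 1e-9)
  expect_equal(max(abs(nh$delta_inconsistency)), 0, tolerance = 1e-10)

  tri_bad <- tri
  tri_bad[[3]]$y <- 2.2  # placebo-propranolol design now conflicts
  nh2 <- net_heat(tri_bad)
  hot <- which(abs(nh2$delta_inconsistency) == max(abs(nh2$delta_inconsistency)),
               arr.ind = TRUE)
  key <- "placebo-propranolol"
  expect_true(all(rownames(nh2$delta_inconsistency)[hot[, 1]] == key |
                    colnames(nh2$delta_inconsistency)[hot[, 2]] == key))

  expect_error(net_heat(list(list(treats = c("placebo", "topiramate"),
                                  y = 0.5))), ">= 2 designs")
})

test_that("node splitting requires an indirect path and reports coherent summaries", {
  two <- rbind(bin_arm("S1", "placebo", 100, 10), bin_arm("S1", "topiramate", 100, 20))
  expect_error(node_split(two, 9, c("placebo", "topiramate"), quick_cfg()),
               "not splittable")

  sim <- simulate_network(triangle_scenario(seed = 51, trials = 6))
  ns <- suppressWarnings(node_split(sim$arms, 9, c("placebo", "topiramate"),
                                    quick_cfg(seed = 8, iterations = 4000,
                                              burnin = 1500)))
  expect_gte(ns$p_value, 0)
  expect_lte(ns$p_value, 1)
  expect_equal(ns$difference[["median"]],
               ns$direct[["median"]] - ns$indirect[["median"]],
               tolerance = 0.1)
})

test_that("node-split p-values are approximately uniform under consistency", {
  p <- numeric(200)
  for (r in seq_len(200)) {
    sc <- triangle_scenario(seed = 2000 + r, n_per_arm = 500)
    sim <- simulate_network(sc)
    cfg <- quick_cfg(seed = 17 + 131L * r, iterations = 6000, burnin = 2000)
    p[r] <- suppressWarnings(
      node_split(sim$arms, 9, c("placebo", "topiramate"), cfg))$p_value
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("funnel centering and Egger regression behave as designed", {
  # single-study comparisons center to zero, Egger needs three studies
  eff <- list(list(study_id = "S1", comparison = c("placebo", "topiramate"),
                   effect = 0.4, se = 0.2, scale = "logOR"),
              list(study_id = "S2", comparison = c("placebo", "propranolol"),
                   effect = -0.1, se = 0.3, scale = "logOR"))
  fd <- funnel_data(eff)
  expect_equal(fd$data$centered_effect, c(0, 0))
  expect_null(fd$egger)

  # unbiased continuous simulation: intercept near zero most of the time
  set.seed(19)
  rejections <- 0L
  for (r in 1:50) {
    se <- runif(40, 0.05, 0.5)
    y <- rnorm(40, 0.3, se)
    eff <- lapply(seq_along(y), function(i) {
      list(study_id = paste0("S", i), comparison = c("placebo", "topiramate"),
           effect = y[i], se = se[i], scale = "MD")
    })
    if (funnel_data(eff)$egger$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / 50, 0.10)

  # injected small-study bias pushes the intercept positive on average
  set.seed(20)
  intercepts <- vapply(1:50, function(r) {
    se <- runif(40, 0.05, 0.5)
    y <- rnorm(40, 0.3 + 0.5 * se, se)
    eff <- lapply(seq_along(y), function(i) {
      list(study_id = paste0("S", i), comparison = c("placebo", "topiramate"),
           effect = y[i], se = se[i], scale = "MD")
    })
    funnel_data(eff)$egger$intercept
  }, 1.0)
  expect_gt(mean(intercepts), 0)
})
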