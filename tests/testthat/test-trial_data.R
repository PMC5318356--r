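test_that("endpoint and treatment registries satisfy their invariants", {
  eps <- mignet_endpoints()
  expect_identical(eps$scale[1:2], rep("continuous_MD", 2))
  expect_identical(eps$scale[3:9], rep("binary_OR", 7))
  expect_identical(eps$direction[3], "higher_is_better")
  expect_true(all(eps$direction[-3] == "lower_is_better"))
  tr <- mignet_treatments()
  expect_identical(tr$code, LETTERS[1:7])
  expect_identical(tr$name[c(1, 7)], c("placebo", "valproate"))
  expect_identical(as_endpoint(3)$name, as_endpoint("reduction50")$name)
  expect_error(as_endpoint("not_an_endpoint"), "unknown endpoint")
})

test_that("arm tables are read, validated and round-tripped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,year,design,blinding,endpoint,treatment,n,events,mean,sd,follow_up_weeks",
    "S1,2010,parallel,double,9,placebo,50,5,,,12",
    "S1,2010,parallel,double,9,topiramate,50,9,,,12"), path)
  arms <- read_arm_table(path)
  expect_equal(nrow(arms), 2L)
  expect_identical(arms$treatment, c("placebo", "topiramate"))
  expect_equal(arms$endpoint, c(9L, 9L))

  writeLines(c(
    "study_id,year,design,blinding,endpoint,treatment,n,events,mean,sd,follow_up_weeks",
    "S9,2010,parallel,double,9,placebo,10,12,,,12"), path)
  expect_error(read_arm_table(path), "S9")

  writeLines(c(
    "study_id,year,design,blinding,endpoint,treatment,n,events,mean,sd",
    "S1,2010,parallel,double,9,placebo,50,5,,"), path)
  expect_error(read_arm_table(path), "follow_up_weeks")

  # round trip of a simulated 50-record table
  sim <- simulate_network(triangle_scenario(seed = 4, trials = 9))
  tab <- sim$arms[1:50, ]
  out <- withr::local_tempfile(fileext = ".csv")
  write_arm_table(tab, out)
  back <- read_arm_table(out)
  expect_equal(back, tab, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("arm validation rejects scale mismatches", {
  bad <- bin_arm("S1", "placebo", 50, 5)
  bad$mean <- 3
  expect_error(validate_arms(bad), "must not carry mean")
  bad2 <- cont_arm("S1", "placebo", 50, 4, 0)
  expect_error(validate_arms(rbind(cont_arm("S1", "placebo", 50, 4, 2),
                                   bad2)), "sd must be")
})

test_that("build_network forms nodes, edges and detects disconnection", {
  arms <- rbind(bin_arm("S1", "placebo", 50, 5), bin_arm("S1", "topiramate", 50, 8),
                bin_arm("S2", "topiramate", 50, 6), bin_arm("S2", "propranolol", 50, 9))
  net <- build_network(arms, 9)
  expect_s3_class(net, "evidence_network")
  expect_identical(net$treatments, c("placebo", "topiramate", "propranolol"))
  expect_equal(nrow(net$edges), 2L)

  disc <- rbind(bin_arm("S1", "placebo", 50, 5), bin_arm("S1", "topiramate", 50, 8),
                bin_arm("S2", "propranolol", 50, 6), bin_arm("S2", "gabapentin", 50, 9))
  err <- tryCatch(build_network(disc, 9), error = identity)
  expect_match(conditionMessage(err), "not connected")
  expect_match(conditionMessage(err), "placebo,topiramate")
  expect_match(conditionMessage(err), "propranolol,gabapentin")

  oneurm <- rbind(bin_arm("S1", "placebo", 50, 5), bin_arm("S1", "topiramate", 50, 8),
                  bin_arm("S3", "placebo", 40, 4))
  expect_warning(net2 <- build_network(oneurm, 9), "S3")
  expect_equal(length(net2$studies), 1L)
})

test_that("direct comparisons match the brute-force pair enumeration and are order-invariant", {
  sim <- simulate_network(triangle_scenario(seed = 8, trials = 4))
  arms <- sim$arms
  net <- build_network(arms, 9)
  dc <- direct_comparisons(net)

  # oracle: double loop over studies and within-study treatment pairs
  oracle <- unique(do.call(rbind, lapply(split(arms, arms$study_id), function(s) {
    tr <- sort(unique(s$treatment))
    cmb <- t(combn(tr, 2))
    data.frame(t1 = pmin(cmb[, 1], cmb[, 2]), t2 = pmax(cmb[, 1], cmb[, 2]),
               stringsAsFactors = FALSE)
  })))
  got <- unique(data.frame(t1 = pmin(dc$t1, dc$t2), t2 = pmax(dc$t1, dc$t2),
                           stringsAsFactors = FALSE))
  expect_setequal(paste(got$t1, got$t2), paste(oracle$t1, oracle$t2))

  # permutation invariance
  set.seed(1)
  shuffled <- arms[sample(nrow(arms)), ]
  dc2 <- direct_comparisons(build_network(shuffled, 9))
  expect_equal(dc, dc2, ignore_attr = TRUE)

  # one three-arm study yields all three pairs
  three <- rbind(bin_arm("T1", "placebo", 50, 5), bin_arm("T1", "topiramate", 50, 8),
                 bin_arm("T1", "propranolol", 50, 6))
  expect_equal(nrow(direct_comparisons(build_network(three, 9))), 3L)
})

test_that("the packaged study table reproduces the published headline counts", {
  s <- fixture_summary()
  expect_identical(s$n_studies, 32L)
  expect_identical(s$total_size, 6052L)
  expect_identical(s$n_crossover, 5L)
  expect_identical(s$n_pairs, 10L)
  expect_output(summarize_fixture(), "32 studies, 6052 subjects")
})

test_that("every endpoint of the paper-like geometry forms a connected network", {
  sim <- simulate_network(make_paper_like_scenario(seed = 2))
  for (code in 1:9) {
    net <- suppressWarnings(build_network(sim$arms, code))
    expect_s3_class(net, "evidence_network")
  }
  # withdrawal-due-to-AEs spans all seven interventions
  net9 <- build_network(sim$arms, 9)
  expect_identical(net9$treatments, mignet_treatments()$name)
})
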