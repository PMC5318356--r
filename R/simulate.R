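#' Define a trial-network simulation scenario
#'
#' Describes a network of randomized trials with known truth: true basic
#' effects versus the reference treatment, study-level baselines, between
#' -study heterogeneity, optional loop inconsistency injected on chosen
#' edges, design mix and sample sizes. Binary endpoints draw arm events
#' from binomials on the logit scale; continuous endpoints draw arm means
#' around the study baseline with a common outcome SD.
#'
#' @param treatments Treatment names (reference first). Single letters are
#'   mapped through the packaged registry (A = placebo, ...).
#' @param true_d Named vector of true effects versus the reference (log OR
#'   or MD units); the reference entry must be 0 and missing treatments
#'   default to 0.
#' @param comparisons Data frame (`t1`, `t2`) of edges carrying trials;
#'   default: every treatment versus the reference.
#' @param trials_per_comparison Trials per edge (single count, or vector
#'   matching `comparisons` rows).
#' @param n_per_arm Participants per arm: a count or a range `c(lo, hi)`.
#' @param endpoint Endpoint code or name (sets the outcome scale).
#' @param tau Between-study SD of the true study effects.
#' @param inconsistency Named vector of additive offsets on specific edges,
#'   names like `"placebo vs topiramate"` (or `"A vs B"`).
#' @param baseline_mean,baseline_sd Study baseline distribution: logit
#'   event probability for binary endpoints (defaults `qlogis(0.3)`, 0.3),
#'   outcome mean for continuous (defaults 5, 0.3 — roughly monthly
#'   migraine days under no treatment).
#' @param sigma Common outcome SD for continuous endpoints.
#' @param crossover_fraction Proportion of trials flagged as crossover.
#' @param dropout_rate Baseline probability used when the endpoint is a
#'   withdrawal outcome (overrides `baseline_mean` on the logit scale).
#' @param seed Integer seed; simulation is fully reproducible.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(treatments = c("placebo", "topiramate",
                                               "propranolol"),
                                true_d = NULL, comparisons = NULL,
                                trials_per_comparison = 5, n_per_arm = 100,
                                endpoint = "withdrawal", tau = 0.1,
                                inconsistency = NULL,
                                baseline_mean = NULL, baseline_sd = 0.3,
                                sigma = 2, crossover_fraction = 0,
                                dropout_rate = 0.15, seed = 1) {
  tr <- mignet_treatments()
  lettered <- match(toupper(treatments), tr$code)
  treatments <- ifelse(!is.na(lettered) & nchar(treatments) == 1L,
                       tr$name[lettered], tolower(treatments))
  ep <- as_endpoint(endpoint)
  if (is.null(true_d)) true_d <- stats::setNames(numeric(length(treatments)),
                                                 treatments)
  full <- stats::setNames(numeric(length(treatments)), treatments)
  full[names(true_d)] <- true_d
  if (abs(full[[treatments[1]]]) > 0) {
    stop("reference treatment must have true_d = 0", call. = FALSE)
  }
  if (is.null(comparisons)) {
    comparisons <- data.frame(t1 = treatments[1], t2 = treatments[-1],
                              stringsAsFactors = FALSE)
  }
  stopifnot(tau >= 0, crossover_fraction >= 0, crossover_fraction <= 1,
            all(n_per_arm >= 2))
  if (length(trials_per_comparison) == 1L) {
    trials_per_comparison <- rep(trials_per_comparison, nrow(comparisons))
  }
  stopifnot(length(trials_per_comparison) == nrow(comparisons))
  g <- igraph::graph_from_data_frame(comparisons, directed = FALSE,
                                     vertices = treatments)
  if (igraph::components(g)$no > 1) {
    stop("comparison graph is disconnected", call. = FALSE)
  }
  binary <- ep$scale == "binary_OR"
  if (is.null(baseline_mean)) {
    baseline_mean <- if (!binary) 5 else if (ep$name %in%
      c("withdrawal", "withdrawal_aes")) stats::qlogis(dropout_rate) else
      stats::qlogis(0.3)
  }
  structure(list(treatments = treatments, true_d = full,
                 comparisons = comparisons,
                 trials_per_comparison = trials_per_comparison,
                 n_per_arm = n_per_arm, endpoint = ep, tau = tau,
                 inconsistency = inconsistency,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sigma = sigma, crossover_fraction = crossover_fraction,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "simulation_scenario")
}

draw_arm_n <- function(n_per_arm) {
  if (length(n_per_arm) == 2L) {
    as.integer(round(stats::runif(1, n_per_arm[1], n_per_arm[2])))
  } else as.integer(n_per_arm)
}

#' Simulate a network of randomized trials
#'
#' Per trial on edge (a, b) the true study effect is
#' `theta ~ Normal(true_d[b] - true_d[a] + offset_ab, tau^2)`; binary arms
#' draw events from `Binomial(n, plogis(baseline))` and
#' `Binomial(n, plogis(baseline + theta))`, continuous arms draw means
#' around `baseline` and `baseline + theta` with SD `sigma/sqrt(n)` and
#' report `sigma` as the arm SD. Fully reproducible from the scenario seed.
#'
#' @param scenario A [simulation_scenario()]. For scenarios built by
#'   [make_paper_like_scenario()] the packaged study geometry (sizes,
#'   designs, endpoint sets) is reproduced.
#' @return List of class `simulated_network`: `arms` (arm-record data
#'   frame) and `truth` (true effects, tau, offsets, seed).
#' @export
simulate_network <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  if (!is.null(scenario$studies)) return(simulate_from_studies(scenario))
  ep <- scenario$endpoint
  binary <- ep$scale == "binary_OR"
  offs <- offsets_lookup(scenario)
  rows <- list()
  trial_no <- 0L
  for (e in seq_len(nrow(scenario$comparisons))) {
    a <- scenario$comparisons$t1[e]; b <- scenario$comparisons$t2[e]
    off <- offs(a, b)
    for (s in seq_len(scenario$trials_per_comparison[e])) {
      trial_no <- trial_no + 1L
      id <- sprintf("S%03d_%s_%s", trial_no, treatment_code(a),
                    treatment_code(b))
      design <- if (stats::runif(1) < scenario$crossover_fraction)
        "crossover" else "parallel"
      theta <- stats::rnorm(1, scenario$true_d[[b]] - scenario$true_d[[a]] +
                              off, scenario$tau)
      base <- stats::rnorm(1, scenario$baseline_mean, scenario$baseline_sd)
      n1 <- draw_arm_n(scenario$n_per_arm)
      n2 <- draw_arm_n(scenario$n_per_arm)
      rows[[length(rows) + 1L]] <- simulate_two_arms(
        id, design, ep, a, b, base, theta, n1, n2, binary, scenario$sigma)
    }
  }
  arms <- do.call(rbind, rows)
  rownames(arms) <- NULL
  structure(list(arms = validate_arms(arms),
                 truth = list(true_d = scenario$true_d, tau = scenario$tau,
                              inconsistency = scenario$inconsistency,
                              seed = scenario$seed)),
            class = "simulated_network")
}

offsets_lookup <- function(scenario) {
  offs <- scenario$inconsistency
  if (!is.null(offs)) {
    nm <- names(offs)
    nm <- vapply(strsplit(nm, " vs ", fixed = TRUE), function(p) {
      tr <- mignet_treatments()
      p <- ifelse(nchar(p) == 1L & toupper(p) %in% tr$code,
                  tr$name[match(toupper(p), tr$code)], tolower(p))
      paste(sort(p), collapse = " vs ")
    }, "")
    names(offs) <- nm
  }
  function(a, b) {
    if (is.null(offs)) return(0)
    key <- paste(sort(c(a, b)), collapse = " vs ")
    if (key %in% names(offs)) offs[[key]] else 0
  }
}

simulate_two_arms <- function(id, design, ep, a, b, base, theta, n1, n2,
                              binary, sigma) {
  if (binary) {
    e1 <- stats::rbinom(1, n1, stats::plogis(base))
    e2 <- stats::rbinom(1, n2, stats::plogis(base + theta))
    data.frame(study_id = id, year = 2020L, design = design,
               blinding = "double", endpoint = ep$code,
               treatment = c(a, b), n = c(n1, n2), events = c(e1, e2),
               mean = NA_real_, sd = NA_real_, follow_up_weeks = 12,
               stringsAsFactors = FALSE)
  } else {
    m1 <- stats::rnorm(1, base, sigma / sqrt(n1))
    m2 <- stats::rnorm(1, base + theta, sigma / sqrt(n2))
    data.frame(study_id = id, year = 2020L, design = design,
               blinding = "double", endpoint = ep$code,
               treatment = c(a, b), n = c(n1, n2), events = NA_real_,
               mean = c(m1, m2), sd = sigma, follow_up_weeks = 12,
               stringsAsFactors = FALSE)
  }
}

# simulate outcomes on the packaged study geometry (one row per study x
# measured endpoint); arm sizes split the printed total
simulate_from_studies <- function(scenario) {
  studies <- scenario$studies
  rows <- list()
  for (i in seq_len(nrow(studies))) {
    st <- studies[i, ]
    a <- st$treat1; b <- st$treat2
    # orient edges so the canonical-order treatment is the reference arm
    if (treatment_order(c(a, b))[1] == 2L) { tmp <- a; a <- b; b <- tmp }
    n1 <- st$size %/% 2L; n2 <- st$size - n1
    offs <- offsets_lookup(scenario)
    for (code in st$endpoints[[1]]) {
      ep <- as_endpoint(code)
      binary <- ep$scale == "binary_OR"
      base_mean <- if (!binary) 5 else if (ep$name %in%
        c("withdrawal", "withdrawal_aes"))
        stats::qlogis(scenario$dropout_rate) else stats::qlogis(0.3)
      theta <- stats::rnorm(1, scenario$true_d[[b]] - scenario$true_d[[a]] +
                              offs(a, b), scenario$tau)
      base <- stats::rnorm(1, base_mean, scenario$baseline_sd)
      rec <- simulate_two_arms(st$study_id, st$design, ep, a, b, base,
                               theta, n1, n2, binary, scenario$sigma)
      rec$blinding <- st$blinding
      rec$year <- st$year
      rows[[length(rows) + 1L]] <- rec
    }
  }
  arms <- do.call(rbind, rows)
  rownames(arms) <- NULL
  structure(list(arms = validate_arms(arms),
                 truth = list(true_d = scenario$true_d, tau = scenario$tau,
                              inconsistency = scenario$inconsistency,
                              seed = scenario$seed)),
            class = "simulated_network")
}

#' Write a simulated network to disk
#'
#' Writes the arm table (`arms.csv`, the [read_arm_table()] contract) and
#' the ground truth (`truth.json`) of a simulated network.
#'
#' @param sim A `simulated_network`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_simulated_network <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arms_path <- file.path(dir, "arms.csv")
  truth_path <- file.path(dir, "truth.json")
  write_arm_table(sim$arms, arms_path)
  truth <- sim$truth
  truth$true_d <- as.list(truth$true_d)  # keep treatment names in JSON
  if (!is.null(truth$inconsistency)) {
    truth$inconsistency <- as.list(truth$inconsistency)
  }
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(arms = arms_path, truth = truth_path))
}

#' Scenario reproducing the packaged evidence-base geometry
#'
#' Builds a scenario over the 7 treatments with the 10 direct comparisons,
#' per-study sizes, designs and endpoint sets of the packaged study table;
#' true effects default to 0 so the simulated network is consistent under
#' the null.
#'
#' @param true_d Optional named true effects versus placebo.
#' @param tau Between-study SD (default 0.1).
#' @param seed Integer seed.
#' @return A `simulation_scenario` whose [simulate_network()] output has
#'   one row per study arm per measured endpoint.
#' @export
make_paper_like_scenario <- function(true_d = NULL, tau = 0.1, seed = 1) {
  fx <- table1_fixture()
  sc <- simulation_scenario(treatments = mignet_treatments()$name,
                            true_d = true_d, tau = tau, seed = seed,
                            comparisons = fixture_summary(fx)$pairs)
  sc$studies <- fx
  sc
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a scenario, fits the NMA, and aggregates recovery
#' of the true basic parameters: bias, RMSE and 95% credible-interval
#' coverage, optionally with node-splitting rejection rates.
#'
#' @param scenario A [simulation_scenario()].
#' @param config An [nma_config()].
#' @param replicates Number of simulation replicates.
#' @param node_split_comparison Optional comparison to node-split each
#'   replicate (adds a rejection-rate column at alpha = 0.05).
#' @return List with per-treatment `bias`, `rmse`, `coverage`, the
#'   replicate-level `estimates` data frame, and `nodesplit_reject` when
#'   requested.
#' @export
recovery_experiment <- function(scenario, config = nma_config(),
                                replicates = 10,
                                node_split_comparison = NULL) {
  stopifnot(replicates >= 1)
  rows <- list(); pvals <- numeric()
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc$seed <- scenario$seed + r - 1L
    sim <- simulate_network(sc)
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    post <- suppressWarnings(fit_nma(sim$arms, scenario$endpoint$code, cfg))
    for (trt in setdiff(post$treatments, post$reference)) {
      dr <- d_draws(post, trt)
      q <- unname(stats::quantile(dr, c(0.5, 0.025, 0.975), type = 7))
      truth <- scenario$true_d[[trt]] - scenario$true_d[[post$reference]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, treatment = trt, truth = truth, estimate = q[1],
        cri_low = q[2], cri_high = q[3],
        covered = truth >= q[2] & truth <= q[3],
        stringsAsFactors = FALSE)
    }
    if (!is.null(node_split_comparison)) {
      ns <- suppressWarnings(node_split(sim$arms, scenario$endpoint$code,
                                        node_split_comparison, cfg))
      pvals <- c(pvals, ns$p_value)
    }
  }
  est <- do.call(rbind, rows)
  agg <- function(f) tapply(est$estimate - est$truth, est$treatment, f)
  out <- list(bias = agg(mean),
              rmse = tapply(est$estimate - est$truth, est$treatment,
                            function(x) sqrt(mean(x^2))),
              coverage = tapply(est$covered, est$treatment, mean),
              estimates = est)
  if (!is.null(node_split_comparison)) {
    out$nodesplit_p <- pvals
    out$nodesplit_reject <- mean(pvals < 0.05)
  }
  out
}
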