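# shared builders for simulated networks and small MCMC configurations

triangle_scenario <- function(seed, tau = 0.1, n_per_arm = 200, trials = 10,
                              endpoint = "withdrawal_aes",
                              inconsistency = NULL,
                              true_d = c(placebo = 0, topiramate = -0.5,
                                         propranolol = -1.0)) {
  simulation_scenario(
    treatments = c("placebo", "topiramate", "propranolol"),
    true_d = true_d,
    comparisons = data.frame(
      t1 = c("placebo", "placebo", "topiramate"),
      t2 = c("topiramate", "propranolol", "propranolol"),
      stringsAsFactors = FALSE),
    trials_per_comparison = trials, n_per_arm = n_per_arm,
    endpoint = endpoint, tau = tau, inconsistency = inconsistency,
    seed = seed)
}

quick_cfg <- function(seed = 1, chains = 2, iterations = 6000,
                      burnin = 2000, thin = 4, ...) {
  nma_config(chains = chains, iterations = iterations, burnin = burnin,
             thin = thin, seed = seed, ...)
}

# one binary arm record
bin_arm <- function(study_id, treatment, n, events, endpoint = 9,
                    design = "parallel") {
  data.frame(study_id = study_id, year = 2020L, design = design,
             blinding = "double", endpoint = endpoint,
             treatment = treatment, n = n, events = events,
             mean = NA_real_, sd = NA_real_, follow_up_weeks = 12,
             stringsAsFactors = FALSE)
}

# one continuous arm record
cont_arm <- function(study_id, treatment, n, mean, sd, endpoint = 1,
                     design = "parallel") {
  data.frame(study_id = study_id, year = 2020L, design = design,
             blinding = "double", endpoint = endpoint,
             treatment = treatment, n = n, events = NA_real_,
             mean = mean, sd = sd, follow_up_weeks = 12,
             stringsAsFactors = FALSE)
}

# minimal posterior object for ranking tests: draws is a matrix with one
# column per treatment (link scale)
fake_posterior <- function(draws, endpoint = "withdrawal") {
  treatments <- colnames(draws)
  structure(list(endpoint = as_endpoint(endpoint),
                 treatments = treatments, reference = treatments[1],
                 d = list(draws)),
            class = "nma_posterior")
}
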