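#' Configuration of the Bayesian network meta-analysis
#'
#' Vague-prior defaults: Normal(0, 100^2) on basic parameters and study
#' baselines, Uniform(0, `tau_prior_upper`) on the between-study SD
#' (defaults to 5 on the log-odds scale and 10 on the mean-difference
#' scale when left `NULL`). MCMC settings follow the usual
#' iterations/burn-in/thinning layout; `iterations` counts all draws per
#' chain including burn-in.
#'
#' @param prior_d_sd Prior SD of basic parameters.
#' @param prior_mu_sd Prior SD of study baselines.
#' @param tau_prior_upper Upper bound of the uniform prior on tau, or `NULL`
#'   to pick the scale-dependent default.
#' @param chains Number of chains (at least 2).
#' @param iterations Total iterations per chain (burn-in included).
#' @param burnin Burn-in iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param reference Reference treatment (default placebo).
#' @param adapt Adapt proposal scales during burn-in (default `TRUE`;
#'   disable only to study sampler failure modes).
#' @param init_proposal_scale Initial random-walk proposal SD.
#' @return A list of class `nma_config`.
#' @export
nma_config <- function(prior_d_sd = 100, prior_mu_sd = 100,
                       tau_prior_upper = NULL, chains = 4,
                       iterations = 50000, burnin = 10000, thin = 10,
                       seed = 1, reference = "placebo", adapt = TRUE,
                       init_proposal_scale = 0.5) {
  stopifnot(prior_d_sd > 0, prior_mu_sd > 0, chains >= 2,
            iterations > burnin, burnin >= 0, thin >= 1,
            init_proposal_scale > 0)
  if (!is.null(tau_prior_upper)) stopifnot(tau_prior_upper > 0)
  structure(list(prior_d_sd = prior_d_sd, prior_mu_sd = prior_mu_sd,
                 tau_prior_upper = tau_prior_upper, chains = chains,
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), reference = reference,
                 adapt = isTRUE(adapt),
                 init_proposal_scale = init_proposal_scale),
            class = "nma_config")
}

#' Fit the Bayesian random-effects network meta-analysis
#'
#' Arm-based hierarchical model: binary endpoints use a binomial-logit
#' likelihood on the arm counts, continuous endpoints a normal likelihood
#' on the arm means. Study baselines are nuisance parameters; relative
#' effects of each study's non-baseline arms are exchangeable around the
#' basic-parameter contrasts with between-study SD tau (multi-arm trials
#' via sequential conditional normals with between-arm covariance tau^2/2).
#' Sampling is adaptive Metropolis-within-Gibbs (see the package vignette).
#'
#' @param arms Arm-record data frame.
#' @param endpoint Endpoint code or name.
#' @param config An [nma_config()].
#' @param split Optional comparison `c(ref_treatment, alt_treatment)`: its
#'   two-arm direct studies receive a separate direct-evidence parameter
#'   (used by [node_split()]).
#' @return An object of class `nma_posterior` holding per-chain draws of
#'   the basic parameters `d` (reference column identically 0), baselines
#'   `mu`, heterogeneity `tau` (and `d_split` when splitting), plus the
#'   convergence report and a `converged` flag.
#' @export
fit_nma <- function(arms, endpoint, config = nma_config(), split = NULL) {
  stopifnot(inherits(config, "nma_config"))
  if (!nrow(arms)) stop("empty arm list", call. = FALSE)
  ep <- as_endpoint(endpoint)
  net <- build_network(arms, endpoint)
  binary <- ep$scale == "binary_OR"
  tau_upper <- config$tau_prior_upper
  if (is.null(tau_upper)) tau_upper <- if (binary) 5 else 10

  reference <- tolower(config$reference)
  if (!reference %in% net$treatments) {
    reference <- net$treatments[1]
    message("reference treatment not in network; using ", reference)
  }
  treatments <- c(reference, setdiff(net$treatments, reference))

  split_ids <- character()
  if (!is.null(split)) {
    split <- tolower(split)
    stopifnot(length(split) == 2L, all(split %in% treatments))
    split_ids <- names(net$studies)[vapply(net$studies, function(s) {
      tr <- unique(s$treatment)
      length(tr) == 2L && setequal(tr, split)
    }, TRUE)]
    if (!length(split_ids)) {
      stop("no two-arm direct study for the split comparison", call. = FALSE)
    }
  }

  # flatten arms: baseline arm first within each study
  study_ids <- names(net$studies)
  rows <- list(); study_start <- integer(); study_narms <- integer()
  for (id in study_ids) {
    s <- net$studies[[id]]
    if (anyDuplicated(s$treatment)) {
      stop("study ", id, " has duplicate arms for one treatment",
           call. = FALSE)
    }
    s <- s[order(match(s$treatment, treatments)), , drop = FALSE]
    study_start <- c(study_start, length(rows))
    study_narms <- c(study_narms, nrow(s))
    rows <- c(rows, split(s, seq_len(nrow(s))))
  }
  flat <- do.call(rbind, rows)
  if (any(flat$n <= 0)) stop("non-positive arm size", call. = FALSE)
  arm_treat <- match(flat$treatment, treatments) - 1L
  study_split <- study_ids %in% split_ids

  run_chain <- function(chain) {
    set.seed(config$seed + chain - 1L)
    .nma_mwg_chain(
      as.integer(study_start), as.integer(study_narms),
      as.integer(arm_treat), study_split, binary,
      as.numeric(ifelse(is.na(flat$events), 0, flat$events)),
      as.numeric(flat$n),
      as.numeric(ifelse(is.na(flat$mean), 0, flat$mean)),
      as.numeric(ifelse(is.na(flat$sd), 1, flat$sd^2 / flat$n)),
      length(treatments), config$prior_d_sd, config$prior_mu_sd,
      tau_upper, config$iterations, config$burnin, config$thin,
      length(split_ids) > 0, config$init_proposal_scale, config$adapt)
  }
  chains <- lapply(seq_len(config$chains), run_chain)

  d <- lapply(chains, function(ch) {
    m <- ch$d; colnames(m) <- treatments; m
  })
  mu <- lapply(chains, function(ch) {
    m <- ch$mu; colnames(m) <- study_ids; m
  })
  tau <- lapply(chains, `[[`, "tau")
  d_split <- if (length(split_ids)) lapply(chains, `[[`, "d_split") else NULL

  post <- structure(list(
    endpoint = ep, treatments = treatments, reference = reference,
    studies = study_ids, d = d, mu = mu, tau = tau, d_split = d_split,
    split = split, split_studies = split_ids, config = config,
    tau_prior_upper = tau_upper,
    accept_rate = vapply(chains, `[[`, 1.0, "accept_rate")),
    class = "nma_posterior")
  post$convergence <- convergence(post)
  post$converged <- all(post$convergence$rhat < 1.05, na.rm = TRUE)
  if (!post$converged) {
    warning("NMA did not converge (max R-hat = ",
            format(max(post$convergence$rhat, na.rm = TRUE), digits = 4),
            ") for endpoint ", ep$name, call. = FALSE)
  }
  post
}

#' @export
print.nma_posterior <- function(x, ...) {
  cat("NMA posterior:", x$endpoint$name, "\n")
  cat(" ", length(x$treatments), "treatments (reference:", x$reference,
      ");", length(x$studies), "studies\n")
  cat(" ", length(x$d), "chains x", nrow(x$d[[1]]), "kept draws;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(max R-hat %.3f)\n", max(x$convergence$rhat, na.rm = TRUE)))
  invisible(x)
}

# stack per-chain draws of a basic parameter (link scale)
d_draws <- function(post, treatment) {
  treatment <- tolower(treatment)
  if (!treatment %in% post$treatments) {
    stop("unknown treatment: ", treatment, call. = FALSE)
  }
  unlist(lapply(post$d, function(m) m[, treatment]), use.names = FALSE)
}

tau_draws <- function(post) unlist(post$tau, use.names = FALSE)

#' Posterior relative effect of one treatment versus another
#'
#' Computed draw-wise as `d_b - d_a`; every contrast is a deterministic
#' function of the basic parameters, so consistency holds by construction.
#' For odds-ratio endpoints the summary is exponentiated.
#'
#' @param post An `nma_posterior`.
#' @param a,b Treatments; the effect of `b` relative to `a`.
#' @return List with `median`, `cri_low`, `cri_high` (on the reporting
#'   scale), `scale` (`"OR"` or `"MD"`), and the link-scale `draws`.
#' @export
relative_effect <- function(post, a, b) {
  dr <- d_draws(post, b) - d_draws(post, a)
  q <- unname(stats::quantile(dr, c(0.5, 0.025, 0.975), type = 7))
  expit <- post$endpoint$scale == "binary_OR"
  if (expit) q <- exp(q)
  list(median = q[1], cri_low = q[2], cri_high = q[3],
       scale = if (expit) "OR" else "MD", draws = dr)
}

#' League table of all pairwise contrasts
#'
#' Square matrix over treatments; cell (row, column) summarises the
#' posterior of the row-versus-column contrast (median and 95% credible
#' interval), exponentiated for odds-ratio endpoints. Lower and upper
#' triangles hold reciprocal (OR) or negated (MD) contrasts draw-wise.
#' Cells whose interval excludes the null are flagged significant.
#'
#' @param post An `nma_posterior`.
#' @return Object of class `league_table`: matrices `median`, `cri_low`,
#'   `cri_high`, `significant`, plus `long` (one row per ordered pair) and
#'   the reporting `scale`.
#' @export
league_table <- function(post) {
  tr <- post$treatments
  K <- length(tr)
  expit <- post$endpoint$scale == "binary_OR"
  null_val <- if (expit) 1 else 0
  med <- lo <- hi <- matrix(null_val, K, K, dimnames = list(tr, tr))
  sig <- matrix(FALSE, K, K, dimnames = list(tr, tr))
  long <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    re <- relative_effect(post, tr[j], tr[i])  # row vs column
    med[i, j] <- re$median; lo[i, j] <- re$cri_low; hi[i, j] <- re$cri_high
    sig[i, j] <- re$cri_low > null_val || re$cri_high < null_val
    long[[length(long) + 1L]] <- data.frame(
      row = tr[i], col = tr[j], median = re$median, cr_low = re$cri_low,
      cr_high = re$cri_high, significant = sig[i, j],
      stringsAsFactors = FALSE)
  }
  structure(list(median = med, cri_low = lo, cri_high = hi,
                 significant = sig, long = do.call(rbind, long),
                 scale = if (expit) "OR" else "MD",
                 treatments = tr, endpoint = post$endpoint),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  cat("League table (", x$scale, "): ", x$endpoint$name, "\n", sep = "")
  K <- length(x$treatments)
  fmt <- matrix("", K, K, dimnames = dimnames(x$median))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    fmt[i, j] <- if (i == j) x$treatments[i] else
      sprintf("%s%.2f (%.2f, %.2f)", if (x$significant[i, j]) "*" else "",
              x$median[i, j], x$cri_low[i, j], x$cri_high[i, j])
  }
  print(fmt, quote = FALSE)
  invisible(x)
}
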