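# Split-chain potential scale reduction factor (R-hat) and a basic
# effective sample size, computed from per-chain draw vectors.

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2L
    if (m < 2L) stop("chains too short for split diagnostics", call. = FALSE)
    out <- c(out, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  out
}

rhat_split <- function(chains) {
  sp <- split_chains(chains)
  n <- length(sp[[1]])
  means <- vapply(sp, mean, 1.0)
  vars <- vapply(sp, stats::var, 1.0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

ess_basic <- function(chains) {
  sp <- split_chains(chains)
  n <- length(sp[[1]]); m <- length(sp)
  means <- vapply(sp, mean, 1.0)
  vars <- vapply(sp, stats::var, 1.0)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (var_plus <= 0) return(m * n)
  # Geyer initial-positive-sequence estimate of the autocorrelation time
  max_lag <- min(n - 2L, 200L)
  rho <- numeric(max_lag)
  for (t in seq_len(max_lag)) {
    acov <- mean(vapply(sp, function(ch) {
      mean((ch[seq_len(n - t)] - mean(ch)) * (ch[t + seq_len(n - t)] - mean(ch)))
    }, 1.0))
    rho[t] <- 1 - (W - acov) / var_plus
  }
  tau_sum <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau_sum <- tau_sum + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tau_sum)
  min(ess, m * n)
}

#' Convergence diagnostics of an NMA posterior
#'
#' Split-chain potential scale reduction factor (R-hat) and effective
#' sample size for every basic parameter and the heterogeneity SD.
#'
#' @param post An `nma_posterior` with at least two chains.
#' @return Data frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergence <- function(post) {
  stopifnot(inherits(post, "nma_posterior"))
  if (length(post$d) < 2L) {
    stop("convergence diagnostics need >= 2 chains", call. = FALSE)
  }
  params <- setdiff(post$treatments, post$reference)
  rows <- lapply(params, function(tr) {
    chains <- lapply(post$d, function(m) m[, tr])
    data.frame(parameter = paste0("d[", tr, "]"),
               rhat = rhat_split(chains), ess = ess_basic(chains),
               stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(data.frame(parameter = "tau",
                                  rhat = rhat_split(post$tau),
                                  ess = ess_basic(post$tau),
                                  stringsAsFactors = FALSE)))
  if (!is.null(post$d_split)) {
    rows <- c(rows, list(data.frame(parameter = "d_direct",
                                    rhat = rhat_split(post$d_split),
                                    ess = ess_basic(post$d_split),
                                    stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
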