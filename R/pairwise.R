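#' Study-level log odds ratio from two arms
#'
#' Computes the log odds ratio of the alternative arm versus the reference
#' arm of one study, with the usual 0.5 continuity correction added to all
#' four cells of the 2x2 table only when some cell is zero.
#'
#' @param ref_arm,alt_arm Single arm records (one-row data frames or lists)
#'   of the same study on a binary endpoint.
#' @param correction Continuity constant (default 0.5).
#' @return List with `study_id`, `comparison` (`c(ref, alt)` treatments),
#'   `effect` (log OR), `se` and `scale = "logOR"`.
#' @export
study_effect_binary <- function(ref_arm, alt_arm, correction = 0.5) {
  stopifnot(correction >= 0)
  if (ref_arm$study_id != alt_arm$study_id) {
    stop("arms belong to different studies", call. = FALSE)
  }
  a <- alt_arm$events; b <- alt_arm$n - alt_arm$events
  c_ <- ref_arm$events; d <- ref_arm$n - ref_arm$events
  if (any(is.na(c(a, b, c_, d)))) {
    stop("binary effect requires event counts (study ", ref_arm$study_id,
         ")", call. = FALSE)
  }
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + correction; b <- b + correction
    c_ <- c_ + correction; d <- d + correction
  }
  if (any(c(a, b, c_, d) == 0)) {
    stop("degenerate 2x2 table in study ", ref_arm$study_id, call. = FALSE)
  }
  list(study_id = ref_arm$study_id,
       comparison = c(ref_arm$treatment, alt_arm$treatment),
       effect = log((a * d) / (b * c_)),
       se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d),
       scale = "logOR")
}

#' Study-level raw mean difference from two arms
#'
#' @param ref_arm,alt_arm Single arm records of the same study on a
#'   continuous endpoint (mean, sd, n present).
#' @return List with `study_id`, `comparison`, `effect` (mean difference
#'   alt - ref), `se` and `scale = "MD"`.
#' @export
study_effect_continuous <- function(ref_arm, alt_arm) {
  if (ref_arm$study_id != alt_arm$study_id) {
    stop("arms belong to different studies", call. = FALSE)
  }
  if (any(is.na(c(ref_arm$mean, ref_arm$sd, alt_arm$mean, alt_arm$sd)))) {
    stop("continuous effect requires mean and sd (study ", ref_arm$study_id,
         ")", call. = FALSE)
  }
  list(study_id = ref_arm$study_id,
       comparison = c(ref_arm$treatment, alt_arm$treatment),
       effect = alt_arm$mean - ref_arm$mean,
       se = sqrt(alt_arm$sd^2 / alt_arm$n + ref_arm$sd^2 / ref_arm$n),
       scale = "MD")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools study effects with the DerSimonian-Laird moment estimator of the
#' between-study variance: with fixed-effect weights \eqn{w_i = 1/se_i^2},
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2} and
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))}. The
#' summary effect uses random-effects weights \eqn{w^*_i = 1/(se_i^2+\tau^2)}
#' with a Wald 95% confidence interval.
#'
#' @param effects List of study effect estimates (as returned by the
#'   `study_effect_*` functions), all on the same comparison and scale.
#' @return List of class `pooled_result`: `comparison`, `k`, `pooled`,
#'   `se`, `ci_low`, `ci_high`, `Q`, `tau2`, `I2` (percent), `scale`.
#' @export
pool_dl <- function(effects) {
  if (length(effects) == 0L) stop("no effects to pool", call. = FALSE)
  scale <- unique(vapply(effects, `[[`, "", "scale"))
  if (length(scale) != 1L) stop("mixed effect scales", call. = FALSE)
  cmp <- unique(t(vapply(effects, `[[`, c("", ""), "comparison")))
  if (nrow(cmp) != 1L) stop("mixed comparisons", call. = FALSE)
  y <- vapply(effects, `[[`, 1.0, "effect")
  se <- vapply(effects, `[[`, 1.0, "se")
  stopifnot(all(se > 0), all(is.finite(y)))
  k <- length(y)
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  if (k > 1L) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
    I2 <- max(0, (Q - (k - 1)) / Q) * 100
    if (Q == 0) I2 <- 0
  } else {
    tau2 <- 0
    I2 <- 0
  }
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se_pooled <- 1 / sqrt(sum(wstar))
  structure(list(comparison = cmp[1, ], k = k, pooled = pooled,
                 se = se_pooled,
                 ci_low = pooled - 1.96 * se_pooled,
                 ci_high = pooled + 1.96 * se_pooled,
                 Q = Q, tau2 = tau2, I2 = I2, scale = scale),
            class = "pooled_result")
}

# All two-arm study effects contributing to one endpoint. Multi-arm studies
# contribute every within-study pair. Zero-zero binary studies are dropped
# (no information about the odds ratio), with a warning.
endpoint_effects <- function(arms, endpoint, correction = 0.5,
                             crossover_rho = NULL) {
  ep <- as_endpoint(endpoint)
  net <- build_network(arms, endpoint)
  binary <- ep$scale == "binary_OR"
  effects <- list()
  for (id in names(net$studies)) {
    s <- net$studies[[id]]
    tr <- unique(s$treatment)
    tr <- tr[treatment_order(tr)]
    cmb <- utils::combn(tr, 2)
    for (j in seq_len(ncol(cmb))) {
      ref <- s[s$treatment == cmb[1, j], ][1, ]
      alt <- s[s$treatment == cmb[2, j], ][1, ]
      if (binary) {
        if (ref$events == 0 && alt$events == 0) {
          warning("study ", id, " has zero events in both arms for ",
                  ep$name, "; excluded", call. = FALSE)
          next
        }
        if (ref$events == ref$n && alt$events == alt$n) {
          warning("study ", id, " has all events in both arms for ",
                  ep$name, "; excluded", call. = FALSE)
          next
        }
        eff <- study_effect_binary(ref, alt, correction)
      } else {
        eff <- study_effect_continuous(ref, alt)
        if (!is.null(crossover_rho) && ref$design == "crossover") {
          # sensitivity option: within-subject correlation shrinks the SE of
          # a crossover contrast by sqrt(1 - rho)
          eff$se <- eff$se * sqrt(1 - crossover_rho)
        }
      }
      effects[[length(effects) + 1L]] <- eff
    }
  }
  effects
}

#' Pairwise random-effects meta-analysis table for one endpoint
#'
#' Runs [pool_dl()] on every direct comparison of the endpoint's evidence
#' network. Odds ratios are reported exponentiated; mean differences on the
#' raw scale.
#'
#' @param arms Arm-record data frame.
#' @param endpoint Endpoint code or name.
#' @param correction Continuity constant for sparse 2x2 tables.
#' @param crossover_rho Optional within-subject correlation for a crossover
#'   sensitivity analysis of continuous endpoints (default `NULL`: crossover
#'   arm summaries are pooled as parallel-group data).
#' @return Data frame with one row per direct comparison: `ref`, `alt`, `k`,
#'   `effect`, `ci_low`, `ci_high`, `tau2`, `Q`, `I2`, `scale`.
#' @export
pairwise_table <- function(arms, endpoint, correction = 0.5,
                           crossover_rho = NULL) {
  ep <- as_endpoint(endpoint)
  effects <- endpoint_effects(arms, endpoint, correction, crossover_rho)
  if (!length(effects)) {
    return(data.frame(ref = character(), alt = character(), k = integer(),
                      effect = numeric(), ci_low = numeric(),
                      ci_high = numeric(), tau2 = numeric(), Q = numeric(),
                      I2 = numeric(), scale = character(),
                      stringsAsFactors = FALSE))
  }
  key <- vapply(effects, function(e) paste(e$comparison, collapse = " vs "),
                "")
  rows <- lapply(split(effects, key), function(group) {
    p <- pool_dl(group)
    expit <- p$scale == "logOR"
    data.frame(ref = p$comparison[1], alt = p$comparison[2], k = p$k,
               effect = if (expit) exp(p$pooled) else p$pooled,
               ci_low = if (expit) exp(p$ci_low) else p$ci_low,
               ci_high = if (expit) exp(p$ci_high) else p$ci_high,
               tau2 = p$tau2, Q = p$Q, I2 = p$I2,
               scale = if (expit) "OR" else "MD",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tr <- mignet_treatments()
  out <- out[order(match(out$ref, tr$name), match(out$alt, tr$name)), ]
  rownames(out) <- NULL
  out
}
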