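#' Node-splitting assessment of consistency for one comparison
#'
#' Refits the network meta-analysis with the split comparison's two-arm
#' direct studies assigned their own direct-evidence parameter, while the
#' rest of the network supplies the indirect estimate through the basic
#' parameters. The two-sided Bayesian p-value is
#' `2 * min(P(diff > 0), P(diff < 0))` over draws of
#' `difference = direct - indirect`.
#'
#' @param arms Arm-record data frame.
#' @param endpoint Endpoint code or name.
#' @param comparison Character vector `c(a, b)`; the effect of `b` vs `a`.
#' @param config An [nma_config()].
#' @return Object of class `node_split_result` with posterior summaries of
#'   `direct`, `indirect` and `difference` (link scale) and `p_value`.
#' @export
node_split <- function(arms, endpoint, comparison, config = nma_config()) {
  comparison <- tolower(comparison)
  stopifnot(length(comparison) == 2L)
  net <- build_network(arms, endpoint)
  if (!all(comparison %in% net$treatments)) {
    stop("comparison treatments not in network", call. = FALSE)
  }
  # orient as the network does
  comparison <- comparison[order(match(comparison, net$treatments))]
  dc <- direct_comparisons(net)
  has_direct <- any(dc$t1 == comparison[1] & dc$t2 == comparison[2])
  if (!has_direct) {
    stop("comparison ", paste(comparison, collapse = " vs "),
         " has no direct evidence; not splittable", call. = FALSE)
  }
  direct_ids <- names(net$studies)[vapply(net$studies, function(s) {
    tr <- unique(s$treatment)
    length(tr) == 2L && setequal(tr, comparison)
  }, TRUE)]
  # indirect path must survive removal of the direct studies
  rest <- do.call(rbind, net$studies[setdiff(names(net$studies), direct_ids)])
  splittable <- FALSE
  if (!is.null(rest) && nrow(rest)) {
    pair_list <- lapply(split(rest, rest$study_id), function(s) {
      tr <- sort(unique(s$treatment))
      if (length(tr) < 2) return(NULL)
      t(utils::combn(tr, 2))
    })
    pairs <- do.call(rbind, pair_list)
    if (!is.null(pairs) && nrow(pairs)) {
      g <- igraph::graph_from_data_frame(
        as.data.frame(pairs, stringsAsFactors = FALSE), directed = FALSE,
        vertices = unique(rest$treatment))
      if (all(comparison %in% igraph::V(g)$name)) {
        splittable <- igraph::distances(g, comparison[1],
                                        comparison[2]) < Inf
      }
    }
  }
  if (!splittable) {
    stop("comparison ", paste(comparison, collapse = " vs "),
         " has no indirect path; not splittable", call. = FALSE)
  }

  post <- fit_nma(arms, endpoint, config, split = comparison)
  # d_split measures the higher-indexed treatment vs the lower-indexed one
  # in the fit's own treatment ordering; align the indirect contrast
  ord <- match(comparison, post$treatments)
  lo <- comparison[which.min(ord)]; hi <- comparison[which.max(ord)]
  direct <- unlist(post$d_split, use.names = FALSE)
  indirect <- d_draws(post, hi) - d_draws(post, lo)
  if (!identical(c(lo, hi), comparison)) {  # flip to requested orientation
    direct <- -direct; indirect <- -indirect
  }
  difference <- direct - indirect
  p <- 2 * min(mean(difference > 0), mean(difference < 0))
  summ <- function(v) {
    q <- unname(stats::quantile(v, c(0.5, 0.025, 0.975), type = 7))
    c(median = q[1], cri_low = q[2], cri_high = q[3])
  }
  structure(list(comparison = comparison, direct = summ(direct),
                 indirect = summ(indirect), difference = summ(difference),
                 p_value = p, n_direct_studies = length(direct_ids),
                 draws = list(direct = direct, indirect = indirect),
                 posterior = post),
            class = "node_split_result")
}

#' @export
print.node_split_result <- function(x, ...) {
  cat("Node split:", paste(x$comparison, collapse = " vs "), "\n")
  m <- rbind(direct = x$direct, indirect = x$indirect,
             difference = x$difference)
  print(round(m, 3))
  cat("two-sided p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Node-splitting for every splittable comparison of an endpoint
#'
#' Comparisons without both direct evidence and an indirect path are
#' skipped with a message.
#'
#' @inheritParams node_split
#' @return Data frame with one row per splittable comparison: `ref`,
#'   `alt`, `direct`, `indirect`, `diff`, `p`.
#' @export
node_split_all <- function(arms, endpoint, config = nma_config()) {
  net <- build_network(arms, endpoint)
  dc <- direct_comparisons(net)
  rows <- list()
  for (i in seq_len(nrow(dc))) {
    cmp <- c(dc$t1[i], dc$t2[i])
    res <- tryCatch(node_split(arms, endpoint, cmp, config),
                    error = function(e) {
                      message("skipping ", paste(cmp, collapse = " vs "),
                              ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ref = cmp[1], alt = cmp[2],
      direct = res$direct[["median"]], indirect = res$indirect[["median"]],
      diff = res$difference[["median"]], p = res$p_value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(ref = character(), alt = character(),
                      direct = numeric(), indirect = numeric(),
                      diff = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
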