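#' Rank probability matrix from posterior draws
#'
#' For every posterior draw the treatments are ranked with the better
#' direction first (rank 1 = best); ties are broken by canonical treatment
#' order. Entry `[k, j]` is the fraction of draws in which treatment `k`
#' attains rank `j`.
#'
#' @param post An `nma_posterior`.
#' @param direction `"higher_is_better"` or `"lower_is_better"`; defaults
#'   to the endpoint's registered direction.
#' @return K x K matrix of rank probabilities (rows: treatments, columns:
#'   ranks), doubly stochastic.
#' @export
rank_samples <- function(post, direction = NULL) {
  if (is.null(direction)) direction <- post$endpoint$direction
  direction <- match.arg(direction, c("higher_is_better", "lower_is_better"))
  tr <- post$treatments
  K <- length(tr)
  draws <- do.call(rbind, post$d)[, tr, drop = FALSE]
  sgn <- if (direction == "higher_is_better") -1 else 1
  P <- matrix(0, K, K, dimnames = list(tr, paste0("rank", seq_len(K))))
  idx <- seq_len(K)
  for (r in seq_len(nrow(draws))) {
    o <- order(sgn * draws[r, ], idx)  # ties by treatment order
    rk <- integer(K); rk[o] <- idx
    P[cbind(idx, rk)] <- P[cbind(idx, rk)] + 1
  }
  P / nrow(draws)
}

#' SUCRA scores from a rank probability matrix
#'
#' The surface under the cumulative ranking curve:
#' \eqn{SUCRA_k = \sum_{j=1}^{K-1} cum_k(j) / (K-1)} with
#' \eqn{cum_k(j) = \sum_{h \le j} P[k, h]}. Equals the probability of being
#' best when K = 2; 1 means certainly best, 0 certainly worst; the mean
#' over treatments is always 0.5.
#'
#' @param ranks A rank probability matrix (rows sum to 1).
#' @return Named numeric vector of SUCRA scores in `[0, 1]`.
#' @export
sucra <- function(ranks) {
  stopifnot(is.matrix(ranks), nrow(ranks) == ncol(ranks), nrow(ranks) >= 2)
  if (any(abs(rowSums(ranks) - 1) > 1e-9) || any(ranks < -1e-12)) {
    stop("rank matrix rows must be probabilities summing to 1",
         call. = FALSE)
  }
  K <- ncol(ranks)
  cum <- t(apply(ranks, 1, cumsum))
  s <- rowSums(cum[, seq_len(K - 1), drop = FALSE]) / (K - 1)
  pmin(pmax(s, 0), 1)
}

#' Cluster treatments on two SUCRA coordinates
#'
#' k-means on the points (SUCRA on endpoint x, SUCRA on endpoint y) with 50
#' seeded restarts. With `k = "auto"` the number of clusters is chosen in
#' {2, 3, 4} (bounded by K - 1) to maximise the mean silhouette width.
#'
#' @param x,y Named SUCRA vectors over the same treatments.
#' @param k Number of clusters, or `"auto"`.
#' @param seed Seed for the restarts.
#' @return Object of class `cluster_assignment`: data frame `assignment`
#'   (`treatment`, `sucra_x`, `sucra_y`, `cluster`), chosen `k`, mean
#'   `silhouette`, and a `degenerate` flag when all points coincide.
#' @export
cluster_treatments <- function(x, y, k = "auto", seed = 1) {
  if (!setequal(names(x), names(y))) {
    stop("treatment sets of the two SUCRA vectors differ", call. = FALSE)
  }
  y <- y[names(x)]
  pts <- cbind(sucra_x = unname(x), sucra_y = unname(y))
  K <- nrow(pts)
  if (identical(k, "auto") && K < 3) stop("auto-k needs K >= 3", call. = FALSE)
  n_distinct <- nrow(unique(pts))
  if (n_distinct < 2) {
    assignment <- data.frame(treatment = names(x), sucra_x = pts[, 1],
                             sucra_y = pts[, 2], cluster = 1L,
                             stringsAsFactors = FALSE)
    warning("all treatments have identical SUCRA coordinates; ",
            "single degenerate cluster", call. = FALSE)
    return(structure(list(assignment = assignment, k = 2L, silhouette = 0,
                          degenerate = TRUE), class = "cluster_assignment"))
  }
  fit_k <- function(kk) {
    set.seed(seed)
    km <- stats::kmeans(pts, centers = kk, nstart = 50)
    sil <- cluster::silhouette(km$cluster, stats::dist(pts))
    list(km = km, sil = mean(sil[, "sil_width"]))
  }
  if (identical(k, "auto")) {
    ks <- 2:min(4, K - 1, n_distinct)
    fits <- lapply(ks, fit_k)
    best <- which.max(vapply(fits, `[[`, 1.0, "sil"))
    k <- ks[best]; fit <- fits[[best]]
  } else {
    stopifnot(k >= 2, k < K)
    fit <- fit_k(k)
  }
  assignment <- data.frame(treatment = names(x), sucra_x = pts[, 1],
                           sucra_y = pts[, 2], cluster = fit$km$cluster,
                           stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, k = as.integer(k),
                 silhouette = fit$sil, degenerate = FALSE),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Treatment clusters (k =", x$k,
      sprintf(", mean silhouette %.3f%s)\n", x$silhouette,
              if (x$degenerate) ", degenerate" else ""))
  print(x$assignment)
  invisible(x)
}
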