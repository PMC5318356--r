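# Frequentist design-level backbone of the net-heat construction:
# per-design contrasts, weighted least squares on the basic parameters,
# the Q decomposition into within-design heterogeneity and between-design
# inconsistency, and the net-heat contribution/delta matrices.

design_key <- function(treats) paste(treats, collapse = "-")

# contrasts of one study versus its baseline arm, with the full covariance
# of contrasts sharing the baseline arm
study_contrast <- function(s, binary, correction = 0.5) {
  s <- s[order(treatment_order(s$treatment)), , drop = FALSE]
  stratum <- s$design[1]
  a <- nrow(s)
  if (binary) {
    ev <- s$events; ne <- s$n - s$events
    if (any(c(ev, ne) == 0)) {
      ev <- ev + correction; ne <- ne + correction
    }
    y <- log(ev[-1] / ne[-1]) - log(ev[1] / ne[1])
    v0 <- 1 / ev[1] + 1 / ne[1]
    V <- matrix(v0, a - 1, a - 1)
    diag(V) <- v0 + 1 / ev[-1] + 1 / ne[-1]
  } else {
    y <- s$mean[-1] - s$mean[1]
    v0 <- s$sd[1]^2 / s$n[1]
    V <- matrix(v0, a - 1, a - 1)
    diag(V) <- v0 + s$sd[-1]^2 / s$n[-1]
  }
  list(treats = s$treatment, y = y, W = solve(V), stratum = stratum)
}

#' Design-level contrasts for one endpoint
#'
#' A design is a distinct set of treatments compared within a study.
#' Studies are reduced to contrasts versus their baseline arm (with the
#' covariance adjustment for multi-arm trials) and pooled within design by
#' generalised least squares, retaining the within-design heterogeneity
#' statistic.
#'
#' @param arms Arm-record data frame.
#' @param endpoint Endpoint code or name.
#' @param correction Continuity constant for sparse binary tables.
#' @return Object of class `design_contrasts`: `treatments`, `ref`,
#'   `scale`, and `designs` (per design: `design` key, `treats`, pooled
#'   `y` and weight matrix `W`, `Q_het`, per-study contrasts).
#' @export
design_contrasts <- function(arms, endpoint, correction = 0.5) {
  ep <- as_endpoint(endpoint)
  net <- build_network(arms, endpoint)
  binary <- ep$scale == "binary_OR"
  per_study <- lapply(net$studies, study_contrast, binary = binary,
                      correction = correction)
  # a design is a distinct treatment set within a study-design stratum,
  # so parallel and crossover trials of the same comparison stay separate
  keys <- vapply(per_study, function(x) {
    k <- design_key(x$treats)
    if (x$stratum == "crossover") paste0(k, " (crossover)") else k
  }, "")
  designs <- lapply(split(per_study, keys), function(group) {
    treats <- group[[1]]$treats
    Wsum <- Reduce(`+`, lapply(group, `[[`, "W"))
    wy <- Reduce(`+`, lapply(group, function(g) g$W %*% g$y))
    yhat <- drop(solve(Wsum, wy))
    Qhet <- sum(vapply(group, function(g) {
      r <- g$y - yhat
      drop(t(r) %*% g$W %*% r)
    }, 1.0))
    list(design = NA_character_, treats = treats, y = yhat, W = Wsum,
         Q_het = Qhet,
         studies = lapply(group, function(g) g[c("y", "W")]))
  })
  for (i in seq_along(designs)) designs[[i]]$design <- names(designs)[i]
  designs <- designs[order(names(designs))]
  structure(list(treatments = net$treatments, ref = net$treatments[1],
                 scale = ep$scale, designs = unname(designs)),
            class = "design_contrasts")
}

# accept either a design_contrasts object or a bare list of designs
as_designs <- function(contrasts) {
  if (inherits(contrasts, "design_contrasts")) return(contrasts$designs)
  stopifnot(is.list(contrasts), length(contrasts) >= 1)
  out <- lapply(contrasts, function(d) {
    stopifnot(!is.null(d$treats), !is.null(d$y))
    if (is.null(d$W)) d$W <- diag(1, nrow = length(d$y))
    if (is.null(d$design)) d$design <- design_key(d$treats)
    d
  })
  keys <- make.unique(vapply(out, `[[`, "", "design"))
  for (i in seq_along(out)) out[[i]]$design <- keys[i]
  out
}

designs_treatments <- function(designs) {
  tr <- unique(unlist(lapply(designs, `[[`, "treats")))
  tr[treatment_order(tr)]
}

# rows of the basic-parameter design matrix for one design
design_X <- function(d, params, ref) {
  t1 <- d$treats[1]
  do.call(rbind, lapply(d$treats[-1], function(t2) {
    row <- stats::setNames(numeric(length(params)), params)
    if (t2 != ref) row[t2] <- 1
    if (t1 != ref) row[t1] <- -1
    row
  }))
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 1)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

block_diag <- function(mats) {
  sizes <- vapply(mats, nrow, 1L)
  M <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    M[idx, idx] <- m
    at <- at + nrow(m)
  }
  M
}

#' Weighted least-squares network fit of design-level contrasts
#'
#' Regresses the pooled design contrasts on the basic-parameter design
#' matrix X with the design weight matrices:
#' `theta = (X'WX)^-1 X'W y`, hat matrix `H = X (X'WX)^-1 X'W`.
#'
#' @param contrasts A `design_contrasts` object, or a bare list of designs
#'   (each a list with `treats`, `y`, optional `W`).
#' @param drop_designs Optional design keys to exclude from the fit (used
#'   when detaching designs); excluded rows are still projected by the
#'   returned coefficients.
#' @return List with `theta` (named basic parameters), `H`, `X`, `W`, `y`,
#'   `fitted`, `residuals`, `row_design` (design key per row),
#'   `Q_inc_by_design` and `Q_inc`.
#' @export
wls_network_fit <- function(contrasts, drop_designs = NULL) {
  designs <- as_designs(contrasts)
  treatments <- designs_treatments(designs)
  ref <- if (inherits(contrasts, "design_contrasts")) contrasts$ref else
    treatments[1]
  params <- setdiff(treatments, ref)
  keys <- vapply(designs, `[[`, "", "design")

  X <- do.call(rbind, lapply(designs, design_X, params = params, ref = ref))
  y <- unlist(lapply(designs, `[[`, "y"), use.names = FALSE)
  W <- block_diag(lapply(designs, function(d) as.matrix(d$W)))
  row_design <- rep(keys, vapply(designs, function(d) length(d$y), 1L))

  fit_rows <- !row_design %in% drop_designs
  Xf <- X[fit_rows, , drop = FALSE]
  Wf <- W[fit_rows, fit_rows, drop = FALSE]
  yf <- y[fit_rows]
  XtWX <- t(Xf) %*% Wf %*% Xf
  rank <- qr(XtWX)$rank
  if (is.null(drop_designs) && rank < length(params)) {
    g <- igraph::graph_from_data_frame(do.call(rbind, lapply(designs,
      function(d) cbind(d$treats[1], d$treats[-1]))), directed = FALSE,
      vertices = treatments)
    comp <- igraph::components(g)
    groups <- split(names(comp$membership), comp$membership)
    stop("design matrix is rank deficient; disconnected components: ",
         paste(vapply(groups, function(x)
           paste0("{", paste(x, collapse = ","), "}"), ""),
           collapse = " "), call. = FALSE)
  }
  XtWX_inv <- if (rank < length(params)) pinv(XtWX) else solve(XtWX)
  theta <- drop(XtWX_inv %*% t(Xf) %*% Wf %*% yf)
  names(theta) <- params
  H <- Xf %*% XtWX_inv %*% t(Xf) %*% Wf
  fitted <- drop(X %*% theta)
  resid <- y - fitted
  q_by <- vapply(unique(row_design), function(k) {
    i <- row_design == k
    drop(t(resid[i]) %*% W[i, i, drop = FALSE] %*% resid[i])
  }, 1.0)
  fitted_keys <- setdiff(unique(row_design), drop_designs)
  list(theta = theta, H = H, X = X, W = W, y = y, fitted = fitted,
       residuals = resid, row_design = row_design,
       fit_rows = fit_rows, treatments = treatments, ref = ref,
       Q_inc_by_design = q_by, Q_inc = sum(q_by[fitted_keys]))
}

#' Decomposition of total heterogeneity into within- and between-design parts
#'
#' `Q_total` is the weighted sum of squared deviations of every study
#' contrast from the network estimates; `Q_het` is the within-design
#' heterogeneity; `Q_inc = Q_total - Q_het` measures design-by-treatment
#' inconsistency. The decomposition is exact.
#'
#' @param contrasts A `design_contrasts` object (or bare design list, in
#'   which case each design counts as a single study and `Q_het = 0`).
#' @return List with `Q_total`, `Q_het`, `Q_inc`.
#' @export
q_decomposition <- function(contrasts) {
  designs <- as_designs(contrasts)
  fit <- wls_network_fit(contrasts)
  Q_inc <- sum(fit$Q_inc_by_design[unique(fit$row_design)])
  Q_het <- sum(vapply(designs, function(d) {
    if (is.null(d$Q_het)) 0 else d$Q_het
  }, 1.0))
  # Q_total from its own (study-level) definition when study contrasts are
  # available; the Q_total = Q_het + Q_inc identity then holds because the
  # within-design pooling is the weighted projection
  if (all(vapply(designs, function(d) !is.null(d$studies), TRUE))) {
    at <- 0L
    Q_total <- 0
    for (d in designs) {
      idx <- at + seq_len(length(d$y))
      fit_d <- fit$fitted[idx]
      for (s in d$studies) {
        r <- s$y - fit_d
        Q_total <- Q_total + drop(t(r) %*% s$W %*% r)
      }
      at <- at + length(d$y)
    }
  } else {
    Q_total <- Q_het + Q_inc
  }
  list(Q_total = Q_total, Q_het = Q_het, Q_inc = Q_inc)
}

#' Net-heat matrices
#'
#' `contribution[d, d']` is the fraction of design d's network estimate
#' contributed by design d' (normalised absolute hat-matrix entries).
#' `delta_inconsistency[d, d']` is the change in design d's inconsistency
#' contribution after detaching design d' (refitting with d' excluded from
#' the consistency fit): positive values mean inconsistency decreases when
#' d' is detached (warm colours), negative an increase (blue).
#'
#' @param contrasts A `design_contrasts` object or bare design list with
#'   at least two designs.
#' @return Object of class `net_heat_matrix`: `contribution`,
#'   `delta_inconsistency` (designs x designs), `Q_total`, `Q_het`, `Q_inc`.
#' @export
net_heat <- function(contrasts) {
  designs <- as_designs(contrasts)
  keys <- vapply(designs, `[[`, "", "design")
  if (length(designs) < 2) stop("net heat needs >= 2 designs", call. = FALSE)
  fit <- wls_network_fit(contrasts)
  qd <- q_decomposition(contrasts)

  D <- length(keys)
  contribution <- matrix(0, D, D, dimnames = list(keys, keys))
  for (a in seq_len(D)) {
    ra <- which(fit$row_design == keys[a])
    for (b in seq_len(D)) {
      rb <- which(fit$row_design == keys[b])
      contribution[a, b] <- sum(abs(fit$H[ra, rb]))
    }
    contribution[a, ] <- contribution[a, ] / sum(contribution[a, ])
  }

  q_full <- fit$Q_inc_by_design[keys]
  delta <- matrix(0, D, D, dimnames = list(keys, keys))
  for (b in seq_len(D)) {
    refit <- wls_network_fit(contrasts, drop_designs = keys[b])
    q_after <- refit$Q_inc_by_design[keys]
    q_after[keys[b]] <- 0  # detached design fits its own parameter exactly
    delta[, b] <- q_full - q_after
  }

  structure(list(contribution = contribution,
                 delta_inconsistency = delta,
                 Q_total = qd$Q_total, Q_het = qd$Q_het, Q_inc = qd$Q_inc,
                 designs = keys),
            class = "net_heat_matrix")
}

#' @export
print.net_heat_matrix <- function(x, ...) {
  cat("Net heat:", length(x$designs), "designs; Q_total =",
      format(x$Q_total, digits = 4), "= Q_het", format(x$Q_het, digits = 4),
      "+ Q_inc", format(x$Q_inc, digits = 4), "\n")
  cat("contribution matrix:\n")
  print(round(x$contribution, 3))
  invisible(x)
}
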