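#' Run the full evidence-synthesis pipeline
#'
#' For each requested endpoint: build the evidence network, pairwise
#' random-effects meta-analysis, Bayesian NMA, league table, rank
#' probabilities and SUCRA, node-splitting of every splittable comparison,
#' net-heat matrices and funnel data; finally a cluster analysis of the
#' treatments on the SUCRA scores of a chosen endpoint pair. All artifacts
#' are written as CSV under `output_dir` and listed in the returned
#' manifest. Deterministic given the seed.
#'
#' @param arms Arm-record data frame (or path to an arms CSV).
#' @param endpoints Endpoint codes/names to analyse; defaults to all
#'   endpoints present in `arms`.
#' @param output_dir Output directory (created if missing).
#' @param config An [nma_config()] used for every endpoint (per-endpoint
#'   seeds are derived from it).
#' @param correction Continuity constant for sparse binary tables.
#' @param crossover_rho Optional crossover sensitivity correlation passed
#'   to [pairwise_table()].
#' @param cluster_endpoints Length-2 vector naming the endpoint pair for
#'   the cluster analysis (both must be in `endpoints`), or `NULL` to skip.
#' @param run_nodesplit,run_netheat Toggles for the slower diagnostics.
#' @return Object of class `run_report`: per-endpoint artifact `manifest`,
#'   convergence summaries and collected `warnings`.
#' @export
run_pipeline <- function(arms, endpoints = NULL, output_dir = tempfile("mignet_"),
                         config = nma_config(), correction = 0.5,
                         crossover_rho = NULL,
                         cluster_endpoints = c("reduction50", "withdrawal_aes"),
                         run_nodesplit = TRUE, run_netheat = TRUE) {
  if (is.character(arms) && length(arms) == 1L) arms <- read_arm_table(arms)
  validate_arms(arms)
  present <- sort(unique(arms$endpoint))
  if (is.null(endpoints)) endpoints <- present
  eps <- lapply(endpoints, as_endpoint)
  missing_eps <- vapply(eps, function(e) !e$code %in% present, TRUE)
  if (any(missing_eps)) {
    stop("endpoint(s) absent from input: ",
         paste(vapply(eps[missing_eps], `[[`, "", "name"), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cluster_endpoints)) {
    cl_eps <- vapply(lapply(cluster_endpoints, as_endpoint), `[[`, 1L, "code")
    if (!all(cl_eps %in% vapply(eps, `[[`, 1L, "code"))) {
      stop("cluster endpoints must be among the analysed endpoints",
           call. = FALSE)
    }
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(); convergence_all <- list(); warnings <- character()
  sucra_store <- list()
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }

  for (j in seq_along(eps)) {
    ep <- eps[[j]]
    files <- character()
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s/%s] %s", ep$name, what, conditionMessage(e)),
             call. = FALSE)
      })
    }
    pw <- stage("pairwise", wcollect(
      pairwise_table(arms, ep$code, correction, crossover_rho)))
    files["pairwise"] <- emit(pw, sprintf("pairwise_%s.csv", ep$name))

    cfg <- config
    cfg$seed <- config$seed + 100L * j
    post <- stage("nma", wcollect(fit_nma(arms, ep$code, cfg)))
    lg <- stage("league", league_table(post))
    files["league"] <- emit(lg$long, sprintf("league_%s.csv", ep$name))
    json_path <- file.path(output_dir, sprintf("league_%s.json", ep$name))
    jsonlite::write_json(lg$long, json_path, auto_unbox = TRUE, digits = NA)
    files["league_json"] <- json_path
    convergence_all[[ep$name]] <- post$convergence

    P <- stage("rank", rank_samples(post))
    rk <- data.frame(treatment = rep(rownames(P), ncol(P)),
                     rank = rep(seq_len(ncol(P)), each = nrow(P)),
                     probability = as.vector(P), stringsAsFactors = FALSE)
    files["rankogram"] <- emit(rk, sprintf("rankogram_%s.csv", ep$name))
    sc <- stage("sucra", sucra(P))
    sucra_store[[as.character(ep$code)]] <- sc
    files["sucra"] <- emit(
      data.frame(treatment = names(sc), sucra = unname(sc)),
      sprintf("sucra_%s.csv", ep$name))

    if (run_nodesplit) {
      ns <- stage("nodesplit", wcollect(node_split_all(arms, ep$code, cfg)))
      files["nodesplit"] <- emit(ns, sprintf("nodesplit_%s.csv", ep$name))
    }
    if (run_netheat) {
      dcx <- stage("netheat", wcollect(design_contrasts(arms, ep$code,
                                                        correction)))
      if (length(dcx$designs) >= 2) {
        nh <- stage("netheat", net_heat(dcx))
        long <- expand.grid(row = nh$designs, col = nh$designs,
                            stringsAsFactors = FALSE)
        long$contribution <- as.vector(nh$contribution)
        long$delta_inconsistency <- as.vector(nh$delta_inconsistency)
        long$Q_total <- nh$Q_total; long$Q_het <- nh$Q_het
        long$Q_inc <- nh$Q_inc
        files["netheat"] <- emit(long, sprintf("netheat_%s.csv", ep$name))
      }
    }
    eff <- stage("funnel", wcollect(endpoint_effects(arms, ep$code,
                                                     correction)))
    if (length(eff)) {
      fd <- stage("funnel", funnel_data(eff))
      files["funnel"] <- emit(fd$data, sprintf("funnel_%s.csv", ep$name))
    }
    manifest[[ep$name]] <- files
  }

  if (!is.null(cluster_endpoints)) {
    cl_eps <- vapply(lapply(cluster_endpoints, as_endpoint), `[[`, 1L, "code")
    sx <- sucra_store[[as.character(cl_eps[1])]]
    sy <- sucra_store[[as.character(cl_eps[2])]]
    common <- intersect(names(sx), names(sy))
    cl <- wcollect(cluster_treatments(sx[common], sy[common],
                                      seed = config$seed))
    manifest[["clusters"]] <- c(clusters = emit(
      cl$assignment, sprintf("clusters_%s_%s.csv",
                             as_endpoint(cl_eps[1])$name,
                             as_endpoint(cl_eps[2])$name)))
  }

  structure(list(manifest = manifest, convergence = convergence_all,
                 warnings = warnings, output_dir = output_dir,
                 seed = config$seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") ->", x$output_dir, "\n")
  for (ep in names(x$manifest)) {
    cat(" ", ep, ":", length(x$manifest[[ep]]), "artifact(s)\n")
  }
  if (length(x$warnings)) cat(length(x$warnings), "warning(s) collected\n")
  invisible(x)
}
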