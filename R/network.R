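#' Build an evidence network for one endpoint
#'
#' Treatments become nodes and studies become edges for the chosen endpoint.
#' Studies that report the endpoint in only one arm cannot contribute a
#' comparison and are dropped with a warning. A disconnected network is an
#' error: treatments that cannot be placed in a closed network with the rest
#' cannot be compared, directly or indirectly.
#'
#' @param arms Arm-record data frame (see [read_arm_table()]).
#' @param endpoint Endpoint code or name.
#' @return An object of class `evidence_network`: a list with the resolved
#'   `endpoint`, the `treatments` present (canonical order), `studies` (arm
#'   records split by study), and `edges` (one row per direct comparison with
#'   its study count).
#' @export
build_network <- function(arms, endpoint) {
  ep <- as_endpoint(endpoint)
  validate_arms(arms)
  sub <- arms[arms$endpoint == ep$code, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no study measures endpoint ", ep$name,
                            call. = FALSE)
  keep <- vapply(split(sub, sub$study_id),
                 function(s) length(unique(s$treatment)) >= 2L, TRUE)
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warning("dropping single-arm stud",
            if (length(dropped) > 1) "ies: " else "y: ",
            paste(dropped, collapse = ", "),
            " for endpoint ", ep$name, call. = FALSE)
    sub <- sub[!sub$study_id %in% dropped, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop("no study compares >= 2 treatments on endpoint ",
                            ep$name, call. = FALSE)
  treatments <- unique(sub$treatment)
  treatments <- treatments[treatment_order(treatments)]
  studies <- split(sub, sub$study_id)

  pair_rows <- do.call(rbind, lapply(names(studies), function(id) {
    tr <- sort(unique(studies[[id]]$treatment))
    cmb <- utils::combn(tr, 2)
    data.frame(t1 = cmb[1, ], t2 = cmb[2, ], study_id = id,
               stringsAsFactors = FALSE)
  }))
  # orient each pair in canonical treatment order
  ord1 <- match(pair_rows$t1, treatments)
  ord2 <- match(pair_rows$t2, treatments)
  swap <- ord1 > ord2
  tmp <- pair_rows$t1[swap]
  pair_rows$t1[swap] <- pair_rows$t2[swap]
  pair_rows$t2[swap] <- tmp
  key <- paste(pair_rows$t1, pair_rows$t2, sep = " vs ")
  edges <- do.call(rbind, lapply(split(pair_rows, key), function(g) {
    data.frame(t1 = g$t1[1], t2 = g$t2[1], k = nrow(g),
               studies = I(list(sort(unique(g$study_id)))),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[order(match(edges$t1, treatments),
                       match(edges$t2, treatments)), , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges[, c("t1", "t2")],
                                     directed = FALSE,
                                     vertices = treatments)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    groups <- split(names(comp$membership), comp$membership)
    stop("network for endpoint ", ep$name, " is not connected; components: ",
         paste(vapply(groups, function(x) paste0("{", paste(x, collapse = ","), "}"),
                      ""), collapse = " "),
         call. = FALSE)
  }
  structure(list(endpoint = ep, treatments = treatments,
                 studies = studies, edges = edges),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network:", x$endpoint$name,
      sprintf("(%s)\n", x$endpoint$scale))
  cat(" ", length(x$treatments), "treatments:",
      paste(x$treatments, collapse = ", "), "\n")
  cat(" ", length(x$studies), "studies,", nrow(x$edges),
      "direct comparisons\n")
  invisible(x)
}

#' Enumerate direct comparisons
#'
#' @param network An `evidence_network`.
#' @return Data frame with one row per unordered treatment pair compared
#'   head-to-head in at least one study (`t1`, `t2`, `k` studies).
#' @export
direct_comparisons <- function(network) {
  stopifnot(inherits(network, "evidence_network"))
  network$edges[, c("t1", "t2", "k")]
}
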