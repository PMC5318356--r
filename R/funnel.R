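#' Comparison-adjusted funnel data and Egger regression
#'
#' Centers every study effect on the pooled direct effect of its own
#' comparison (so studies of different comparisons share a common null) and
#' quantifies funnel asymmetry with the Egger regression of the
#' standardised centered effect on precision:
#' `centered/se ~ intercept + slope * (1/se)`; a non-zero intercept
#' indicates small-study effects.
#'
#' @param effects List of study effect estimates (see
#'   [study_effect_binary()], [study_effect_continuous()]), typically all
#'   studies of one endpoint.
#' @param pooled Optional list of pooled results keyed by comparison; when
#'   `NULL` each comparison is pooled with [pool_dl()] from `effects`.
#' @return List with `data` (data frame `study_id`, `ref`, `alt`,
#'   `centered_effect`, `se`) and `egger` (`intercept`, `se`, `p`), or
#'   `egger = NULL` with fewer than 3 studies.
#' @export
funnel_data <- function(effects, pooled = NULL) {
  stopifnot(length(effects) >= 1)
  key <- vapply(effects, function(e) paste(e$comparison, collapse = " vs "),
                "")
  if (is.null(pooled)) {
    pooled <- lapply(split(effects, key), pool_dl)
  } else {
    nm <- vapply(pooled, function(p) paste(p$comparison, collapse = " vs "),
                 "")
    names(pooled) <- nm
  }
  rows <- lapply(seq_along(effects), function(i) {
    e <- effects[[i]]
    p <- pooled[[key[i]]]
    if (is.null(p)) stop("no pooled effect for comparison ", key[i],
                         call. = FALSE)
    data.frame(study_id = e$study_id, ref = e$comparison[1],
               alt = e$comparison[2],
               centered_effect = e$effect - p$pooled, se = e$se,
               stringsAsFactors = FALSE)
  })
  data <- do.call(rbind, rows)
  egger <- NULL
  if (nrow(data) >= 3) {
    z <- data$centered_effect / data$se
    prec <- 1 / data$se
    fit <- stats::lm(z ~ prec)
    sm <- summary(fit)$coefficients
    egger <- list(intercept = unname(sm["(Intercept)", "Estimate"]),
                  se = unname(sm["(Intercept)", "Std. Error"]),
                  p = unname(sm["(Intercept)", "Pr(>|t|)"]))
  }
  list(data = data, egger = egger)
}
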