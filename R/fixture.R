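#' Study metadata of the migraine prophylaxis evidence base
#'
#' A transcription of the 32 randomized trials (parallel and crossover) of
#' seven interventions that form the packaged evidence base: study design,
#' blinding, the two interventions compared, total randomized size, and the
#' set of endpoints each study measured. Study-level outcome data are not
#' part of the fixture (they were never published in aggregate); the
#' simulator ([make_paper_like_scenario()]) generates outcomes on this
#' geometry instead.
#'
#' @return Data frame with one row per study: `study_id`, `year`, `design`,
#'   `blinding`, `treat1`, `treat2`, `size`, `male_pct`, `follow_up`
#'   (as printed, units vary), `endpoints` (list column of integer codes).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_fixture.csv", package = "mignet")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$year <- as.integer(df$year)
  df$size <- as.integer(df$size)
  df$male_pct <- as.integer(df$male_pct)
  df$treat1 <- normalize_treatments(df$treat1)
  df$treat2 <- normalize_treatments(df$treat2)
  df$endpoints <- lapply(strsplit(df$endpoints, ";", fixed = TRUE),
                         as.integer)
  stopifnot(all(df$size > 0))
  df
}

#' Summary counts of the packaged evidence base
#'
#' @param fixture A fixture data frame, by default [table1_fixture()].
#' @return List with `n_studies`, `total_size`, `n_crossover`, `pairs`
#'   (data frame of unique direct comparisons) and `n_pairs`.
#' @export
fixture_summary <- function(fixture = table1_fixture()) {
  a <- pmin(fixture$treat1, fixture$treat2)
  b <- pmax(fixture$treat1, fixture$treat2)
  pairs <- unique(data.frame(t1 = a, t2 = b, stringsAsFactors = FALSE))
  pairs <- pairs[order(match(pairs$t1, mignet_treatments()$name),
                       match(pairs$t2, mignet_treatments()$name)), ]
  rownames(pairs) <- NULL
  list(
    n_studies = nrow(fixture),
    total_size = sum(fixture$size),
    n_crossover = sum(fixture$design == "crossover"),
    pairs = pairs,
    n_pairs = nrow(pairs)
  )
}

#' Print the fixture summary
#'
#' Convenience wrapper that prints the headline counts of the packaged
#' evidence base: number of studies, total randomized subjects, crossover
#' trials and direct comparisons.
#'
#' @return The [fixture_summary()] list, invisibly.
#' @export
summarize_fixture <- function() {
  s <- fixture_summary()
  cat(s$n_studies, "studies,", s$total_size, "subjects,",
      s$n_crossover, "crossover trials,", s$n_pairs, "direct comparisons\n")
  invisible(s)
}
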