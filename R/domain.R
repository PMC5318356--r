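#' Intervention registry
#'
#' The seven interventions of the migraine prophylaxis evidence base, with
#' their single-letter network labels. Placebo (code `"A"`) is the reference
#' treatment of every network.
#'
#' @return A data frame with columns `code` (letters A-G) and `name`
#'   (lower-case intervention name).
#' @export
#' @examples
#' mignet_treatments()
mignet_treatments <- function() {
  data.frame(
    code = LETTERS[1:7],
    name = c("placebo", "topiramate", "propranolol", "gabapentin",
             "amitriptyline", "divalproex", "valproate"),
    stringsAsFactors = FALSE
  )
}

#' Endpoint registry
#'
#' The nine clinical endpoints: two continuous efficacy outcomes analysed as
#' raw mean differences (monthly migraine headache days, headache frequency),
#' one binary efficacy outcome (at least 50% reduction in attacks, where a
#' higher odds ratio is better), and six binary safety/tolerability outcomes
#' (adverse events, nausea, somnolence, dizziness, all-cause withdrawal,
#' withdrawal due to adverse events), all of which rank lower as better.
#'
#' @return A data frame with columns `code` (1-9), `name`, `scale`
#'   (`"continuous_MD"` or `"binary_OR"`) and `direction`
#'   (`"higher_is_better"` or `"lower_is_better"`).
#' @export
mignet_endpoints <- function() {
  data.frame(
    code = 1:9,
    name = c("migraine_headache_days", "headache_frequency", "reduction50",
             "all_adverse_events", "nausea", "somnolence", "dizziness",
             "withdrawal", "withdrawal_aes"),
    scale = c("continuous_MD", "continuous_MD", rep("binary_OR", 7)),
    direction = c("lower_is_better", "lower_is_better", "higher_is_better",
                  rep("lower_is_better", 6)),
    stringsAsFactors = FALSE
  )
}

#' Resolve an endpoint given its code or name
#'
#' @param x Integer code 1-9, or the canonical endpoint name.
#' @return One row of [mignet_endpoints()] as a list.
#' @export
as_endpoint <- function(x) {
  eps <- mignet_endpoints()
  if (is.numeric(x) || grepl("^[0-9]+$", as.character(x)[1])) {
    i <- match(as.integer(x), eps$code)
  } else {
    i <- match(tolower(as.character(x)), eps$name)
  }
  if (length(i) != 1L || is.na(i)) {
    stop("unknown endpoint: ", paste(x, collapse = ", "), call. = FALSE)
  }
  as.list(eps[i, ])
}

# Resolve treatment names (case-folded); unknown names are rejected so the
# seven-node universe stays fixed unless explicitly opened up.
normalize_treatments <- function(x, allow_new = FALSE) {
  tr <- mignet_treatments()
  x <- tolower(trimws(as.character(x)))
  unknown <- setdiff(unique(x), tr$name)
  if (length(unknown) && !allow_new) {
    stop("unknown treatment(s): ", paste(unknown, collapse = ", "),
         " (use allow_new_treatments = TRUE to accept)", call. = FALSE)
  }
  x
}

treatment_code <- function(name) {
  tr <- mignet_treatments()
  i <- match(tolower(name), tr$name)
  ifelse(is.na(i), toupper(substr(name, 1, 1)), tr$code[i])
}

# Canonical ordering of treatments: registry order first, novel names after.
treatment_order <- function(names) {
  tr <- mignet_treatments()
  i <- match(names, tr$name)
  order(ifelse(is.na(i), 100L + match(names, sort(unique(names))), i))
}
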