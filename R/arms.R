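ARM_COLUMNS <- c("study_id", "year", "design", "blinding", "endpoint",
                 "treatment", "n", "events", "mean", "sd", "follow_up_weeks")

#' Read an arm-level trial table
#'
#' Reads the long-format CSV contract used throughout the package: one row
#' per treatment arm per study per endpoint. Binary endpoints carry `events`;
#' continuous endpoints carry `mean` and `sd`; the unused cells are empty.
#'
#' @param path Path to a CSV file with the exact header
#'   `study_id,year,design,blinding,endpoint,treatment,n,events,mean,sd,follow_up_weeks`.
#' @param allow_new_treatments Accept treatment names outside the packaged
#'   seven-intervention registry (default `FALSE`).
#' @return A validated data frame of arm records, row order preserved, with
#'   `endpoint` resolved to its integer code and `treatment` case-folded.
#' @export
read_arm_table <- function(path, allow_new_treatments = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(ARM_COLUMNS, names(df))
  if (length(missing)) {
    stop("arm table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, ARM_COLUMNS]
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  out <- data.frame(
    study_id = df$study_id,
    year = as.integer(num(df$year)),
    design = tolower(df$design),
    blinding = tolower(df$blinding),
    endpoint = vapply(df$endpoint, function(e) as_endpoint(e)$code, 1L),
    treatment = normalize_treatments(df$treatment, allow_new_treatments),
    n = as.integer(num(df$n)),
    events = num(df$events),
    mean = num(df$mean),
    sd = num(df$sd),
    follow_up_weeks = num(df$follow_up_weeks),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_arms(out)
}

#' Write an arm-level trial table
#'
#' Inverse of [read_arm_table()]: writes the CSV contract with empty cells
#' for inapplicable fields.
#'
#' @param arms A validated arm-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_arm_table <- function(arms, path) {
  arms <- validate_arms(arms)
  out <- arms
  for (col in c("events", "mean", "sd", "follow_up_weeks")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], trim = TRUE, digits = 15))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate arm records
#'
#' Enforces the arm-record invariants: counts within range, positive standard
#' deviations, and exactly one of events / (mean, sd) populated, matching the
#' endpoint scale.
#'
#' @param arms A data frame with the arm-table columns.
#' @return `arms`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending study.
#' @export
validate_arms <- function(arms) {
  stopifnot(is.data.frame(arms))
  missing <- setdiff(ARM_COLUMNS, names(arms))
  if (length(missing)) {
    stop("arm table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eps <- mignet_endpoints()
  bad <- function(cond, msg) {
    if (any(cond)) {
      stop(msg, " (study ", paste(unique(arms$study_id[cond]), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  bad(is.na(arms$n) | arms$n < 1, "n must be >= 1")
  bad(!arms$design %in% c("parallel", "crossover"),
      "design must be parallel or crossover")
  bad(!arms$blinding %in% c("single", "double"),
      "blinding must be single or double")
  scale <- eps$scale[match(arms$endpoint, eps$code)]
  binary <- scale == "binary_OR"
  bad(binary & is.na(arms$events), "binary endpoint requires events")
  bad(binary & (!is.na(arms$mean) | !is.na(arms$sd)),
      "binary endpoint must not carry mean/sd")
  bad(!binary & (is.na(arms$mean) | is.na(arms$sd)),
      "continuous endpoint requires mean and sd")
  bad(!binary & !is.na(arms$events),
      "continuous endpoint must not carry events")
  bad(binary & (arms$events < 0 | arms$events > arms$n),
      "events must satisfy 0 <= events <= n")
  bad(!binary & arms$sd <= 0, "sd must be > 0")
  invisible(arms)
}
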