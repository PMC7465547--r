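#' Read a patient cohort from CSV
#'
#' The cohort schema is one row per patient with the columns of
#' [patient_record()] in any order; tri-state findings use the literal
#' tokens `present`/`absent`/`unknown`, unknown numerics are empty cells,
#' UTF-8 encoding. `read_cohort()` is the inverse of [write_cohort()].
#'
#' @param path CSV file path.
#' @param strict if `TRUE` (default) any invalid row rejects the whole
#'   file; if `FALSE` invalid rows are skipped and reported via the
#'   `"excluded"` attribute of the result (mirroring explicit exclusion
#'   accounting in retrospective reviews — exclusions are never silent).
#' @return A validated cohort data frame; in lenient mode with attribute
#'   `excluded`, a character vector of row-level exclusion messages.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[COHORT_COLUMNS]

  excluded_rows <- logical(nrow(raw))
  exclusion_msgs <- character(0)
  for (col in c("age", "hemoglobin")) {
    txt <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(txt))
    bad <- nzchar(txt) & is.na(num)
    if (any(bad)) {
      msgs <- sprintf("row %d: field '%s' is not numeric ('%s')",
                      which(bad), col, txt[bad])
      if (strict) stop("invalid cohort file:\n  ",
                       paste(msgs, collapse = "\n  "), call. = FALSE)
      excluded_rows <- excluded_rows | bad
      exclusion_msgs <- c(exclusion_msgs, msgs)
      num[bad] <- NA
    }
    raw[[col]] <- num
  }

  problems <- validate_cohort(raw, stop_on_error = FALSE)
  if (strict && length(problems))
    stop("invalid cohort file:\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "),
         call. = FALSE)
  if (length(problems)) {
    rows <- as.integer(sub("^row (\\d+):.*$", "\\1", problems))
    excluded_rows[rows] <- TRUE
    exclusion_msgs <- c(exclusion_msgs, problems)
  }

  cohort <- raw[!excluded_rows, , drop = FALSE]
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  attr(cohort, "excluded") <- exclusion_msgs
  cohort
}

#' Write a patient cohort to CSV
#'
#' Writes the schema-conformant CSV that [read_cohort()] reads back
#' exactly, including unknown tokens and empty numeric cells.
#'
#' @param cohort a valid cohort data frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[COHORT_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

recommendation_as_list <- function(x) {
  list(id = x$id, priority = x$priority,
       satisfied_criteria = as.list(x$satisfied_criteria),
       referral_window = x$referral_window, policy = x$policy,
       posttest_probability = if (is.na(x$posttest_probability)) NULL
         else x$posttest_probability,
       posttest_rule = if (is.na(x$posttest_probability)) NULL
         else "max of per-criterion median PPVs")
}

evaluation_as_list <- function(x) {
  list(n = x$n, counts = as.list(x$counts), positives = x$positives,
       n_confirmed = x$n_confirmed, sensitivity = x$sensitivity,
       sensitivity_percent = percent1(x$sensitivity),
       ci_low = x$ci_low, ci_high = x$ci_high, ci_method = x$ci_method,
       confidence = x$confidence, policy = x$policy,
       threshold = x$threshold, meets_threshold = x$meets_threshold,
       demoted = if (is.null(x$demoted)) NULL else x$demoted,
       warnings = as.list(x$warnings))
}

#' Render a recommendation or cohort evaluation as a report
#'
#' @param x a `crc_recommendation` or `cohort_evaluation`.
#' @param format `"text"` for an aligned human-readable report, `"json"`
#'   for a machine-readable document.
#' @return A character vector of report lines (`"text"`) or a JSON string
#'   (`"json"`).
#' @export
render_report <- function(x, format = c("text", "json")) {
  format <- match.arg(format)
  if (inherits(x, "crc_recommendation")) {
    if (format == "json")
      return(jsonlite::toJSON(recommendation_as_list(x),
                              auto_unbox = TRUE, digits = NA, null = "null"))
    lines <- c(
      sprintf("Patient %s  [policy: %s]", x$id, x$policy),
      sprintf("  Priority: %s", x$priority),
      sprintf("  Action:   %s", x$referral_window),
      if (length(x$satisfied_criteria))
        sprintf("  Criteria: %s", paste(x$satisfied_criteria,
                                        collapse = ", "))
      else "  Criteria: none",
      if (!is.na(x$posttest_probability))
        sprintf("  Post-test probability of CRC: %s%% (max of criterion median PPVs)",
                percent1(x$posttest_probability))
    )
    return(lines)
  }
  if (inherits(x, "cohort_evaluation")) {
    if (format == "json")
      return(jsonlite::toJSON(evaluation_as_list(x), auto_unbox = TRUE,
                              digits = NA, null = "null"))
    pct <- percent1(x$counts / x$n)
    lines <- c(
      sprintf("Cohort evaluation (n = %d, policy = %s)", x$n, x$policy),
      sprintf("  %-18s %5d (%s%%)", names(x$counts), x$counts, pct),
      sprintf("  Positive (immediate or urgent): %d of %d confirmed cases",
              x$positives, x$n_confirmed),
      sprintf("  Sensitivity: %s%% (%d%% CI %s to %s%%, %s)",
              percent1(x$sensitivity), round(100 * x$confidence),
              percent1(x$ci_low), percent1(x$ci_high),
              gsub("_", "-", x$ci_method)),
      sprintf("  Verdict: %s the pre-specified %s%% sensitivity threshold",
              if (x$meets_threshold) "meets" else "fails",
              percent1(x$threshold)),
      if (!is.null(x$demoted))
        sprintf("  Demotions vs BASE policy: %d", nrow(x$demoted)),
      if (length(x$warnings)) sprintf("  Note: %s", x$warnings)
    )
    return(lines)
  }
  stop("cannot render objects of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
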