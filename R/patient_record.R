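#' Construct a single patient record
#'
#' Builds a one-row cohort data frame holding demographics, hemoglobin and
#' the tri-state clinical findings used by the triage rules. Unknown
#' numerics are `NA`; tri-state findings take the tokens `"present"`,
#' `"absent"` or `"unknown"`.
#'
#' @param id opaque identifier (coerced to character).
#' @param age age in years (18--120) or `NA` for unknown.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param menstruating tri-state; meaningful only for females.
#' @param hemoglobin hemoglobin in g/L, in (0, 250], or `NA` for unknown.
#' @param ida clinician-asserted unexplained iron-deficiency anemia
#'   (tri-state).
#' @param palpable_mass,abnormal_imaging immediate-criterion findings
#'   (tri-state).
#' @param rectal_bleeding,dark_blood,blood_mixed_stool,perianal_symptoms,bowel_habit_change,weight_loss
#'   bleeding-related findings (tri-state). A record with dark blood or
#'   blood mixed with stool present must also have rectal bleeding present.
#' @param fdr_family_history first-degree relative with colorectal cancer
#'   (tri-state).
#' @param crc_confirmed outcome label for evaluation runs: `"yes"`, `"no"`
#'   or `"unknown"`.
#' @return A one-row data frame in the cohort schema.
#' @examples
#' patient_record(id = "p1", sex = "male", age = 72,
#'                rectal_bleeding = "present", perianal_symptoms = "absent")
#' @export
patient_record <- function(id = "p1", age = NA, sex = "unknown",
                           menstruating = "absent", hemoglobin = NA,
                           ida = "absent", palpable_mass = "absent",
                           abnormal_imaging = "absent",
                           rectal_bleeding = "absent", dark_blood = "absent",
                           blood_mixed_stool = "absent",
                           perianal_symptoms = "absent",
                           bowel_habit_change = "absent",
                           weight_loss = "absent",
                           fdr_family_history = "absent",
                           crc_confirmed = "unknown") {
  rec <- data.frame(
    id = as.character(id), age = as.numeric(age), sex = as.character(sex),
    menstruating = as.character(menstruating),
    hemoglobin = as.numeric(hemoglobin), ida = as.character(ida),
    palpable_mass = as.character(palpable_mass),
    abnormal_imaging = as.character(abnormal_imaging),
    rectal_bleeding = as.character(rectal_bleeding),
    dark_blood = as.character(dark_blood),
    blood_mixed_stool = as.character(blood_mixed_stool),
    perianal_symptoms = as.character(perianal_symptoms),
    bowel_habit_change = as.character(bowel_habit_change),
    weight_loss = as.character(weight_loss),
    fdr_family_history = as.character(fdr_family_history),
    crc_confirmed = as.character(crc_confirmed),
    stringsAsFactors = FALSE
  )
  validate_cohort(rec)
  rec
}

#' Validate a cohort data frame against the record invariants
#'
#' Checks the schema and the record-level invariants: tri-state and sex
#' tokens, hemoglobin in (0, 250] g/L when known, age in [18, 120] when
#' known, and the implication that dark blood or blood mixed with stool can
#' only be present when rectal bleeding is present.
#'
#' @param cohort a cohort data frame.
#' @param stop_on_error if `TRUE` (default) the first problem raises an
#'   error naming the field and row; if `FALSE` a character vector of
#'   row-level problem messages is returned (empty when valid).
#' @return Invisibly, the cohort (when valid); or the problem messages when
#'   `stop_on_error = FALSE`.
#' @export
validate_cohort <- function(cohort, stop_on_error = TRUE) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data frame", call. = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems,
                     sprintf("row %d: %s", which(rows), msg))
  }

  for (f in c(FINDING_FIELDS, "menstruating"))
    note(!(cohort[[f]] %in% TRISTATE_TOKENS),
         sprintf("field '%s' must be one of present/absent/unknown", f))
  note(!(cohort$sex %in% c("male", "female", "unknown")),
       "field 'sex' must be one of male/female/unknown")
  note(!(cohort$crc_confirmed %in% c("yes", "no", "unknown")),
       "field 'crc_confirmed' must be one of yes/no/unknown")
  note(!is.na(cohort$hemoglobin) &
         (cohort$hemoglobin <= 0 | cohort$hemoglobin > 250),
       "field 'hemoglobin' must lie in (0, 250] g/L when known")
  note(!is.na(cohort$age) & (cohort$age < 18 | cohort$age > 120),
       "field 'age' must lie in [18, 120] when known")
  note(cohort$dark_blood == "present" & cohort$rectal_bleeding != "present",
       "field 'dark_blood' present requires rectal_bleeding present")
  note(cohort$blood_mixed_stool == "present" &
         cohort$rectal_bleeding != "present",
       "field 'blood_mixed_stool' present requires rectal_bleeding present")

  if (!stop_on_error) return(problems)
  if (length(problems))
    stop("invalid patient record(s):\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "), call. = FALSE)
  invisible(cohort)
}

#' Resolve unknown findings under a missing-data policy
#'
#' Returns a cohort with no unknown tri-state findings. Under the `BASE`
#' policy every unknown finding, including perianal symptoms, becomes
#' absent. Under the `CONSERVATIVE` policy unknown perianal symptoms become
#' present (the study's sensitivity analysis, which moves such patients to
#' a less urgent pathway); all other unknowns still become absent. Unknown
#' menstruating status in a female is treated as menstruating, which blocks
#' the female hemoglobin route of the anemia criterion. Demographics and
#' labs are untouched.
#'
#' @param cohort a valid cohort data frame.
#' @param policy a [missing_data_policy()] or its mode string.
#' @return The resolved cohort.
#' @export
resolve_cohort <- function(cohort, policy = missing_data_policy("BASE")) {
  validate_cohort(cohort)
  policy <- as_policy(policy)
  for (f in FINDING_FIELDS) {
    fill <- if (f == "perianal_symptoms" && policy$mode == "CONSERVATIVE")
      "present" else "absent"
    cohort[[f]][cohort[[f]] == "unknown"] <- fill
  }
  cohort$menstruating[cohort$menstruating == "unknown"] <- "present"
  cohort
}
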