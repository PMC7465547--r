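#' @keywords internal
"_PACKAGE"

## Public vocabularies. These strings are the stable interface used in CSV
## headers, registries, reports and marginal specifications; do not reorder
## PRIORITY_LEVELS (ascending urgency is relied upon for comparisons).

#' Referral priority levels, in ascending order of urgency
#'
#' The four-level output vocabulary of the triage engine. The order is
#' meaningful: `NO_ACTION < POSSIBLE_PRIORITY < URGENT < IMMEDIATE`.
#' @export
PRIORITY_LEVELS <- c("NO_ACTION", "POSSIBLE_PRIORITY", "URGENT", "IMMEDIATE")

#' Tri-state tokens for clinical findings
#' @export
TRISTATE_TOKENS <- c("present", "absent", "unknown")

#' Immediate-referral criterion identifiers
#' @export
IMMEDIATE_CRITERIA <- c("palpable_mass", "abnormal_imaging")

#' Urgent-referral criterion identifiers
#'
#' The five bleeding qualifiers require rectal bleeding to be present;
#' `ida_with_low_hb` (unexplained iron-deficiency anemia with a
#' sex-specific low hemoglobin) does not.
#' @export
URGENT_CRITERIA <- c("dark_blood", "mixed_with_stool",
                     "bleeding_without_perianal", "bleeding_with_habit_change",
                     "bleeding_with_weight_loss", "ida_with_low_hb")

#' Possible-priority basis identifiers
#' @export
POSSIBLE_PRIORITY_BASES <- c("isolated_bleeding", "modifier_age",
                             "modifier_male", "modifier_family_history")

## Tri-state finding columns of a patient record, in schema order.
FINDING_FIELDS <- c("ida", "palpable_mass", "abnormal_imaging",
                    "rectal_bleeding", "dark_blood", "blood_mixed_stool",
                    "perianal_symptoms", "bowel_habit_change", "weight_loss",
                    "fdr_family_history")

## Findings that count as a pathological sign of colorectal cancer for the
## possible-priority modifier basis. Perianal symptoms are excluded: they are
## a reassuring (protective) qualifier, not a sign of malignancy, and their
## presence must never raise a priority.
SIGN_FIELDS <- c("palpable_mass", "abnormal_imaging", "rectal_bleeding",
                 "dark_blood", "blood_mixed_stool", "bowel_habit_change",
                 "weight_loss", "ida")

## Full cohort CSV column set, in canonical order.
COHORT_COLUMNS <- c("id", "age", "sex", "menstruating", "hemoglobin",
                    FINDING_FIELDS, "crc_confirmed")

#' Rule constants for the triage engine
#'
#' Hemoglobin thresholds for the iron-deficiency-anemia criterion and the
#' age cutoff for the possible-priority modifier basis. Defaults follow the
#' Cancer Care Ontario criteria: hemoglobin of 110 g/L or less for males,
#' 100 g/L or less for nonmenstruating females (inclusive comparisons), and
#' age strictly greater than 59 years for the age modifier.
#'
#' @param hb_threshold_male hemoglobin threshold for males, g/L.
#' @param hb_threshold_nonmenstruating_female hemoglobin threshold for
#'   nonmenstruating females, g/L.
#' @param modifier_age_cutoff age above which the age modifier applies, years.
#' @param enable_modifier_basis logical; whether the possible-priority
#'   modifier rows (age > cutoff, male sex, first-degree family history, in
#'   combination with any pathological sign) may upgrade a record that meets
#'   no immediate or urgent criterion.
#' @return An object of class `rule_constants`.
#' @export
rule_constants <- function(hb_threshold_male = 110,
                           hb_threshold_nonmenstruating_female = 100,
                           modifier_age_cutoff = 59,
                           enable_modifier_basis = TRUE) {
  stopifnot(is.numeric(hb_threshold_male), hb_threshold_male > 0,
            is.numeric(hb_threshold_nonmenstruating_female),
            hb_threshold_nonmenstruating_female > 0,
            is.numeric(modifier_age_cutoff), modifier_age_cutoff >= 18,
            is.logical(enable_modifier_basis))
  structure(list(
    hb_threshold_male = hb_threshold_male,
    hb_threshold_nonmenstruating_female = hb_threshold_nonmenstruating_female,
    modifier_age_cutoff = modifier_age_cutoff,
    enable_modifier_basis = enable_modifier_basis
  ), class = "rule_constants")
}

#' Missing-data policy for unknown tri-state findings
#'
#' Both policies resolve every unknown finding to absent, except perianal
#' symptoms under the conservative policy, which are resolved to present
#' (pushing the record toward a less urgent pathway). The conservative
#' policy reproduces the study's perianal-symptom sensitivity analysis.
#'
#' @param mode `"BASE"` or `"CONSERVATIVE"`.
#' @return An object of class `missing_data_policy`.
#' @export
missing_data_policy <- function(mode = c("BASE", "CONSERVATIVE")) {
  mode <- match.arg(toupper(mode[1L]), c("BASE", "CONSERVATIVE"))
  structure(list(mode = mode), class = "missing_data_policy")
}

as_policy <- function(policy) {
  if (inherits(policy, "missing_data_policy")) return(policy)
  missing_data_policy(policy)
}
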