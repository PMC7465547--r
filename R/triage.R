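## The rule engine. All evaluators are vectorized over cohort rows and
## assume resolved inputs (no unknown tri-states); triage_cohort() handles
## validation and resolution.

#' Does the iron-deficiency-anemia criterion fire?
#'
#' The criterion requires a clinician-asserted unexplained iron-deficiency
#' anemia together with a hemoglobin at or below the sex-specific
#' threshold: 110 g/L for males, 100 g/L for nonmenstruating females
#' (inclusive). Unknown hemoglobin or unknown sex never qualifies; a
#' menstruating female never qualifies via the hemoglobin route.
#'
#' @param sex,menstruating,hemoglobin,ida resolved record fields
#'   (vectorized).
#' @param constants a [rule_constants()].
#' @return Logical vector.
#' @export
anemia_qualifies <- function(sex, menstruating, hemoglobin, ida,
                             constants = rule_constants()) {
  hb_known <- !is.na(hemoglobin)
  male_route <- sex == "male" & hb_known &
    hemoglobin <= constants$hb_threshold_male
  female_route <- sex == "female" & menstruating == "absent" & hb_known &
    hemoglobin <= constants$hb_threshold_nonmenstruating_female
  ida == "present" & (male_route | female_route)
}

## Logical criterion matrix for the immediate tier (n x 2).
immediate_matrix <- function(cohort) {
  cbind(palpable_mass = cohort$palpable_mass == "present",
        abnormal_imaging = cohort$abnormal_imaging == "present")
}

## Logical criterion matrix for the urgent tier (n x 6). The five bleeding
## qualifiers require rectal bleeding to be present; the anemia criterion
## stands alone.
urgent_matrix <- function(cohort, constants = rule_constants()) {
  rb <- cohort$rectal_bleeding == "present"
  cbind(
    dark_blood = rb & cohort$dark_blood == "present",
    mixed_with_stool = rb & cohort$blood_mixed_stool == "present",
    bleeding_without_perianal = rb & cohort$perianal_symptoms == "absent",
    bleeding_with_habit_change = rb & cohort$bowel_habit_change == "present",
    bleeding_with_weight_loss = rb & cohort$weight_loss == "present",
    ida_with_low_hb = anemia_qualifies(cohort$sex, cohort$menstruating,
                                       cohort$hemoglobin, cohort$ida,
                                       constants)
  )
}

## Possible-priority basis matrix (n x 4), meaningful only for rows where
## the immediate and urgent tiers are empty:
##   (a) isolated bleeding -- rectal bleeding present but no urgent
##       qualifier (e.g. bleeding with perianal symptoms and nothing else);
##   (b) modifier basis -- any pathological sign present combined with
##       age > cutoff, male sex, or a first-degree family history.
possible_matrix <- function(cohort, constants = rule_constants()) {
  sign_present <- Reduce(`|`, lapply(SIGN_FIELDS,
                                     function(f) cohort[[f]] == "present"))
  if (constants$enable_modifier_basis) {
    age_mod <- !is.na(cohort$age) & cohort$age > constants$modifier_age_cutoff
    male_mod <- cohort$sex == "male"
    fdr_mod <- cohort$fdr_family_history == "present"
  } else {
    age_mod <- male_mod <- fdr_mod <- rep(FALSE, nrow(cohort))
  }
  cbind(isolated_bleeding = cohort$rectal_bleeding == "present",
        modifier_age = sign_present & age_mod,
        modifier_male = sign_present & male_mod,
        modifier_family_history = sign_present & fdr_mod)
}

criteria_from_matrix <- function(m, i) colnames(m)[which(m[i, ])]

#' Satisfied immediate criteria for one resolved record
#' @param record a resolved one-row cohort data frame.
#' @return Character vector of satisfied immediate criterion identifiers.
#' @export
evaluate_immediate <- function(record) {
  criteria_from_matrix(immediate_matrix(record), 1L)
}

#' Satisfied urgent criteria for one resolved record
#' @inheritParams evaluate_immediate
#' @param constants a [rule_constants()].
#' @return Character vector of satisfied urgent criterion identifiers.
#' @export
evaluate_urgent <- function(record, constants = rule_constants()) {
  criteria_from_matrix(urgent_matrix(record, constants), 1L)
}

#' Satisfied possible-priority bases for one resolved record
#'
#' Only meaningful when [evaluate_immediate()] and [evaluate_urgent()] are
#' both empty for the record.
#' @inheritParams evaluate_urgent
#' @return Character vector of satisfied possible-priority bases.
#' @export
evaluate_possible_priority <- function(record,
                                       constants = rule_constants()) {
  criteria_from_matrix(possible_matrix(record, constants), 1L)
}

## Referral action texts, per priority (configurable via options would be
## overkill; the two upper tiers carry the published windows, the lower two
## carry neutral defaults).
REFERRAL_WINDOWS <- c(
  IMMEDIATE = paste("Immediate referral: referral within 24 hours;",
                    "expected endoscopy within 2 weeks."),
  URGENT = paste("Urgent referral: expected consultation within 4 weeks;",
                 "expected endoscopy within 8 weeks."),
  POSSIBLE_PRIORITY = paste("Possible priority referral: expedited routine",
                            "referral at clinician discretion."),
  NO_ACTION = "No specific action recommended."
)

#' Triage an entire cohort
#'
#' Vectorized engine behind [triage()]: validates, resolves unknowns under
#' the policy, evaluates the criterion tiers and applies the strict
#' precedence IMMEDIATE > URGENT > POSSIBLE_PRIORITY > NO_ACTION.
#'
#' @param cohort a cohort data frame.
#' @param policy a [missing_data_policy()] or mode string.
#' @param constants a [rule_constants()].
#' @return A data frame with columns `id`, `priority` (ordered factor over
#'   [PRIORITY_LEVELS]) and `criteria` (semicolon-joined satisfied
#'   criteria, or possible-priority bases for that tier).
#' @export
triage_cohort <- function(cohort, policy = missing_data_policy("BASE"),
                          constants = rule_constants()) {
  resolved <- resolve_cohort(cohort, policy)
  im <- immediate_matrix(resolved)
  ur <- urgent_matrix(resolved, constants)
  po <- possible_matrix(resolved, constants)
  has_im <- rowSums(im) > 0
  has_ur <- rowSums(ur) > 0
  has_po <- rowSums(po) > 0
  priority <- ifelse(has_im, "IMMEDIATE",
                     ifelse(has_ur, "URGENT",
                            ifelse(has_po, "POSSIBLE_PRIORITY",
                                   "NO_ACTION")))
  criteria <- character(nrow(resolved))
  for (i in seq_len(nrow(resolved))) {
    criteria[i] <- switch(
      priority[i],
      IMMEDIATE = paste(c(criteria_from_matrix(im, i),
                          criteria_from_matrix(ur, i)), collapse = ";"),
      URGENT = paste(criteria_from_matrix(ur, i), collapse = ";"),
      POSSIBLE_PRIORITY = paste(criteria_from_matrix(po, i),
                                collapse = ";"),
      NO_ACTION = ""
    )
  }
  data.frame(id = resolved$id,
             priority = factor(priority, levels = PRIORITY_LEVELS,
                               ordered = TRUE),
             criteria = criteria, stringsAsFactors = FALSE)
}

#' Triage a single patient record
#'
#' Applies the referral-urgency rules to one record: resolves unknown
#' findings under the missing-data policy, evaluates the immediate, urgent
#' and possible-priority tiers, and returns the highest tier satisfied
#' (strict precedence), together with the satisfied criteria, the
#' recommended action window and, when a PPV registry is supplied, a
#' post-test probability of colorectal cancer.
#'
#' @param record a one-row cohort data frame (see [patient_record()]).
#' @param policy a [missing_data_policy()] or mode string.
#' @param constants a [rule_constants()].
#' @param registry optional [ppv_registry()].
#' @return An object of class `crc_recommendation`: a list with `id`,
#'   `priority`, `satisfied_criteria`, `referral_window`, `policy` and
#'   `posttest_probability` (`NA` without a registry).
#' @examples
#' rec <- patient_record(sex = "male", age = 72,
#'                       rectal_bleeding = "present",
#'                       perianal_symptoms = "absent")
#' triage(rec)
#' @export
triage <- function(record, policy = missing_data_policy("BASE"),
                   constants = rule_constants(), registry = NULL) {
  if (!is.data.frame(record) || nrow(record) != 1L)
    stop("record must be a one-row cohort data frame", call. = FALSE)
  policy <- as_policy(policy)
  res <- triage_cohort(record, policy, constants)
  criteria <- if (nzchar(res$criteria))
    strsplit(res$criteria, ";", fixed = TRUE)[[1L]] else character(0)
  priority <- as.character(res$priority)
  posttest <- NA_real_
  if (!is.null(registry)) {
    scoreable <- setdiff(criteria, POSSIBLE_PRIORITY_BASES)
    posttest <- posttest_probability(scoreable, registry)
  }
  structure(list(id = record$id, priority = priority,
                 satisfied_criteria = criteria,
                 referral_window = unname(REFERRAL_WINDOWS[priority]),
                 policy = policy$mode,
                 posttest_probability = posttest),
            class = "crc_recommendation")
}

#' @export
print.crc_recommendation <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Positive-predictive-value registry for post-test probabilities
#'
#' A mapping from criterion identifier to the median positive predictive
#' value of that criterion (fractions in \[0, 1\]), plus a pre-test
#' probability. The engine prints no claim about how PPVs combine beyond
#' the documented aggregation rule of [posttest_probability()].
#'
#' @param ppv named numeric vector of per-criterion median PPVs.
#' @param pretest_probability pre-test probability of colorectal cancer.
#' @return An object of class `ppv_registry`.
#' @export
ppv_registry <- function(ppv = numeric(0), pretest_probability = 0.0) {
  ppv <- unlist(ppv)
  if (length(ppv) && (is.null(names(ppv)) || any(!nzchar(names(ppv)))))
    stop("registry PPVs must be named by criterion identifier",
         call. = FALSE)
  if (any(ppv < 0 | ppv > 1) ||
      pretest_probability < 0 || pretest_probability > 1)
    stop("registry probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(ppv = ppv, pretest_probability = pretest_probability),
            class = "ppv_registry")
}

#' Post-test probability from satisfied criteria
#'
#' Aggregation rule: the maximum of the registry PPVs over the satisfied
#' criteria — the weakest defensible aggregator, since criterion PPVs are
#' marginal values whose joint behaviour is unknown. With no satisfied
#' criterion the registry's pre-test probability is returned. A satisfied
#' criterion missing from the registry is a configuration error, never a
#' silent zero.
#'
#' @param satisfied_criteria character vector of criterion identifiers.
#' @param registry a [ppv_registry()].
#' @return A probability in \[0, 1\].
#' @export
posttest_probability <- function(satisfied_criteria, registry) {
  if (!inherits(registry, "ppv_registry"))
    stop("registry must be a ppv_registry", call. = FALSE)
  if (!length(satisfied_criteria)) return(registry$pretest_probability)
  missing_ppv <- setdiff(satisfied_criteria, names(registry$ppv))
  if (length(missing_ppv))
    stop("registry has no PPV for criterion: ",
         paste(missing_ppv, collapse = ", "), call. = FALSE)
  max(registry$ppv[satisfied_criteria])
}
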