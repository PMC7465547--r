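#' Specification for the seeded random cohort generator
#'
#' Defaults emulate the demographics of the published validation cohort
#' (age 67 +/- 13.4 years, hemoglobin 123.3 +/- 22.3 g/L, 56.2% male) with
#' per-finding prevalences in the range of the cohort-wide criterion
#' frequencies. The generator is a property-test input source, not a
#' validated reconstruction of any real cohort.
#'
#' @param n cohort size (> 0).
#' @param prevalence named vector of per-finding presence probabilities
#'   over the tri-state finding fields; dark blood and blood mixed with
#'   stool are sampled conditionally on rectal bleeding being present, so
#'   their marginal prevalence is `prevalence * P(bleeding)`.
#' @param unknown_rate probability that a tri-state finding is recorded as
#'   unknown (applied where it cannot violate record invariants).
#' @param age_mean,age_sd,hb_mean,hb_sd demographic distributions.
#' @param male_fraction fraction of males.
#' @param crc_rate probability a record is a confirmed case.
#' @param seed integer RNG seed; same seed, same cohort.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n = 100L,
                           prevalence = c(ida = 0.17, palpable_mass = 0.19,
                                          abnormal_imaging = 0.07,
                                          rectal_bleeding = 0.85,
                                          dark_blood = 0.08,
                                          blood_mixed_stool = 0.45,
                                          perianal_symptoms = 0.15,
                                          bowel_habit_change = 0.55,
                                          weight_loss = 0.30,
                                          fdr_family_history = 0.10),
                           unknown_rate = 0.05,
                           age_mean = 67.0, age_sd = 13.4,
                           hb_mean = 123.3, hb_sd = 22.3,
                           male_fraction = 0.562, crc_rate = 1.0,
                           seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  missing_prev <- setdiff(FINDING_FIELDS, names(prevalence))
  if (length(missing_prev))
    stop("prevalence missing for finding(s): ",
         paste(missing_prev, collapse = ", "), call. = FALSE)
  probs <- c(prevalence, unknown_rate = unknown_rate,
             male_fraction = male_fraction, crc_rate = crc_rate)
  if (any(probs < 0 | probs > 1))
    stop("prevalences and rates must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 unknown_rate = unknown_rate, age_mean = age_mean,
                 age_sd = age_sd, hb_mean = hb_mean, hb_sd = hb_sd,
                 male_fraction = male_fraction, crc_rate = crc_rate,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a seeded random cohort
#'
#' Samples `spec$n` independent records. The record invariants are
#' enforced by construction: dark blood and blood mixed with stool can
#' only be present when rectal bleeding is present, and rectal bleeding is
#' never blanked to unknown on a record carrying either; ages and
#' hemoglobins are clamped to their validation bounds.
#'
#' @param spec a [generator_spec()].
#' @return A valid cohort data frame of `spec$n` records.
#' @export
generate_random_cohort <- function(spec = generator_spec()) {
  if (!inherits(spec, "generator_spec"))
    stop("spec must be a generator_spec", call. = FALSE)
  n <- spec$n
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  draw <- function(p) ifelse(stats::runif(n) < p, "present", "absent")
  pv <- spec$prevalence

  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  age <- pmin(120, pmax(18, round(stats::rnorm(n, spec$age_mean,
                                               spec$age_sd))))
  hb <- pmin(250, pmax(40, round(stats::rnorm(n, spec$hb_mean,
                                              spec$hb_sd), 1)))
  menstruating <- ifelse(sex == "female" & age < 50,
                         draw(0.8), "absent")

  rb <- draw(pv["rectal_bleeding"])
  dark <- ifelse(rb == "present", draw(pv["dark_blood"]), "absent")
  mixed <- ifelse(rb == "present", draw(pv["blood_mixed_stool"]), "absent")

  cohort <- data.frame(
    id = sprintf("rnd%05d", seq_len(n)), age = as.numeric(age), sex = sex,
    menstruating = menstruating, hemoglobin = hb,
    ida = draw(pv["ida"]), palpable_mass = draw(pv["palpable_mass"]),
    abnormal_imaging = draw(pv["abnormal_imaging"]), rectal_bleeding = rb,
    dark_blood = dark, blood_mixed_stool = mixed,
    perianal_symptoms = draw(pv["perianal_symptoms"]),
    bowel_habit_change = draw(pv["bowel_habit_change"]),
    weight_loss = draw(pv["weight_loss"]),
    fdr_family_history = draw(pv["fdr_family_history"]),
    crc_confirmed = ifelse(stats::runif(n) < spec$crc_rate, "yes", "no"),
    stringsAsFactors = FALSE
  )

  # sprinkle unknowns where they cannot break invariants
  if (spec$unknown_rate > 0) {
    blankable <- function(field) stats::runif(n) < spec$unknown_rate
    for (f in setdiff(FINDING_FIELDS,
                      c("rectal_bleeding", "dark_blood",
                        "blood_mixed_stool")))
      cohort[[f]][blankable(f)] <- "unknown"
    rb_lockable <- cohort$dark_blood != "present" &
      cohort$blood_mixed_stool != "present"
    cohort$rectal_bleeding[blankable("rectal_bleeding") & rb_lockable] <-
      "unknown"
    for (f in c("dark_blood", "blood_mixed_stool"))
      cohort[[f]][blankable(f) & cohort[[f]] == "absent"] <- "unknown"
  }

  validate_cohort(cohort)
  cohort
}
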