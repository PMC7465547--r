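test_that("resolution honours the missing-data policy", {
  rec <- patient_record(id = "r1", rectal_bleeding = "present",
                        perianal_symptoms = "unknown",
                        weight_loss = "unknown")
  base <- resolve_cohort(rec, "BASE")
  cons <- resolve_cohort(rec, "CONSERVATIVE")
  expect_equal(base$perianal_symptoms, "absent")
  expect_equal(cons$perianal_symptoms, "present")
  # every other unknown resolves to absent under both policies
  expect_equal(base$weight_loss, "absent")
  expect_equal(cons$weight_loss, "absent")
  # a fully-known record is untouched by either policy
  known <- patient_record(id = "r2", rectal_bleeding = "present",
                          perianal_symptoms = "present", age = 70)
  expect_identical(resolve_cohort(known, "BASE"), known)
  expect_identical(resolve_cohort(known, "CONSERVATIVE"), known)
})

test_that("record validation rejects each broken invariant by name", {
  expect_error(patient_record(hemoglobin = 300), "hemoglobin")
  expect_error(patient_record(age = 10), "age")
  expect_error(patient_record(dark_blood = "present",
                              rectal_bleeding = "absent"), "dark_blood")
  expect_error(patient_record(blood_mixed_stool = "present",
                              rectal_bleeding = "unknown"),
               "blood_mixed_stool")
  expect_error(patient_record(ida = "maybe"), "ida")
  expect_error(patient_record(sex = "m"), "sex")
})

test_that("anemia criterion applies sex-specific inclusive thresholds", {
  cases <- list(
    # sex, menstruating, hb, ida, expected
    list("male", "absent", 105, "present", TRUE),
    list("male", "absent", 110, "present", TRUE),   # inclusive at 110
    list("male", "absent", 110.5, "present", FALSE),
    list("female", "present", 95, "present", FALSE), # menstruating blocks
    list("female", "absent", 95, "present", TRUE),
    list("female", "absent", 100, "present", TRUE),  # inclusive at 100
    list("female", "absent", 101, "present", FALSE),
    list("male", "absent", 105, "absent", FALSE),    # needs the IDA flag
    list("male", "absent", NA, "present", FALSE),    # unknown hemoglobin
    list("unknown", "absent", 90, "present", FALSE)  # unknown sex
  )
  for (cs in cases)
    expect_equal(anemia_qualifies(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                 cs[[5]],
                 info = paste(unlist(cs), collapse = "/"))
})

test_that("tier evaluators return the satisfied criterion identifiers", {
  rec <- function(...) resolve_cohort(patient_record(...), "BASE")

  expect_equal(evaluate_immediate(rec(palpable_mass = "present")),
               "palpable_mass")
  expect_equal(evaluate_immediate(rec()), character(0))
  expect_setequal(evaluate_immediate(rec(palpable_mass = "present",
                                         abnormal_imaging = "present")),
                  c("palpable_mass", "abnormal_imaging"))

  expect_equal(evaluate_urgent(rec(rectal_bleeding = "present",
                                   perianal_symptoms = "absent")),
               "bleeding_without_perianal")
  expect_equal(evaluate_urgent(rec()), character(0))
  expect_equal(evaluate_urgent(rec(rectal_bleeding = "present",
                                   perianal_symptoms = "present",
                                   bowel_habit_change = "present")),
               "bleeding_with_habit_change")
  # anemia criterion does not require bleeding
  expect_equal(evaluate_urgent(rec(sex = "male", hemoglobin = 105,
                                   ida = "present")),
               "ida_with_low_hb")

  # isolated bleeding: perianal symptoms present, nothing else
  expect_equal(evaluate_possible_priority(
    rec(rectal_bleeding = "present", perianal_symptoms = "present",
        age = 45, sex = "female")),
    "isolated_bleeding")
  # modifiers alone never fire without a sign
  expect_equal(evaluate_possible_priority(rec(age = 70, sex = "male")),
               character(0))
  # sub-threshold sign plus age modifier
  expect_equal(evaluate_possible_priority(
    rec(weight_loss = "present", age = 65, sex = "female")),
    "modifier_age")
})

test_that("triage applies strict tier precedence and action windows", {
  imm <- triage(patient_record(palpable_mass = "present",
                               rectal_bleeding = "present",
                               dark_blood = "present"))
  expect_s3_class(imm, "crc_recommendation")
  expect_equal(imm$priority, "IMMEDIATE")
  expect_true("palpable_mass" %in% imm$satisfied_criteria)
  expect_match(imm$referral_window, "24 hours")
  expect_match(imm$referral_window, "2 weeks")

  urg <- triage(patient_record(rectal_bleeding = "present"))
  expect_equal(urg$priority, "URGENT")
  expect_match(urg$referral_window, "4 weeks")
  expect_match(urg$referral_window, "8 weeks")

  none <- triage(patient_record())
  expect_equal(none$priority, "NO_ACTION")
  expect_length(none$satisfied_criteria, 0)

  # the demotion mechanism of the policy comparison: unknown perianal
  amb <- patient_record(rectal_bleeding = "present",
                        perianal_symptoms = "unknown",
                        age = 45, sex = "female")
  expect_equal(triage(amb, "BASE")$priority, "URGENT")
  expect_equal(triage(amb, "CONSERVATIVE")$priority, "POSSIBLE_PRIORITY")
})

test_that("modifier basis is configurable and off by switch", {
  rec <- patient_record(weight_loss = "present", age = 70, sex = "male")
  on <- triage(rec, constants = rule_constants())
  off <- triage(rec,
                constants = rule_constants(enable_modifier_basis = FALSE))
  expect_equal(on$priority, "POSSIBLE_PRIORITY")
  expect_equal(off$priority, "NO_ACTION")
})

test_that("post-test probability is the max PPV with pre-test fallback", {
  reg <- ppv_registry(ppv = c(bleeding_without_perianal = 0.10,
                              mixed_with_stool = 0.25),
                      pretest_probability = 0.03)
  expect_equal(posttest_probability("bleeding_without_perianal",
                                    ppv_registry(
                                      c(bleeding_without_perianal = 0.12))),
               0.12)
  expect_equal(posttest_probability(character(0), reg), 0.03)
  expect_equal(posttest_probability(c("bleeding_without_perianal",
                                      "mixed_with_stool"), reg), 0.25)
  # order invariance
  expect_equal(posttest_probability(c("mixed_with_stool",
                                      "bleeding_without_perianal"), reg),
               0.25)
  # unknown criterion is a configuration error, never a silent zero
  expect_error(posttest_probability("dark_blood", reg), "dark_blood")
  expect_error(ppv_registry(c(dark_blood = 1.2)), "\\[0, 1\\]")

  rec <- triage(patient_record(rectal_bleeding = "present"),
                registry = reg)
  expect_equal(rec$posttest_probability, 0.10)
})
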