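# Independent flat-decision-table oracle for the triage rules: one scalar
# record at a time, nested conditionals, no shared code with the package's
# vectorized engine. Used to cross-check the engine over exhaustive
# enumerations of finding combinations.

oracle_triage <- function(row, policy = "BASE",
                          hb_male = 110, hb_female = 100, age_cutoff = 59,
                          modifiers = TRUE) {
  rs <- function(v, fill = "absent") if (v == "unknown") fill else v
  peri_fill <- if (policy == "CONSERVATIVE") "present" else "absent"
  ida <- rs(row$ida); mass <- rs(row$palpable_mass)
  img <- rs(row$abnormal_imaging); rb <- rs(row$rectal_bleeding)
  dark <- rs(row$dark_blood); mixed <- rs(row$blood_mixed_stool)
  peri <- rs(row$perianal_symptoms, peri_fill)
  habit <- rs(row$bowel_habit_change); wl <- rs(row$weight_loss)
  fdr <- rs(row$fdr_family_history)
  mens <- if (row$menstruating == "unknown") "present" else row$menstruating

  if (mass == "present" || img == "present") return("IMMEDIATE")

  anemia <- FALSE
  if (ida == "present" && !is.na(row$hemoglobin)) {
    if (row$sex == "male" && row$hemoglobin <= hb_male) anemia <- TRUE
    if (row$sex == "female" && mens == "absent" &&
        row$hemoglobin <= hb_female) anemia <- TRUE
  }
  if (rb == "present") {
    if (dark == "present") return("URGENT")
    if (mixed == "present") return("URGENT")
    if (peri == "absent") return("URGENT")
    if (habit == "present") return("URGENT")
    if (wl == "present") return("URGENT")
  }
  if (anemia) return("URGENT")

  if (rb == "present") return("POSSIBLE_PRIORITY")
  sign <- rb == "present" || mass == "present" || img == "present" ||
    dark == "present" || mixed == "present" || habit == "present" ||
    wl == "present" || ida == "present"
  if (modifiers && sign) {
    if (!is.na(row$age) && row$age > age_cutoff) return("POSSIBLE_PRIORITY")
    if (row$sex == "male") return("POSSIBLE_PRIORITY")
    if (fdr == "present") return("POSSIBLE_PRIORITY")
  }
  "NO_ACTION"
}

# Exhaustive grid over the nine tri-state findings at fixed demographics.
# Invalid combinations (dark blood / blood mixed with stool present without
# rectal bleeding present) are dropped.
enumerate_findings <- function(age = 45, sex = "female", hemoglobin = 123,
                               fdr = "absent") {
  states <- c("present", "absent", "unknown")
  grid <- expand.grid(ida = states, palpable_mass = states,
                      abnormal_imaging = states, rectal_bleeding = states,
                      dark_blood = states, blood_mixed_stool = states,
                      perianal_symptoms = states,
                      bowel_habit_change = states, weight_loss = states,
                      stringsAsFactors = FALSE)
  valid <- !((grid$dark_blood == "present" |
                grid$blood_mixed_stool == "present") &
               grid$rectal_bleeding != "present")
  grid <- grid[valid, , drop = FALSE]
  data.frame(id = sprintf("enum%05d", seq_len(nrow(grid))),
             age = age, sex = sex, menstruating = "absent",
             hemoglobin = hemoglobin, grid,
             fdr_family_history = fdr, crc_confirmed = "yes",
             stringsAsFactors = FALSE)
}

priority_rank <- function(p) match(as.character(p), PRIORITY_LEVELS)
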