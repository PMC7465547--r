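test_that("binarization maps the two upper tiers to positive", {
  expect_equal(binarize_priority(c("IMMEDIATE", "URGENT",
                                   "POSSIBLE_PRIORITY", "NO_ACTION")),
               c("positive", "positive", "negative", "negative"))
  expect_error(binarize_priority("LOW"), "unknown priority")
})

test_that("sensitivity is the positive fraction of diseased records", {
  expect_equal(sensitivity(280, 281), 280 / 281)
  expect_equal(percent1(sensitivity(280, 281)), "99.6")
  expect_equal(sensitivity(0, 281), 0)
  expect_equal(percent1(sensitivity(257, 281)), "91.5")
  expect_error(sensitivity(1, 0), "undefined")
  expect_error(sensitivity(5, 3), "positives")
})

test_that("Wilson interval matches the closed form and prop.test", {
  # frozen hand evaluation of the closed form
  expect_equal(unname(wilson_interval(50, 100)),
               c(0.4038, 0.5962), tolerance = 1e-4)
  # reproduces the published bounds for 280/281 at one-decimal rendering
  ci <- wilson_interval(280, 281)
  expect_equal(percent1(ci), c("98.0", "99.9"), ignore_attr = TRUE)
  # boundary clipping
  expect_equal(unname(wilson_interval(0, 10)["low"]), 0)
  expect_equal(unname(wilson_interval(10, 10)["high"]), 1)
  # independent route: score interval from prop.test without continuity
  # correction, over a grid
  for (n in c(7, 25, 100, 281))
    for (x in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      ref <- suppressWarnings(
        stats::prop.test(x, n, correct = FALSE))$conf.int
      expect_equal(unname(wilson_interval(x, n)), as.numeric(ref),
                   tolerance = 1e-8, label = sprintf("wilson(%d, %d)", x, n))
    }
  expect_error(wilson_interval(5, 0), "successes")
  expect_error(wilson_interval(5, 10, confidence = 1), "confidence")
})

test_that("Clopper-Pearson matches binom.test and is conservative", {
  expect_equal(unname(clopper_pearson_interval(0, 10)["low"]), 0)
  expect_equal(unname(clopper_pearson_interval(10, 10)["high"]), 1)
  for (n in c(7, 25, 100, 281))
    for (x in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      ref <- stats::binom.test(x, n)$conf.int
      cp <- clopper_pearson_interval(x, n)
      expect_equal(unname(cp), as.numeric(ref), tolerance = 1e-8,
                   label = sprintf("clopper_pearson(%d, %d)", x, n))
      # both intervals contain the point estimate
      wi <- wilson_interval(x, n)
      p_hat <- x / n
      expect_true(cp["low"] <= p_hat + 1e-12 && p_hat <= cp["high"] + 1e-12)
      expect_true(wi["low"] <= p_hat + 1e-12 && p_hat <= wi["high"] + 1e-12)
      # the exact interval is never narrower than the score interval away
      # from the boundary counts; at x = 0 or x = n the exact interval
      # pins one bound at 0/1 and spends the whole alpha/2 on the other
      # side, which can undercut the score bound slightly (checked below)
      if (x > 0 && x < n) expect_gte(diff(cp) + 1e-12, diff(wi))
    }
  # strict containment on an interior case
  expect_lt(clopper_pearson_interval(5, 10)["low"],
            wilson_interval(5, 10)["low"])
  expect_gt(clopper_pearson_interval(5, 10)["high"],
            wilson_interval(5, 10)["high"])
  # boundary convention: closed form of the exact bounds at x = 0 / x = n
  expect_equal(unname(clopper_pearson_interval(0, 50)),
               c(0, 1 - 0.025^(1 / 50)))
  expect_equal(unname(clopper_pearson_interval(50, 50)),
               c(0.025^(1 / 50), 1))
})

test_that("Wilson 95% interval has nominal coverage at p = 0.9, n = 281", {
  set.seed(20260920)
  p <- 0.9
  n <- 281
  draws <- stats::rbinom(2000, n, p)
  covered <- vapply(draws, function(x) {
    ci <- wilson_interval(x, n)
    ci["low"] <= p && p <= ci["high"]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("Cohen's kappa: frozen values, degeneracies and oracle", {
  # identical vectors
  expect_equal(cohens_kappa(c("a", "b", "a", "c"),
                            c("a", "b", "a", "c")), 1)
  # hand-computed 2x2 table a=15, b=2, c=3, d=5:
  # p_o = 20/25 = 0.8, p_e = (17*18 + 8*7)/25^2 = 0.5792
  ra <- rep(c("pos", "pos", "neg", "neg"), times = c(15, 2, 3, 5))
  rb <- rep(c("pos", "neg", "pos", "neg"), times = c(15, 2, 3, 5))
  expect_equal(cohens_kappa(ra, rb), (0.8 - 0.5792) / (1 - 0.5792))
  expect_equal(round(cohens_kappa(ra, rb), 4), 0.5247)
  # chance-level agreement against a constant rater
  expect_equal(cohens_kappa(rep(c("x", "y"), 10), rep("x", 20)), 0)
  # degenerate perfect agreement on a single label
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5)), 1)
  expect_error(cohens_kappa("a", c("a", "b")), "equal length")
})

test_that("kappa is symmetric and invariant to label permutation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  labs <- PRIORITY_LEVELS
  for (i in 1:20) {
    a <- sample(labs, 60, replace = TRUE)
    b <- ifelse(stats::runif(60) < 0.6, a, sample(labs, 60, replace = TRUE))
    k <- cohens_kappa(a, b)
    expect_equal(cohens_kappa(b, a), k)
    perm <- setNames(sample(labs), labs)
    expect_equal(cohens_kappa(perm[a], perm[b]), k)
    # independent oracle
    tab <- table(factor(a, labs), factor(b, labs))
    expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("evaluate_cohort tallies, binarizes and ledgers demotions", {
  # one all-absent record: negative, sensitivity zero
  solo <- patient_record(crc_confirmed = "yes")
  ev <- evaluate_cohort(solo)
  expect_equal(unname(ev$counts),
               c(0L, 0L, 0L, 1L))  # IMMEDIATE..NO_ACTION descending
  expect_equal(ev$sensitivity, 0)
  expect_false(ev$meets_threshold)

  # small mixed cohort with an unclear-perianal record
  cohort <- rbind(
    patient_record(id = "a", palpable_mass = "present",
                   crc_confirmed = "yes"),
    patient_record(id = "b", rectal_bleeding = "present",
                   perianal_symptoms = "unknown", age = 45,
                   sex = "female", crc_confirmed = "yes"),
    patient_record(id = "c", rectal_bleeding = "present",
                   perianal_symptoms = "present", age = 45,
                   sex = "female", crc_confirmed = "yes"))
  base <- evaluate_cohort(cohort, "BASE")
  expect_equal(sum(base$counts), base$n)
  expect_equal(base$positives, 2)
  expect_equal(base$sensitivity, 2 / 3)
  expect_true(base$ci_low <= base$sensitivity &&
                base$sensitivity <= base$ci_high)
  expect_null(base$demoted)

  cons <- evaluate_cohort(cohort, "CONSERVATIVE")
  expect_equal(cons$demoted$id, "b")
  expect_equal(cons$demoted$base_priority, "URGENT")
  expect_equal(cons$demoted$conservative_priority, "POSSIBLE_PRIORITY")
  expect_equal(cons$positives, 1)

  # mixed confirmation status: sensitivity over the confirmed subset
  cohort$crc_confirmed[3] <- "no"
  mixed <- evaluate_cohort(cohort, "BASE")
  expect_equal(mixed$n_confirmed, 2)
  expect_equal(mixed$sensitivity, 1)
  expect_match(mixed$warnings, "confirmed")

  expect_error(evaluate_cohort(cohort[0, ]), "non-empty")
  cohort$crc_confirmed <- "no"
  expect_error(evaluate_cohort(cohort), "undefined")
})

test_that("percentages render half-up to one decimal", {
  expect_equal(percent1(c(69, 211, 1, 0) / 281),
               c("24.6", "75.1", "0.4", "0.0"))
  expect_equal(percent1(0.0345), "3.5")   # half rounds up
  expect_equal(percent1(1), "100.0")
})
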