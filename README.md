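# crctriage

Rule-based referral triage for patients with suspected colorectal cancer
(CRC), with the statistical machinery to evaluate the rules on a cohort.

## The problem

Patients presenting to primary care with rectal bleeding may harbour an
underlying CRC, and delayed specialist referral delays diagnosis. A
Cancer Care Ontario working group distilled the evidence into a short
list of clinical criteria — each retained because its median positive
predictive value for CRC was at least 10% — and mapped them to four
referral urgencies. `crctriage` encodes those criteria as a total,
deterministic function from a patient record to a referral priority:

| Priority | Criteria |
|---|---|
| **Immediate** (referral ≤ 24 h, endoscopy ≤ 2 weeks) | palpable rectal mass suspicious for CRC; abnormal abdominal imaging suspicious for CRC |
| **Urgent** (consultation ≤ 4 weeks, endoscopy ≤ 8 weeks) | unexplained rectal bleeding that is dark, mixed with stool, without perianal symptoms, with a change in bowel habits, or with weight loss; unexplained iron-deficiency anemia with hemoglobin ≤ 110 g/L (males) or ≤ 100 g/L (nonmenstruating females) |
| **Possible priority** | rectal bleeding with none of the above; any sign combined with age > 59 years, male sex, or a first-degree relative with CRC |
| **No specific action** | none of the features present |

Tiers are evaluated with strict precedence (immediate > urgent > possible
priority > no action). Every clinical finding is *tri-state* —
`present`, `absent` or `unknown` — and unknowns are resolved by an
explicit missing-data policy: the **BASE** policy treats every unknown as
absent; the **CONSERVATIVE** policy additionally treats unknown perianal
symptoms as present, which removes the bleeding-without-perianal
qualifier and demotes such records to a less urgent pathway. Comparing
the two policies quantifies how fragile a cohort evaluation is to
unclear perianal documentation.

For evaluation, an immediate or urgent recommendation counts as a
positive test result. Over a cohort of confirmed CRC cases the package
computes the tool's sensitivity with a binomial confidence interval —
Wilson score by default,

$$\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n},$$

with exact Clopper–Pearson as an option — plus Cohen's kappa for rater
agreement and a demotion ledger between policies. A deterministic
281-record validation cohort, reconstructed from published
per-priority-group criterion frequencies, ships as a builder function
(`build_validation_fixture()`), together with a seeded random cohort
generator for property testing.

## Worked example

```r
library(crctriage)

# one patient: bleeding, perianal status unclear
rec <- patient_record(id = "p001", age = 45, sex = "female",
                      rectal_bleeding = "present",
                      perianal_symptoms = "unknown")
triage(rec, policy = "BASE")$priority          # "URGENT"
triage(rec, policy = "CONSERVATIVE")$priority  # "POSSIBLE_PRIORITY"

# the validation cohort, end to end
cohort <- build_validation_fixture()
evaluate_cohort(cohort, policy = "BASE")
```

```
Cohort evaluation (n = 281, policy = BASE)
  IMMEDIATE             69 (24.6%)
  URGENT               211 (75.1%)
  POSSIBLE_PRIORITY      1 (0.4%)
  NO_ACTION              0 (0.0%)
  Positive (immediate or urgent): 280 of 281 confirmed cases
  Sensitivity: 99.6% (95% CI 98.0 to 99.9%, wilson)
  Verdict: meets the pre-specified 90.0% sensitivity threshold
```

Every record in the cohort is a confirmed CRC case, so the positive
fraction *is* the sensitivity: 280 of 281 records receive an immediate
or urgent recommendation (the one exception bleeds with perianal
symptoms and no other finding). Under the conservative policy the 23
records with unclear perianal documentation are demoted:

```r
evaluate_cohort(cohort, policy = "CONSERVATIVE")
```

```
Cohort evaluation (n = 281, policy = CONSERVATIVE)
  IMMEDIATE             69 (24.6%)
  URGENT               188 (66.9%)
  POSSIBLE_PRIORITY     24 (8.5%)
  NO_ACTION              0 (0.0%)
  Positive (immediate or urgent): 257 of 281 confirmed cases
  Sensitivity: 91.5% (95% CI 87.6 to 94.2%, wilson)
  Verdict: meets the pre-specified 90.0% sensitivity threshold
  Demotions vs BASE policy: 23
```

Sensitivity falls to 91.5% but stays above the 90% adequacy threshold.
`verify_marginals(cohort)` recomputes every per-priority-group criterion
tally and returns an empty discrepancy report when the cohort reproduces
the published table exactly.

A command-line interface wraps the same functions
(`inst/cli/crctriage triage|evaluate|fixture`, see `?triage_cli`).

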