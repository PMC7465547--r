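---
title: "Referral triage for suspected colorectal cancer: rules, evaluation statistics, and the deterministic validation cohort"
author: "crctriage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Referral triage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctriage)
```

## The decision model

`crctriage` encodes an evidence-based referral-urgency rule set for
patients with suspected colorectal cancer (CRC). Each criterion was
retained by its originating clinical working group because its median
positive predictive value (PPV) for CRC across the published literature
was at least 10%. The engine is a total, deterministic function: every
valid patient record maps to exactly one of four priorities, evaluated
with strict precedence:

1. **IMMEDIATE** — palpable rectal mass or abnormal abdominal imaging
   suspicious for CRC (referral within 24 hours, endoscopy within
   2 weeks).
2. **URGENT** — unexplained rectal bleeding with at least one qualifier
   (dark blood, blood mixed with stool, absence of perianal symptoms,
   change in bowel habits, weight loss), or unexplained iron-deficiency
   anemia (IDA) with hemoglobin at or below the sex-specific threshold
   (consultation within 4 weeks, endoscopy within 8 weeks).
3. **POSSIBLE_PRIORITY** — rectal bleeding with none of the urgent
   qualifiers, or any pathological sign combined with a risk modifier
   (age above the cutoff, male sex, first-degree family history of CRC).
4. **NO_ACTION** — none of the features present.

Precedence matters: a record with a palpable mass *and* dark bleeding is
immediate, not urgent. This is also what published per-priority
frequency tables show — urgent-type findings appear inside the immediate
column because the immediate tier claimed those patients first.

### Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `hb_threshold_male` | 110 | g/L | published IDA criterion; comparison is inclusive (`<=`) |
| `hb_threshold_nonmenstruating_female` | 100 | g/L | idem; menstruating females are excluded from this route |
| `modifier_age_cutoff` | 59 | years | "age > 59" modifier row |
| `enable_modifier_basis` | `TRUE` | — | the modifier rows are semantically redundant for records that already meet a higher tier; the switch exists because they only matter for sub-threshold sign combinations |
| evaluation `threshold` | 0.90 | fraction | a priori sensitivity deemed adequate for this class of tool |
| `confidence` | 0.95 | fraction | conventional two-sided level |

### The modifier rows

The published "possible priority" rows read "age > 59 / male / family
history *with any of above signs or symptoms*" — but any of the above
signs already triggers an immediate or urgent tier on its own. We
operationalise the rows as an *upgrade path for sub-threshold records*:
a record with at least one pathological sign that met no immediate or
urgent criterion (for example, weight loss without bleeding) is raised
from NO_ACTION to POSSIBLE_PRIORITY when a modifier applies. "Signs"
are the eight pathological findings — mass, imaging, bleeding, dark
blood, blood mixed with stool, bowel-habit change, weight loss, IDA —
and deliberately exclude perianal symptoms, which are a reassuring
local explanation for bleeding, not a sign of malignancy. Including
them would let the conservative missing-data policy *raise* a priority,
inverting its meaning. The second possible-priority basis, isolated
rectal bleeding (bleeding whose only accompaniment is perianal
symptoms), is forced by the validation cohort: its single
possible-priority patient is exactly such a record.

## Missing data

Clinical findings are tri-state: `present`, `absent`, `unknown`. Two
policies resolve unknowns before the rules run:

* **BASE** — every unknown becomes absent. Triage never acts on imputed
  pathology.
* **CONSERVATIVE** — as BASE, except unknown perianal symptoms become
  *present*. Because "bleeding without perianal symptoms" is an urgent
  qualifier, this demotes records whose urgency rested solely on an
  unclear perianal note. Comparing the two policies bounds the effect
  of inconsistent perianal documentation on a cohort evaluation.

Two further conservative conventions: unknown sex or unknown hemoglobin
fails the IDA criterion (we never triage on an imputed laboratory
value), and a female with unknown menstruation status is treated as
menstruating, blocking the female hemoglobin route. Both are
symmetric with the perianal choice: ambiguity never manufactures
urgency.

### Monotonicity, and its one deliberate exception

For the eight pathological findings, flipping `absent → present` can
never lower the assigned priority; the test suite asserts this by
exhaustive enumeration. Perianal symptoms are the deliberate exception:
their presence removes an urgent qualifier, so the engine is
*anti*-monotone in that finding (also asserted exhaustively). This is
clinically intended — perianal findings explain bleeding benignly — and
it is the entire mechanism of the policy comparison. For the same
reason the conservative policy can only ever demote: the engine's
priority under CONSERVATIVE is less than or equal to its priority under
BASE for every record, a property the suite checks over the full
3^9 tri-state grid of findings (12,393 valid combinations after
excluding records where dark blood or blood mixed with stool is present
without rectal bleeding).

## Evaluation statistics

A recommendation of IMMEDIATE or URGENT is a positive test result;
POSSIBLE_PRIORITY or NO_ACTION is negative. Over a cohort of confirmed
CRC cases, sensitivity is the positive fraction, reported with a
binomial confidence interval:

* **Wilson score** (default): inverts the score test; well behaved near
  0 and 1. For 280 positives of 281 it yields (0.9801, 0.9994), which
  renders as 98.0–99.9% at one decimal — matching the published bounds,
  which is why it is the default.
* **Clopper–Pearson** (option): exact beta-quantile interval;
  conservative in coverage. Its upper bound for 280/281 rounds to
  100.0%, which is why it is *not* the default. One numerical subtlety,
  verified against independent implementations: away from the boundary
  counts the exact interval is never narrower than the score interval,
  but at exactly 0 or n successes it pins one bound at 0/1 and spends
  the whole α/2 on the other side, undercutting the score bound by
  under 10⁻³. The tests assert the width ordering over interior counts
  and the closed-form boundary convention separately.

Percentages are rendered as the field prints them: ×100, rounded
half-up to one decimal (`percent1()`), so 280/281 prints 99.6 and 1/281
prints 0.4. Rater agreement uses unweighted Cohen's kappa,
\((p_o - p_e)/(1 - p_e)\), with expected agreement from marginal
products; priorities are nominal labels, so no weighting scheme is
appropriate. Perfect agreement between two constant raters on the same
label is defined as κ = 1.

The per-criterion PPVs can be supplied as a registry
(`ppv_registry()`), in which case each recommendation carries a
post-test probability. No combination formula for co-occurring criteria
is published anywhere we know of, so the engine uses the weakest
defensible aggregator — the maximum of the satisfied criteria's median
PPVs, falling back to the registry's pre-test probability when nothing
fired — and labels the rule in its output. A satisfied criterion absent
from the registry is a configuration error, never a silent zero.

## The deterministic validation cohort

Published evaluations of this rule set report only *marginal* criterion
frequencies within each assigned priority group, never the
patient-level joint distribution. Any patient-level reconstruction is
therefore under-determined; `build_validation_fixture()` fixes one
canonical, fully deterministic construction and the test suite verifies
that it reproduces every marginal cell exactly (`verify_marginals()`
returns an empty discrepancy report):

* Every record presents with rectal bleeding and is a confirmed CRC
  case (the cohort's inclusion criteria), 158 of 281 male.
* Within each group, each criterion occupies the lowest-index block of
  records. Two documented exceptions: (i) abnormal imaging occupies the
  *top* of the immediate group so that mass (54) and imaging (19)
  jointly cover all 69 records — forcing 54 + 19 − 69 = 4 records to
  carry both flags, an arithmetic consequence of the marginals; (ii)
  bowel-habit change covers the 13 perianal-present urgent records
  first, so every urgent record retains a qualifier.
* Exactly 23 urgent records have perianal symptoms recorded as unknown
  and no urgent qualifier other than bleeding-without-perianal; these
  are precisely the records the conservative policy demotes. (The
  published demotion of all unclear-perianal patients implies none of
  them held another urgent qualifier; the cohort encodes that
  implication.)
* IDA-flagged records receive a hemoglobin below their sex-specific
  threshold (105 g/L male, 95 g/L female); everyone else 123 g/L. Ages
  cycle through ten fixed values with mean 67 years — cosmetic realism
  only; age decides no fixture outcome, and the one possible-priority
  record is constructed young, female and without family history so
  that its tier rests on isolated bleeding alone.

What the cohort does and does not show: it demonstrates that the engine
reproduces the published group sizes, marginal tallies, sensitivities
(99.6% base, 91.5% conservative) and demotion count from first
principles. It does **not** recover the true joint distribution of
findings in the original patients, their laboratory distributions
beyond the means used as constants, or any specificity/NPV/PPV of the
tool — a single-gate cohort of confirmed cases cannot yield those, and
the package deliberately refuses to compute them.

## The random cohort generator

`generate_random_cohort()` is a seeded property-test input source, not
a validated cohort model. Defaults were chosen once: demographics from
the published cohort description (age 67 ± 13.4 years, hemoglobin
123.3 ± 22.3 g/L, 56.2% male), per-finding prevalences in the range of
the cohort-wide criterion frequencies, and a 5% unknown rate per
tri-state field. Record invariants hold by construction (dark blood and
blood mixed with stool are sampled conditionally on bleeding; numerics
are clamped to their validation bounds), the caller's RNG stream is
left untouched, and identical seeds yield identical cohorts. Real
records differ in ways the generator does not emulate — findings are
correlated (a bleeding tumour produces several at once), missingness is
not independent across fields, and laboratory values are skewed — so
property tests on generated cohorts establish engine invariants, not
clinical performance.

## Numerical and interface choices

* Hemoglobin comparisons are inclusive (`<= 110`, `<= 100`), following
  the published thresholds verbatim.
* Half-up decimal rendering uses an epsilon guard
  (`floor(x·1000 + 0.5 + 10⁻⁹)/10`) against binary representation of
  values like 24.55.
* CSV schema: the literal token `unknown` for tri-states and an empty
  cell for unknown numerics, so that a missing value never collides
  with `absent` or zero; `read_cohort(write_cohort(x))` is the identity
  including unknowns. Lenient reads exclude invalid rows *and report
  them*; exclusions are never silent.
* Exit codes of the command-line interface: 0 success, 2 schema error,
  3 validation error, 4 infeasible cohort specification.
* Problem sizes in the test suite — the full 3^9 finding grid under two
  demographic settings and both policies, 2,000 simulated binomial
  draws for Wilson coverage at p = 0.9, n = 281, and 10,000-record
  generator calibration checks — were chosen as the smallest sizes at
  which the respective properties are exhaustive or statistically
  decisive (coverage asserted within 93–97%; prevalences within exact
  binomial bands at α = 0.001).

## Known limitations

* The engine reproduces a referral rule set; it is not a diagnostic
  model and produces no probability of disease beyond the optional
  registry-based post-test figure.
* The modifier-row semantics are an interpretation of tersely published
  criteria (see above); the switch `enable_modifier_basis` exists so
  users can disable the interpretation entirely.
* The validation cohort is one canonical member of the family of
  cohorts consistent with the published marginals; statistics that
  depend on the joint distribution of findings (anything beyond the
  verified marginal cells and headline results) should not be read off
  it.
* Published rater-agreement figures for this rule set were computed on
  rating data that were never printed; the package provides the kappa
  machinery but makes no claim of reproducing those figures.
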