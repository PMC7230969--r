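---
title: "Validating massive-transfusion prediction scores with hemoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating massive-transfusion prediction scores with hemoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscore)
```

## The problem

Uncontrolled hemorrhage is among the leading causes of early death after
severe trauma. A massive transfusion (MT) — here, as in most of the trauma
literature, ≥ 10 units of packed red blood cells within 24 h of
emergency-room arrival — must be anticipated, not reacted to: blood
products, damage-control resuscitation and theatre capacity all need lead
time. Clinical prediction scores condense vitals, labs, imaging and injury
pattern into a number available minutes after (or before) admission.
`hemoscore` implements six such scores and the machinery used to compare
their diagnostic accuracy on a severely injured cohort (ISS ≥ 16).

## The scores and their encoding

All rubrics are data, not code: `inst/extdata/score_definitions.json` holds
one entry per score, each a list of declarative criteria (field, comparator,
threshold, points) with a provenance note per non-obvious weight. The engine
(`apply_score()`, `score_cohort()`) evaluates criteria vectorized over the
cohort; criteria sharing a `group` tag are mutually exclusive bands (e.g.
the TASH hemoglobin bands), listed most-severe-first, and only the first
satisfied band scores. This keeps the five literature scores auditable —
their weights are transcribed from the primary publications, not scattered
through conditionals — and it makes the engine property-testable: the
package's test suite re-evaluates every criterion independently on 1,000
random records and compares the summed points to the engine output.

Two encoding choices deserve mention:

- **TASH fracture criteria** (unstable pelvic fracture, 6 points;
  open/dislocated femur fracture, 3 points) form a mutually exclusive group,
  which is what makes the published maximum of 28 attainable.
- **ETS event types** "traffic accident" (1 point) and "fall > 3 m"
  (1 point) are a mutually exclusive group, reproducing the published
  maximum of 9.5; a record can also satisfy no criterion, so the engine's
  minimum is 0.

### mTICCS specifics

mTICCS awards 2 points for general severity, 5 for any systolic blood
pressure below 90 mmHg, and 1/1/1/2/2/2 points for severe injury of
head-and-neck, upper extremity, lower extremity, torso, abdomen, and pelvis
(range 2–16). "Severe" is not given a numeric definition in the score's
description; `hemoscore` uses **AIS ≥ 3** — the conventional "serious"
boundary — in the mapped regions, configurable via `ais_severe_threshold`.
The AIS-region mapping is: head ∪ neck → head-and-neck, thorax → torso,
abdomen and pelvis direct, extremities direct; **face and external injuries
contribute to no mTICCS region**. Because a severely injured cohort is
treated in the resuscitation room by definition, the 2 general-severity
points are constitutive; `constitutive_general_severity = FALSE` restores
the original 0/2 behaviour driven by a `resus_admission` flag for
mixed-acuity cohorts.

### The TASH logistic transform

TASH ships with its published risk transform
p(MT) = 1/(1 + exp(4.9 − 0.3·score)). Score descriptions often state that
16 points correspond to a > 50% MT probability, but the published
coefficients give p(16) = 0.475; the crossing point of 0.5 is between 16 and
17. `hemoscore` encodes the published coefficients verbatim and documents
the discrepancy here rather than adjusting either number.

## The validation workflow

`run_validation()` reproduces the standard multi-score validation shape:

1. **Labelling.** `label_mt()` applies the ≥ 10-unit/24 h rule (threshold
   configurable, units of pRBC).
2. **Complete cases per score.** A record is excluded only from scores whose
   inputs it lacks (the engine returns the missing fields as the exclusion
   reason). This per-score complete-case policy is how multi-score
   validations are usually run and explains why denominators may differ
   between scores; exclusion counts are part of the report metadata.
3. **ROC/AUC.** The empirical ROC under the strict positivity rule
   "score > c". The AUC is the tie-corrected Mann–Whitney statistic,
   computed through DeLong placement values (mid-rank formulation,
   O(N log N)). Its 95% CI is normal on the **logit scale**, which keeps the
   interval inside (0, 1) — noticeable for small samples and high AUCs.
4. **Cut-off.** Youden's J = TPR − FPR maximized over the observed score
   values; ties go to the **smallest** cut-off. The tie-break is a design
   choice: it is deterministic and favours sensitivity, which is the right
   bias for a screening rule whose costly error is a missed bleeder.
5. **Operating-point metrics.** Confusion counts at the selected cut-off;
   prevalence, sensitivity and specificity with exact Clopper–Pearson
   intervals; PPV and NPV with the logit-method intervals of Mercaldo
   (variance expressed through sensitivity, specificity and the group
   sizes), the convention in MedCalc-style diagnostic output. Ratios with a
   zero denominator are reported as absent with a reason, never as 0.
6. **Paired AUC comparison.** Each non-reference score against the reference
   (default mTICCS) by DeLong's paired test on the intersection of their
   complete cases; the reference never appears in a self-comparison row.

All internal values are kept at full precision; rounding happens only in
`render_report()` (AUC to 3 decimals, sensitivity/specificity to 2, PPV/NPV
and CI bounds to 1, half-up), and only for the markdown rendering — JSON and
CSV serializations are full precision so round-trips lose nothing.

### Descriptives

`summarize_groups()` produces the usual baseline table: median (min–max)
with the Wilcoxon rank-sum test for continuous variables, % (n) with the
chi-square test for categorical ones. Two numerical choices: the Wilcoxon
routine uses exact enumeration when both groups have ≤ 10 observations and
no ties, otherwise the tie-corrected normal approximation with continuity
correction; and **Yates continuity correction is applied to all 2×2
tables** — on sparse tables (e.g. 18/421 vs 7/33 hypotensive patients) the
corrected and uncorrected p-values differ by a factor of ~3, and the
corrected value matches how such tables are conventionally reported. No
multiplicity adjustment is applied, matching exploratory usage. A variable
constant in both groups is reported with p = 1 (no rank or frequency
information) rather than NaN.

## The synthetic cohort generator

No patient-level trauma registry export can ship with a package, so
`generate_cohort()` draws cohorts with the statistical structure the
workflow assumes: a **single latent severity factor** z per patient. The MT
label is drawn first (default prevalence 0.084); then
z ~ N(0, 1) + `effect_size`·MT; and every score input — hypotension flags,
heart rate, hemoglobin, base excess, lactate, GCS, FAST/CT free fluid,
fracture flags, per-region AIS grades — follows a documented monotone link
to z. One factor driving everything is the simplest structure that makes all
six scores informative about MT simultaneously, which is exactly what the
ROC and ordering machinery needs to be exercised.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n` | 479 | typical single-centre severe-trauma cohort size |
| `mt_prevalence` | 0.084 | MT rate reported for ISS ≥ 16 cohorts (~8–9%) |
| `effect_size` | 1.5 | standardized severity shift placing score AUCs in the 0.65–0.80 band typical of MT scores |
| `male_fraction` | 0.706 | male predominance of severe trauma |
| `blunt_fraction` | 0.925 | European blunt-trauma predominance |
| `ais_severity_rates` | per region | baseline P(AIS ≥ 3) at average severity; head/thorax highest, face/external lowest |

pRBC counts are drawn conditional on the label (≥ 10 for MT, ≤ 9 otherwise)
so `label_mt()` reproduces the drawn label exactly. ISS/NISS are computed
from the AIS grades; records falling below ISS 16 have their
external-region AIS raised to 4 — a severity floor chosen because **no
score reads the external region**, so the cohort stays severely injured
without perturbing any score distribution. Everything derives from one PRNG
stream seeded by `config$seed`; equal seeds give byte-identical cohorts.

What the generator does **not** emulate: missing data (registries are
messier), correlations beyond the single factor (e.g. mechanism-specific
injury patterns), length-of-stay/ventilation marginals, and calibration of
absolute score distributions to any real cohort. Tests passing on synthetic
cohorts therefore demonstrate that the machinery is correct and that the
scores order patients by severity — not that any score achieves a
particular accuracy on real patients.

### The benchmark fixture

`fixture_cohort()` is a deterministic 479-patient cohort (40 MT) whose
mTICCS score distribution is placed so that the Youden-optimal cut-off is
uniquely 5 and the confusion matrix at "score > 5" is tp = 31, fp = 114,
fn = 9, tn = 325 (sensitivity 77.50%, specificity 74.03%, PPV 21.4%, NPV
97.3%, prevalence 8.35%). Crucially the fixture stores no scores: it
back-fills raw AIS and blood-pressure fields from per-score recipes so the
engine recomputes the targets end-to-end, making the fixture an integration
oracle for the whole pipeline rather than a lookup table.

## Numerical choices and degenerate inputs

- AUC of an all-tied score vector is exactly 0.5; perfect separation gives
  AUC 1 with a degenerate (point) CI.
- `delong_test()` of a score against itself (or any strictly increasing
  transform of itself) returns difference 0 and p = 1; the variance is
  floored at 0 against floating-point cancellation.
- Clopper–Pearson bounds are closed at 0 (x = 0) and 1 (x = n).
- Strict ">" positivity everywhere: a patient scoring exactly the cut-off
  is test-negative. Cut-off candidates are the observed score values.
- Booleans serialize as 0/1 in CSV; missing values as empty cells. Records
  missing essential fields (id, pRBC count) are dropped with a count in the
  load report in lenient mode and are fatal in strict mode; out-of-range
  values (GCS outside 3–15, AIS outside 0–6) are fatal only in strict mode.
- `sbp_ever_below_90` is reconciled with `sbp_initial < 90` at validation
  (coerced with a warning in lenient mode).
- ISS is recomputed from AIS at validation and mismatches warn rather than
  fail, since registries grade the two independently.

## Test design and problem sizes

The suite checks the statistics against independent oracles: brute-force
enumeration of all positive×negative pairs for the AUC (200 random
instances of n ≤ 20), exhaustive threshold search for the Youden cut-off
(200 instances), a 10,000-replicate stratified bootstrap for the DeLong
variance of an AUC difference (fixed n = 30 instance, 15% relative
agreement), exact permutation enumeration for the Wilcoxon p (n = 8 vs 7),
and `pROC` as an independent implementation of the AUC, its DeLong variance
and the paired test. Generator-level properties use cohorts of n = 2,000
(null AUC centred on 0.5 across 20 seeds; AUC strictly increasing in effect
size over {0, 0.5, 1, 2}) and n = 5,000 (binomial recovery of prevalence
and mix fractions, coverage across 10 seeds); these sizes give stable Monte
Carlo estimates while keeping the full suite under two minutes on one core.

## Limitations

- The five literature scores are encoded from their primary publications;
  variant definitions circulating in secondary sources (e.g. alternative
  TASH hemoglobin band boundaries) are not selectable.
- Only binary MT is modelled; no mortality, length-of-stay or
  critical-administration-threshold outcomes.
- No smoothed/binormal ROC, partial AUC, or bootstrap CIs in the analysis
  path (the bootstrap exists solely as a test oracle); no imputation of
  missing score inputs.
- PPV/NPV confidence intervals assume the cohort's prevalence; they do not
  transport to settings with a different MT rate.
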