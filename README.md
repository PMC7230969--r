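# hemoscore

Massive transfusion (MT) — at least 10 units of packed red blood cells
within 24 h of emergency-room arrival — is a rare but time-critical outcome
in severely injured trauma patients. Several bedside scores exist to flag
patients likely to need MT early enough to trigger damage-control
resuscitation. `hemoscore` implements six of them and the complete
diagnostic-accuracy workflow used to validate such scores against each
other, for biostatisticians and trauma researchers who want the whole
pipeline — score calculation, ROC comparison, operating-point selection,
descriptive group comparison — reproducible from a single cohort CSV.

## What it computes

**Scores** (rubrics shipped as auditable JSON configuration in
`inst/extdata/score_definitions.json`, weights transcribed from the primary
publications):

- **mTICCS** (modified Trauma-Induced Coagulopathy Clinical Score), range
  2–16: 2 points general severity (constitutive for resuscitation-room
  cohorts), 5 points if systolic blood pressure ever fell below 90 mmHg, and
  1/1/1/2/2/2 points for severe injury (AIS ≥ 3) of head-and-neck, upper
  extremity, lower extremity, torso, abdomen, pelvis.
- **TASH** (0–28, with the published logistic transform to an MT
  probability), **ABC** (0–4), **Larson** (0–4), **PWH** (0–18), **ETS**
  (0–9.5).

**Statistics**: empirical ROC with the strict positivity rule
"score > cut-off"; AUC as the tie-corrected Mann–Whitney statistic

&nbsp;&nbsp;&nbsp;&nbsp;AUC = (#{x⁺ > x⁻} + ½·#{x⁺ = x⁻}) / (n₁·n₀),

with variance and paired score-vs-score comparisons by DeLong's
placement-value method (two-sided normal p, CI on the logit scale); cut-off
selection by the Youden index J = max_c (TPR(c) − FPR(c)), smallest c on
ties; sensitivity/specificity/prevalence with exact Clopper–Pearson 95% CIs
and PPV/NPV with Mercaldo logit-method CIs; group descriptives by median
(range) + Wilcoxon rank-sum and % (n) + Yates-corrected chi-square.

**Data**: a fixed CSV column dictionary (`cohort_columns()`), a seedable
synthetic cohort generator with a single latent severity factor
(`generate_cohort()`), and a deterministic 479-patient benchmark fixture
(`fixture_cohort()`) whose raw fields reproduce a known operating point
end-to-end through the score engine.

## Worked example

```r
library(hemoscore)

cohort <- fixture_cohort()          # 479 patients, 40 MT
report <- run_validation(cohort, scores = "mticcs", reference = NA)
report
#> <validation report> 479 records (fixture), MT threshold 10 units
#>   mticcs  n=479  AUC 0.726 (0.644-0.795)  cut-off > 5  sens 77.50%  spec 74.03%

report$per_score$mticcs$summary
#> <diagnostic summary> n = 479 (tp 31, fp 114, fn 9, tn 325)
#>   prevalence     8.35%  (95% CI 6.0-11.2, clopper-pearson)
#>   sensitivity   77.50%  (95% CI 61.5-89.2, clopper-pearson)
#>   specificity   74.03%  (95% CI 69.7-78.1, clopper-pearson)
#>   ppv           21.38%  (95% CI 17.8-25.5, logit (mercaldo))
#>   npv           97.31%  (95% CI 95.3-98.5, logit (mercaldo))
```

Reading: of the 40 MT patients, 31 score above the Youden-selected cut-off
of 5 (sensitivity 77.5%); of the 439 others, 325 score at or below it
(specificity 74.0%). A positive screen carries a 21.4% MT risk, a negative
screen a 97.3% chance of no MT at a prevalence of 8.35%.

On a synthetic cohort all six scores run, with DeLong comparisons against a
reference:

```r
co <- generate_cohort(cohort_config(n = 2000, seed = 42))
run_validation(co, reference = "mticcs")
#> <validation report> 2000 records (synthetic), MT threshold 10 units
#>   mticcs  n=2000  AUC 0.793 (0.758-0.824)  cut-off > 5  sens 77.47%  spec 68.21%
#>   tash    n=2000  AUC 0.847 (0.816-0.873)  cut-off > 5  sens 74.73%  spec 80.20%
#>   ...
#>   pairwise DeLong vs mticcs:
#>     tash    dAUC +0.0539  p = 0.0005
#>     ...
```

Reports serialize to JSON/CSV (full precision) or markdown (printed
rounding) via `render_report()`; `plot_roc()` overlays the ROC curves. A
command-line front end with verbs `score | validate | describe | simulate |
fixture` lives at `inst/cli/hemoscore.R`:

```sh
Rscript inst/cli/hemoscore.R simulate --n 479 --prevalence 0.084 --seed 7 --out synth.csv
Rscript inst/cli/hemoscore.R validate --in synth.csv --reference mticcs --out report.json
```

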