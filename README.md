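# contextfuse

Multi-level cross-domain context fusion for behavior identification in R.

`contextfuse` turns raw, multimodal self-monitoring streams — activity,
location and emotion recognitions, food-item labels, blood glucose, blood
pressure and water-intake readings — into abstract, clinically meaningful
context. It targets digital-health settings (diabetes and hypertension
self-management in particular) where lifestyle feedback needs *fused*
context: what the user was doing, where, eating what, and in which health
state, and what that implies about their weekly behavior.

The pipeline has three levels:

1. **Low-level contexts (LLC).** Timestamped observations in seven
   categories (`Activity`, `Location`, `Emotion`, `Food`, `BloodGlucose`,
   `BloodPressure`, `WaterIntake`). Raw clinical readings are banded into
   labels (e.g. ≥ 315 mg/dL → `DangerouslyHighBG`; ≥ 160/100 mmHg →
   `HypertensionStageII`); readings falling in gaps of the banding tables
   get an `Unspecified` sentinel and never enter fusion.
2. **Vertical fusion (high-level contexts, HLC).** Concurrent LLCs of one
   user — interval overlap or starts within a 15 s sliding window, closed
   transitively — are grouped and instantiated as candidate contexts in
   three domains: physical activity (PA), nutrition (N) and clinical (C).
   Candidates are classified against declarative class definitions built
   from existential (`some`) and universal (`only`) restrictions, with
   closure applied automatically at classification time: an instance with
   `hasActivity: Eating`, `hasLocation: Restaurant`, `hasEmotion: Happiness`,
   `hasFood: FriedFood` is a member of the `Fats` nutrition class; a
   candidate matching no class is `Unidentified` with a reason code.
   Clinical candidates map each label to one of four health states and take
   the more severe state. Downstream consumers are notified only at
   change-points of the classified stream.
3. **Horizontal fusion (behavioral contexts).** Six conjunctive temporal
   rules of the form α₁ ∧ α₂ ∧ … ∧ αₙ → β, with duration, comparison and
   aggregation builtins (`makeSet`/`groupBy`/`size` style), run over a
   rolling 7-day window and label lifestyles: *Sedentary Behavior* (< 2 h
   of gym exercising a week), *Lightly / Moderately Active* (walking or
   running totals on all 7 days), *Very Active* (a 1–3 h session daily),
   *Extremely Active* (two such sessions a day) and *Meal Frequency*
   (> 2 eating events a day).

Everything the classifier and rule engine use — vocabularies (57 food items
in 10 groups, 6 blood glucose / 5 blood pressure / 3 water labels), the
8 PA + 3 N + 4 C class definitions, the banding tables and the rules — is
data, not code: a single YAML configuration (`load_config()`) that users can
override. A seeded synthetic cohort generator with construction-time ground
truth makes the whole pipeline testable without any real sensor data, and an
evaluation module scores predictions (15-class confusion matrix with an
`Unidentified` column, precision/recall/F).

## Worked example

```r
library(contextfuse)

cfg <- load_config()
cohort <- generate_cohort(6, 7, seed = 42)   # 6 users, one per archetype
run <- run_pipeline(cohort$llc, config = cfg, at = cohort$at,
                    truth_hlc = cohort$truth_hlc)
run$evaluation
#> <cf_evaluation>
#>   694 truth contexts, 694 predicted, 694 aligned
#>   accuracy 100.00%, misclassified 0.00%, unidentified 0.00%
#>   macro precision 1.000, recall 1.000, F 1.000
#>   recognized 694, communicated on change 560

dplyr::filter(run$behaviors, rule_id < 6)
#> # A tibble: 12 x 9
#>    user_id rule_id behavior             day  hours  days frequency ...
#>    u01     1       Sedentary Behavior   NA   1      1    NA
#>    u02     2       Lightly Active       NA   2.33   7    NA
#>    u03     3       Moderately Active    NA   3.5    7    NA
#>    u04     4       Very Active          NA   14     7    NA
#>    u05     4       Very Active          NA   21     7    NA
#>    u05     5       Extremely Active     11574 3     NA   2
#>    ...
```

On a clean stream every candidate is classifiable and the pipeline
reproduces the generator's ground truth exactly (100% accuracy, zero
`Unidentified`); only 560 of the 694 recognized contexts are communicated,
because notification happens on change. Injecting missingness degrades this
in the expected way — dropped mandatory LLCs surface as `Unidentified`
candidates with reason codes:

```r
degraded <- inject_missingness(cohort$llc, 0.1, seed = 7)
run2 <- run_pipeline(degraded, config = cfg, at = cohort$at,
                     truth_hlc = cohort$truth_hlc)
unidentified_report(run2$instances)
glance(run2$evaluation)          # broom-style one-row summary
autoplot(run2$evaluation)        # confusion-matrix heat map
```

A thin command-line interface wraps the same functions:

```sh
exec/contextfuse simulate --users 20 --days 7 --seed 42 --out cohort.csv
exec/contextfuse run --in cohort.csv --out classified.csv
exec/contextfuse export-rdf --in cohort.csv --dialect turtle
```

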