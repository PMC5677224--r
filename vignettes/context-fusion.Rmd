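---
title: "Multi-level context fusion: model, rules and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level context fusion: model, rules and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextfuse)
library(dplyr)
```

`contextfuse` infers abstract user context from heterogeneous self-monitoring
streams in three stages: clinical banding of raw readings, ontology-style
classification of concurrent observation bundles (vertical fusion), and a
temporal rule engine over the classified history (horizontal fusion). This
vignette is the package's own account of the model: what each stage assumes,
which parameters matter, where the design was genuinely open and what we
chose, and what the synthetic-data tests do and do not show about real data.

## The context model

The terminological content — vocabularies, class definitions, banding
tables, rules — lives in a single YAML configuration and is deliberately
separated from the event data, mirroring the T-Box / A-Box split of
ontology-backed systems. The packaged default carries:

```{r}
cfg <- load_config()
config_counts(cfg)
```

Seven low-level categories are modeled (`Activity`, `Location`, `Emotion`,
`Food`, `BloodGlucose`, `BloodPressure`, `WaterIntake`). The food
vocabulary has 57 items in 10 disjoint groups (Grain, Meat, SeaFood, Eggs,
MilkAndDairyProducts, Legumes, Nuts, Fruits, Vegetable, Snacks). The model
fixes the 10 group names, the 10 items of the `Fats` nutrition class and
Rice as a `Grain`; the remaining items are a USDA-style default list and are
explicitly replaceable — swap the `vocabulary$foods` map to use your own
food recognizer's vocabulary.

High-level contexts come in three domains: 8 physical-activity classes
(OfficeWork, HouseWork, Amusement, Gardening, Commuting, Sleeping,
Exercising, Inactivity), 3 nutrition classes by major nutrient
(Carbohydrates, Protein, Fats), and 4 clinical health states (Normal,
Moderate, HighRisk, VeryHighRisk).

## Clinical banding

Raw readings are banded by the tables in `labeling`:

```{r}
label_blood_glucose(c(50, 90, 150, 250, 330))
label_blood_pressure(c(118, 150, 165), c(78, 70, 102))
label_water_intake(c(1200, 2000, 2500))
```

Three decisions here were genuinely open:

* **Gaps.** The printed glucose bands leave exactly 70, 108–120, 180–215
  and 280–314 mg/dL uncovered. We refuse to invent boundaries: gap values
  get `UnspecifiedBG` (similarly `UnspecifiedBP`), are excluded from
  clinical fusion, and surface in the unconsumed-records report. The
  alternative — snapping to the nearest band — would silently fabricate
  clinical claims.
* **Discordant blood-pressure components.** The combined bounds (e.g.
  "≥ 160/100") do not say how a systolic and diastolic reading in different
  bands resolve. We band each component separately and return the more
  severe label (severity order LowBP < NormalBP < PreHypertension <
  HypertensionStageI < HypertensionStageII), the usual clinical convention;
  the banding tables are config, so the policy is swappable. Because the
  printed Low band (< 90/60) is a subset of the printed Normal band
  (≤ 120/80), bands are tested most-severe-first with Low before Normal —
  otherwise Low would be unreachable.
* **"Approximately 2000 mL".** Water intake splits strictly at the
  threshold: below → Dehydration, exactly at → NormalIntake, above →
  OverHydration. A tolerance band is available (`labeling$water$tolerance_ml`,
  default 0) for readers of "approx." who want one.

## Synchronization

Two records of one user are concurrent when their half-open intervals
overlap or their start times differ by at most `engine$window_seconds`
(default 15 s); grouping is the transitive closure of that relation,
computed by a single sorted sweep per user. Instantaneous readings are
length-zero intervals: a reading strictly inside an activity episode joins
it, one in a gap forms its own group, and two readings taken within the
window of each other group together. A group seeds up to three candidate
instances: physical activity (needs an Activity record), nutrition (needs
Food *and* an Eating activity), clinical (needs at least one labeled
glucose or pressure reading; water intake never triggers a clinical
candidate — the model lists it among the low-level categories but gives it
no clinical object property, so we treat it as non-triggering metadata).
When a group carries two records of one category the longest-interval
record wins, ties broken by earliest start — the underlying framework never
defines this case, so we chose the rule that preserves the dominant
observation.

## Vertical fusion: classification with closure

A class definition has existential restrictions (the property must be
asserted with a value from the witness set — these are mandatory) and
universal restrictions (every asserted value must come from the allowed
set). Ontology reasoners work under the open-world assumption and need
explicit per-instance closure axioms ("only …") before such definitions
classify anything; this package applies that closure automatically at
classification time — each asserted value is treated as the complete value
set of its property — reproducing the effective behavior without a general
description-logic reasoner (deliberately: no tableau algorithm, no TBox
subsumption beyond the configured definitions).

```{r}
meal <- tibble::tibble(
  instance_id = "ex", user_id = "Bob", domain = "N", group_id = "g",
  activity = "Eating", location = "Restaurant", emotion = "Happiness",
  food = "FriedFood", blood_glucose = NA_character_,
  blood_pressure = NA_character_, start = 0, end = 1800,
  source_ids = list(integer())
)
classify_hlc(meal, cfg)[, c("domain", "inferred_class")]
```

Design decisions in this stage:

* **The nutrition food sets.** `Fats` carries the model's fixed 10-item
  list. `Carbohydrates` and `Protein` are derived from the 10-group map by
  major nutrient (Grain/Fruits/Vegetable/Snacks → Carbohydrates;
  Meat/SeaFood/Eggs/Legumes/Nuts → Protein), minus the items the model
  already claims for Fats. MilkAndDairyProducts is not named by either
  side of that mapping; we default the remaining dairy items (Cheese,
  Yogurt, Butter, Cream) to Protein. The three sets partition the 57 items,
  which is what makes nutrition classification unique.
* **The physical-activity axioms.** The 8 PA definitions are package
  defaults with pairwise-disjoint activity witness sets (so no instance can
  match two siblings) and per-class location sets; they are marked
  swappable in the config. Eating is covered by `Inactivity` (locations
  Home/Office/Restaurant), so a restaurant meal yields both an Inactivity
  PA context and a nutrition context from the same concurrent group.
* **Mandatory location.** PA and N definitions make `hasLocation`
  existential (the nutrition definitions in the model carry
  `hasLocation some (Home or Office or Restaurant)`), so a candidate whose
  location record was lost classifies as `Unidentified` with reason
  `missing:hasLocation` — this is precisely the accounting that the
  unidentified-context report exposes.
* **Clinical states as a severity map.** The four clinical classes are an
  OR-over-properties with severity-max (e.g. DangerouslyHighBG *or*
  HypertensionStageII → VeryHighRiskHealthState), which does not fit
  conjunctive existential/universal semantics; they are implemented as a
  label→state map in `clinical` with the more severe state winning. LowBG
  and LowBP are not named by the source material's state assignments; both
  default to ModerateHealthState so that every labeled reading maps to a
  state.

Classification is deterministic, order-independent across the definition
list, and raises an error if two sibling classes ever match one instance
(that indicates an inconsistent definition set, and the loader's structural
disjointness check should have caught it). `classify_stream()` adds the
notifier semantics: an instance is communicated only when its class differs
from the user's previous class in the same domain, so consumers see
change-points rather than every recognition.

## Horizontal fusion: the rule engine

Rules are conjunctive antecedents over the classified history with
builtins, evaluated per user over a rolling window of
`engine$horizontal_window_days` (default 7) days ending at the evaluation
time, in three phases faithful to the source query language: pattern
matching binds rows, aggregations build per-group values, comparisons
filter. Semantics that needed a decision:

* **Join semantics.** A rule with no matching context rows yields nothing:
  a user who never exercised is *not* labeled sedentary. Sedentary
  Behavior here means "exercised, but less than two hours that week".
* **Weekly totals vs per-session durations.** Rules 1–3 compare the *sum*
  of matched exercising hours in the window ("less than two hours in a
  week" is a weekly total); rules 4–5 filter *each session's* duration into
  the 1–3 h band before counting days or sessions ("performed daily",
  "twice a day" describe session intensity).
* **Day counting.** The day-level variables (`?d`, `?no_of_days`, per-day
  groups) count distinct user-local calendar days touched by the matched
  contexts. The printed rules compute days with the same duration builtin
  as hours, but a continuous day-span can never exactly equal 7 on real
  streams, which would make the "performed daily" and "on all 7 days"
  equalities unsatisfiable; distinct-day counting is the reading under
  which they mean what the prose says. The `temporal_duration()` builtin
  itself keeps continuous semantics (`(end - start) / 86400`). Calendar
  days honor a per-user timezone offset (`tz_offset`, default UTC).
* **Under-specified atoms.** The sedentary rule attaches the gym location
  to the user; we read it as "the Exercising context occurred at Loc_Gym".
  The meal-frequency rule groups by a variable never bound in its
  antecedent; we read it as grouping Eating activities per user and day,
  reporting each qualifying day with its frequency.

All six rules live in the config as ordered atom lists, and the engine's
results are checked against an independent nested-loop join evaluator in
the test suite.

## The synthetic cohort and what the tests show

`generate_cohort()` emulates a multi-user, multi-week self-monitoring
collection at desk scale. The study conditions are fixed in the generator's
defaults: 20 users × 7 days in the closure test; six archetypes cycled
across users (sedentary, lightly/moderately/very/extremely active,
irregular eater) whose exercise schedules are built to land on the six
behavioral rules; three meals a day (five for the irregular eater) cycling
through foods of all three nutrient classes; one fasting and one evening
clinical sampling per day, with values drawn from per-archetype normal
distributions truncated to the interior of a fixed clinical band (so the
intended label is known by construction); a daily accumulated water
reading; missingness 0 by default. Ground truth comes from construction —
the schedule knows each episode's class, each meal's nutrient and each
sampling's health state — and behavioral truth is a direct tally over the
schedule, independent of the rule engine under test.

The central property is **clean-stream closure**: on an undegraded cohort
the pipeline reproduces the generator's ground truth exactly — 100%
accuracy, zero `Unidentified`, behavioral labels identical to the tally.
`inject_missingness()` then degrades the stream record-wise
(independent Bernoulli drops, seeded), and the unidentified report must
equal an independent recount. Problem sizes in the shipped tests — a
20 × 7 cohort (~5,800 records, ~2,300 contexts), 10,000 random instances
for the classifier oracle, 100 random fact bases for the rule-engine
oracle — were chosen as the smallest sizes at which every code path and
every rule fires repeatedly.

What this does **not** show: the synthetic streams are far more regular
than real sensor output (no recognition errors, no label noise, no
overlapping or missing episodes beyond the injected Bernoulli drops, no
circadian variation in clinical values), so closure certifies the fusion
machinery, not real-world recognition accuracy. Published accuracies from
the original 20-volunteer collection (92.65% recognized, 7.35%
unclassified) depend on that unavailable dataset and are deliberately not
reproduction targets; the package replaces them with the closure and
oracle properties, the missingness sweep, and the structural guarantee
that communicated ≤ recognized contexts on any stream.

## Numerical and degenerate-input choices

* Timestamps are epoch seconds; intervals are half-open `[start, end)`;
  instantaneous readings have `end == start`.
* Banding uses the printed strict/closed inequalities verbatim; sweeps at
  integer resolution are part of the test suite.
* Empty inputs flow through every stage without error (empty log → empty
  instances → empty behaviors).
* Ties: equal-timestamp records are grouped identically under any input
  permutation; duplicate-category resolution breaks ties by earliest start,
  then label.
* The RDF export (Turtle/N-Triples under a single package-owned IRI
  prefix) sorts triples canonically, so export → import → export is
  byte-identical; it is an export format, not the processing substrate —
  the canonical inter-stage format is the tibble/CSV/JSON-lines record log.

## Known limitations

* Not a description-logic reasoner: subsumption between configured classes,
  complement classes and cross-property axioms are out of scope; the
  closure semantics assume single-valued properties per instance.
* The rule engine executes the builtin vocabulary the six rules need
  (duration, comparisons, distinct-day and per-day-count aggregation), not
  arbitrary rule programs, and supports no negation-as-failure.
* The physical-activity class axioms and the dairy nutrient assignment are
  package defaults, clearly marked replaceable in the config.
* Per-user timezone handling is a fixed offset, not a tz database lookup;
  daylight-saving transitions will shift day boundaries by an hour.
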