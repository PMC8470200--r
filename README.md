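# wearkg

Knowledge-graph based detection of health-related events from wearable
lifestyle data.

Consumer wearables export per-minute step counts, per-minute heart rate and
session-structured sleep records (stage minutes, awakenings, time to fall
asleep). Clinicians monitoring chronic conditions want more than raw charts:
they want named, explainable events — *Lack of Sleep*, *Increased Napping*,
*Inactivity* — each traceable back to the measurements that triggered it.
`wearkg` implements that pipeline symbolically:

1. **Observation model.** Every measurement becomes a SOSA-style observation
   `o` with a feature of interest `F ∈ {movement, sleep, heart}`, an observed
   property `P` (steps, heart_rate, asleep_duration, efficiency, ...), a
   numeric result and a half-open minute interval. A finite axiom hierarchy
   classifies observations by forward evaluation of class definitions of the
   form

       MovementObservation ≡ Observation ⊓ ∃observedProperty.MovementProperty
                                         ⊓ ∃hasFeatureOfInterest.{movement}
       WalkingFeature      ≡ MovementObservation
                                         ⊓ ∃observedProperty.{distance, elevation, floors, steps}

   Because every axiom is an intersection of nominals and one-property
   existentials, forward evaluation is semantically exact — no external
   reasoner is needed.

2. **Rule base.** Twelve rules with strict comparisons detect problems:
   daily aggregates (time to fall asleep in a day > 1800 s → Insomnia;
   interruptions > 10 → Restlessness; sleep > 480 min / < 300 min; nap
   minutes > 100; a nap ending < 120 min before the main sleep; session
   efficiency < 85 %; daily steps < 8000), per-minute runs (HR < 60 bpm →
   Low Heart Rate), and composite step/heart-rate windows (maximal runs of
   minutes with HR beyond a per-minute limit, qualified by a cumulative step
   limit and a strict minimum duration, e.g. steps < 1000 & HR < 80 for
   > 300 min → Inactivity). Thresholds are per-subject configurable.

3. **Situations.** Each detection is materialised with the
   Descriptions-and-Situations pattern: the problem (a `dul:Situation`) has
   a view (a `dul:Description`) whose concepts classify the observed
   properties, and interprets the contributing observations. Problems map
   onto Web Annotation Data Model records (views → bodies, observations →
   targets) and the whole graph serializes to Turtle or JSON-LD.

A seed-reproducible synthetic generator produces compliant subjects and can
inject episodes that provably satisfy each rule, so the full pipeline is
testable without device data. A benchmark harness measures ingestion and
rule-evaluation scaling.

## Worked example

```r
library(wearkg)

# two days of a compliant synthetic subject, then force one short night
data <- generate_subject_days(synthetic_profile(), n_days = 2, seed = 42)
data <- inject_problem_episode(data, "LackOfSleep", "2021-03-02")

res <- run_rulebase(data$steps, data$hr, data$sessions)
length(res$problems)
#> [1] 1
res$problems[[1]]
#> <problem_situation> LackOfSleep [SleepProblem] tms6  2021-03-02T00:00:00 .. 2021-03-03T00:00:00  (2 observations)

res$aggregates[["2021-03-02"]]$sleep_minutes
#> [1] 295
validate_descriptive_context(res$graph)      # zero rows: structurally valid
#> [1] problem_id check      message
#> <0 rows> (or 0-length row.names)
export_wadm(res$problems[[1]])$targets
#> [[1]]
#> [1] "ms:obs-tms6-asleep_duration-20210301T230000"
#>
#> [[2]]
#> [1] "ms:obs-tms6-asleep_duration-20210302T133000"
```

The injected short night leaves the day with 295 asleep minutes (260 from
the night plus a 35-minute nap), under the strict `< 300` limit, so a
`LackOfSleep` situation is emitted whose view defines *sleep* as a concept
classifying *asleep_duration* and which interprets both of the day's
sleep-duration observations; the annotation export targets exactly those
observations.

From a shell, the same pipeline runs as:

```sh
Rscript inst/cli/wearkg.R simulate --days 2 --seed 42 \
    --inject LackOfSleep:2021-03-02 --out-dir data/
Rscript inst/cli/wearkg.R detect --steps data/steps.csv --hr data/hr.csv \
    --sleep data/sleep.json --out-dir out/
```

which writes `problems.json`, `graph.ttl`, `annotations.jsonld` and
`report.json`.

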