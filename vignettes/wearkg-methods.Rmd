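---
title: "Symbolic detection of health-related events from wearable data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic detection of health-related events from wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearkg)
```

## The model

`wearkg` turns wearable exports into an RDF knowledge graph of *observations*
and enriches it with *problem situations* derived by a symbolic rule base.
The design separates three concerns:

* **What was measured** — the observation layer. Each per-minute sample and
  each sleep-session-derived quantity becomes one observation with a feature
  of interest (`movement`, `sleep` or `heart`), an observed property from an
  18-term controlled vocabulary, a numeric result and a half-open interval
  `[start, end)`. Instantaneous samples get one-minute intervals.
* **What kind of measurement it is** — the classification layer. Observation
  classes are defined by equivalence axioms that intersect a feature nominal
  with an enumerated property set (e.g. a movement observation whose property
  is one of *distance, elevation, floors, steps* is a `WalkingFeature`).
  Because every axiom uses only nominals and one-property existential
  restrictions over a finite vocabulary, membership is decidable by direct
  predicate evaluation; the package evaluates all fourteen class predicates
  forward and closes the result under the class hierarchy. This is
  semantically identical to running a tableau reasoner on these axioms while
  keeping the dependency footprint at zero.
* **What the measurements mean** — the situation layer. A detection is not a
  bare flag: following the Descriptions-and-Situations pattern, the problem
  node is a situation that *has a view* (its descriptive context), the view
  *defines* one concept per feature of interest involved, each concept
  *classifies* the observed-property entities, and the problem *interprets*
  every contributing observation. The linking properties are subproperties
  of the upper-ontology relations, and the package materialises the
  entailed `dul:satisfies` / `dul:isSettingFor` triples so downstream
  SPARQL over the generic vocabulary works without inference.

## The rule base

Twelve rules, all with **strict** comparisons — a value exactly at a limit
never fires. Defaults:

| Problem | Scope | Condition |
|---|---|---|
| Insomnia | day | seconds to fall asleep > 1800 |
| Restlessness | day | awakenings > 10 |
| TooMuchSleep | day | asleep minutes > 480 |
| LackOfSleep | day | asleep minutes < 300 |
| IncreasedNapping | day | nap asleep minutes > 100 |
| NapCloseToBedtime | day | nap-to-main-sleep gap in [0, 120) min |
| LowSleepQuality | session | efficiency < 85 % |
| LackOfExercise | day | steps < 8000 |
| LowHeartRate | run | per-minute HR < 60 bpm |
| StressOrPain | window | steps < 50 & HR > 90 for > 300 min |
| Inactivity | window | steps < 1000 & HR < 80 for > 300 min |
| LackOfMovement | window | steps < 500 & HR < 100 for > 800 min |

Interpretation choices the table itself leaves open, and how this package
resolves them:

* **Day attribution.** Samples belong to the calendar date of their
  timestamp; a sleep session belongs to the date it *ends* on, so the usual
  23:00–06:30 night counts toward the morning's day. Missing sleep data is
  non-adherence, not zero sleep: sleep rules are skipped on days without
  sessions, and the step rule on days without step samples.
* **Naps.** An explicit main-sleep flag wins; otherwise the day's session
  with the most asleep minutes is main sleep (tie: earliest start) and all
  others are naps. The nap-to-bedtime gap is measured from a nap's end to
  the next main-sleep start anywhere in the record, because that start
  usually belongs to the next day's session.
* **Composite windows.** The step condition is *cumulative* over the window
  while the HR condition is *per minute*. Per-minute step counts rarely
  approach 500–1000, so a per-minute reading would make those limits
  vacuous; the cumulative reading keeps them meaningful. A window is a
  *maximal* run of minutes each carrying an HR sample that satisfies the
  comparison — a missing minute breaks the run — and qualifies only if the
  run is strictly longer than the duration limit and its step total
  satisfies the step comparison.
* **Waking-only composite windows.** The three composite rules are evaluated
  with sleep-session minutes removed from both streams. Sleeping heart rate
  sits in the 60s with zero steps for around eight hours, so a literal
  full-stream reading would flag Inactivity on every physiologically normal
  night; the composite rules describe *waking* behaviour, while sleep has
  its own rule family. The low-heart-rate rule stays on the full stream,
  since nocturnal bradycardia is exactly what it is meant to surface.
* **Insomnia units.** Minutes-to-fall-asleep are summed over the day's
  sessions and converted to seconds (the limit is printed in seconds).
* **Sleep efficiency** is `100 × asleep / in-bed` per session, rounded to
  the nearest integer with ties away from zero, matching the integer limit.
* **Per-subject thresholds** are overridable in the rulebase config; the
  table above provides the defaults. A nap-*count* variant of
  IncreasedNapping is exposed in the config without a default.
* **Ordering.** Problems are emitted sorted by (date, type, start), and all
  generated IRIs are deterministic compositions of (subject, type, interval
  start), so a rerun is byte-identical.

The rule base also exports as a SHACL-SPARQL document: daily rules carry a
CONSTRUCT body producing the situation shape under the rule's numeric
filter; the composite rules' maximal-run semantics exceed a single SPARQL
pattern, so their export shows the per-observation filters with an
explanatory comment and the native engine remains authoritative.

## The synthetic generator

There is no public dataset with this exact stream structure, so the
generator is parametric and its defaults describe a *compliant* subject —
the study condition under which the detector should stay silent:

* In bed 23:00–06:30 (450 min); 5–20 min to fall asleep; 10–35 awake
  minutes; at most 9 awakenings. Nightly asleep minutes therefore fall in
  roughly 395–435 and efficiency stays above 85 %.
* 12–16 ten-minute walking bouts per day, one per fully-waking hour block,
  at 50–90 steps/min over a 3 steps/min sedentary base: daily totals around
  11,000 and never below ~8,500, comfortably past the 8,000 limit.
* Waking heart rate 84 ± 5 bpm clamped to [76, 100], with bouts at
  112 ± 8 clamped to [95, 135]; sleeping heart rate 66 ± 2 clamped to
  [62, 74]. The clamps guarantee no sub-60 minute ever occurs, and the
  hourly bouts break any long sub-80 waking run.
* A midday nap on 15 % of days, 20–40 minutes, ending hours before bedtime.

Every draw is governed by one integer seed; identical seeds give identical
byte output. `inject_problem_episode()` rewrites a single day so that one
rule's condition provably holds — e.g. 40 min to fall asleep (2400 s) for
Insomnia, a 310-minute zero-step block at 72 bpm bracketed by two 88 bpm
boundary minutes for Inactivity. The boundary minutes pin the maximal run
to the injected block, and the composite templates first remove the day's
naps, whose masked minutes would otherwise split the run. Injections touch
only the injected day, so detections elsewhere are unchanged. An injected
day may trip neighbouring rules as a side effect (a long stress window also
suppresses the day's step total); the guarantee is that the target rule
fires, which the tests assert across 100 seeds per type.

What the generator does *not* emulate: device dropout, heart-rate artefacts,
shift-work or split-sleep schedules, seasonal trends, or any distributional
fidelity to a real cohort. Passing tests therefore demonstrate the
correctness of the symbolic machinery on well-formed inputs, not clinical
performance on real patients.

## Numerical and degenerate-input choices

* Timestamps are minute-resolution instants in a single implicit timezone;
  intervals are half-open, so consecutive minutes never overlap.
* Duplicate timestamps, negative values and malformed rows are rejected at
  parse time with the offending row; streams are sorted before validation,
  which never changes the sample multiset.
* An empty input file is a valid empty stream; a day context with no
  sessions yields a "no sleep data" aggregate rather than zeros.
* Stage minutes may exceed the in-bed interval by at most one minute, which
  absorbs the rounding of device exports.
* Knowledge-graph triple addition has set semantics (idempotent adds);
  serialization orders triples lexicographically, so equal graphs produce
  byte-identical documents in both Turtle and JSON-LD.

## Scalability harness

Task 1 measures graph-construction time for increasing observation counts;
Task 2 measures per-rule evaluation time and generated-object counts for
nested, day-aligned prefixes of one synthetic dataset with injected
episodes. Day alignment makes the generated counts provably non-decreasing
in the prefix size, which is the structural property the tests assert;
wall-clock milliseconds are reported but never asserted, since they are
hardware-dependent. The shipped tests and the acceptance script use sizes
up to four days of per-minute data (about 12,000 observations), which keeps
the whole suite within a few minutes on a single core while still
exercising three prefix levels; larger sweeps are a parameter away.

## Known limitations

* The classifier is exact only for the axiom family it implements
  (feature nominal × enumerated property sets); arbitrary OWL class
  expressions are out of scope by design.
* The exported SHACL document is for interoperability and inspection; the
  package does not embed a SPARQL engine to execute it, and the composite
  rules cannot be expressed in a single CONSTRUCT anyway.
* Streaming/real-time evaluation is not supported; the engine is batch.
* The nap-to-bedtime rule needs a following main sleep to measure against;
  a nap on the final day of a record cannot fire it.
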