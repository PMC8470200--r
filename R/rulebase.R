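# The a-priori rule base: 12 rules with per-individual threshold overrides.
# Daily rules compare aggregates computed over one calendar day; window rules
# search for maximal runs of minutes whose heart-rate samples satisfy a
# per-minute comparison while the cumulative step count over the run
# satisfies a step comparison; the low-heart-rate rule flags every maximal
# run of sub-threshold heart-rate minutes. All comparisons are strict.

daily_rule <- function(problem_type, variable, comparator, threshold, unit,
                       scope = "daily") {
  list(problem_type = problem_type, scope = scope, variable = variable,
       comparator = comparator, threshold = threshold, unit = unit)
}

window_rule <- function(problem_type, steps_comparator, steps_threshold,
                        hr_comparator, hr_threshold, window_min_duration) {
  list(problem_type = problem_type, scope = "window",
       steps_comparator = steps_comparator, steps_threshold = steps_threshold,
       hr_comparator = hr_comparator, hr_threshold = hr_threshold,
       window_min_duration = window_min_duration, unit = "minutes")
}

#' The default rule base
#'
#' Default thresholds of the 12 rules: time to fall asleep in a day
#' > 1800 s (Insomnia); sleep interruptions in a day > 10 (Restlessness);
#' total sleep in a day > 480 min (TooMuchSleep) or < 300 min (LackOfSleep);
#' nap minutes in a day > 100 (IncreasedNapping); a nap ending < 120 min
#' before the main sleep start (NapCloseToBedtime); session sleep efficiency
#' < 85 % (LowSleepQuality); daily steps < 8000 (LackOfExercise); per-minute
#' heart rate < 60 bpm (LowHeartRate); and three composite step/heart-rate
#' window rules: steps < 50 with HR > 90 for > 300 min (StressOrPain),
#' steps < 1000 with HR < 80 for > 300 min (Inactivity), steps < 500 with
#' HR < 100 for > 800 min (LackOfMovement). Step conditions in composite
#' rules are cumulative over the window; HR conditions are per minute.
#'
#' @return An object of class `rulebase`: `rules` (named list of rule specs)
#'   and `overrides` (per-subject threshold overrides, empty by default).
#' @export
default_rulebase <- function() {
  rules <- list(
    Insomnia = daily_rule("Insomnia", "fall_asleep_seconds", ">", 1800, "seconds"),
    Restlessness = daily_rule("Restlessness", "interruptions", ">", 10, "count"),
    TooMuchSleep = daily_rule("TooMuchSleep", "sleep_minutes", ">", 480, "minutes"),
    LackOfSleep = daily_rule("LackOfSleep", "sleep_minutes", "<", 300, "minutes"),
    IncreasedNapping = daily_rule("IncreasedNapping", "nap_minutes", ">", 100, "minutes"),
    NapCloseToBedtime = daily_rule("NapCloseToBedtime", "nap_to_bed_gap_minutes",
                                   "<", 120, "minutes"),
    LowSleepQuality = daily_rule("LowSleepQuality", "efficiency", "<", 85,
                                 "percent", scope = "session"),
    LackOfExercise = daily_rule("LackOfExercise", "steps", "<", 8000, "steps"),
    LowHeartRate = daily_rule("LowHeartRate", "heart_rate", "<", 60, "bpm",
                              scope = "per_reading_run"),
    StressOrPain = window_rule("StressOrPain", "<", 50, ">", 90, 300),
    Inactivity = window_rule("Inactivity", "<", 1000, "<", 80, 300),
    LackOfMovement = window_rule("LackOfMovement", "<", 500, "<", 100, 800)
  )
  structure(list(rules = rules, overrides = list(),
                 # optional nap-count variant of IncreasedNapping: no default
                 nap_count_threshold = NULL),
            class = "rulebase")
}

#' Resolve per-subject threshold overrides
#'
#' Deployments tune thresholds per monitored individual; overrides are stored
#' as `overrides[[subject_id]][[problem_type]] = list(threshold = ...)`
#' (window rules may override `steps_threshold`, `hr_threshold` and
#' `window_min_duration`).
#'
#' @param rulebase A `rulebase`.
#' @param subject_id Subject identifier.
#' @return The effective rule list for the subject.
#' @export
rulebase_for_subject <- function(rulebase, subject_id) {
  rules <- rulebase$rules
  ov <- rulebase$overrides[[subject_id]]
  for (pt in names(ov)) {
    wkg_stopifnot(pt %in% names(rules), paste0("unknown rule id: ", pt))
    rules[[pt]] <- utils::modifyList(rules[[pt]], ov[[pt]])
  }
  rules
}

#' Read a rule base from YAML or JSON
#'
#' The file may carry `rules` (partial: named by problem type, fields to
#' override on the defaults) and `overrides` (per-subject blocks).
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `rulebase`.
#' @export
read_rulebase <- function(path) {
  wkg_stopifnot(file.exists(path), paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  rb <- default_rulebase()
  for (pt in names(cfg$rules)) {
    wkg_stopifnot(pt %in% names(rb$rules), paste0("unknown rule id: ", pt))
    rb$rules[[pt]] <- utils::modifyList(rb$rules[[pt]], cfg$rules[[pt]])
  }
  rb$overrides <- cfg$overrides %||% list()
  rb$nap_count_threshold <- cfg$nap_count_threshold %||% NULL
  rb
}

#' Write a rule base to YAML
#' @param rulebase A `rulebase`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rulebase <- function(rulebase, path) {
  yaml::write_yaml(list(rules = rulebase$rules,
                        overrides = rulebase$overrides), path)
  invisible(path)
}

shacl_daily_bodies <- function(rule) {
  # WHERE clause matching SOSA observations feeding the rule, with the
  # numeric filter; CONSTRUCT produces the DnS problem shape.
  prop <- switch(rule$problem_type,
                 Insomnia = "minutes_to_fall_asleep",
                 Restlessness = "awake_count",
                 TooMuchSleep = "asleep_duration",
                 LackOfSleep = "asleep_duration",
                 IncreasedNapping = "asleep_duration",
                 NapCloseToBedtime = "asleep_duration",
                 LowSleepQuality = "efficiency",
                 LackOfExercise = "steps",
                 LowHeartRate = "heart_rate")
  feature <- if (prop %in% c("steps")) "movement"
             else if (prop == "heart_rate") "heart" else "sleep"
  filt <- if (rule$problem_type == "Insomnia") {
    sprintf("FILTER((SUM(?r) * 60) %s %s)", rule$comparator, rule$threshold)
  } else {
    sprintf("FILTER(?agg %s %s)", rule$comparator, rule$threshold)
  }
  construct <- paste(
    "CONSTRUCT {",
    sprintf("  ?p rdf:type em:%s .", rule$problem_type),
    "  ?p rdf:type ms:Problem .",
    "  ?p rdf:type dul:Situation .",
    "  ?p em:hasView ?v .",
    "  ?p dul:satisfies ?v .",
    "  ?p em:interprets ?obs .",
    "  ?p dul:isSettingFor ?obs .",
    "  ?v rdf:type ms:View .",
    "  ?v rdf:type dul:Description .",
    sprintf("  ?v dul:defines ms:%s .", feature),
    sprintf("  ms:%s rdf:type dul:Concept .", feature),
    sprintf("  ms:%s dul:classifies ms:%s .", feature, prop),
    "} WHERE {",
    "  SELECT ?obs (SUM(?r) AS ?agg) WHERE {",
    "    ?obs rdf:type sosa:Observation .",
    sprintf("    ?obs sosa:observedProperty ms:%s .", prop),
    sprintf("    ?obs sosa:hasFeatureOfInterest ms:%s .", feature),
    "    ?obs sosa:hasSimpleResult ?r .",
    "    ?obs em:hasStartTime ?t .",
    "  } GROUP BY (day(?t) AS ?day) ?obs",
    sprintf("  %s", filt),
    "}",
    sep = "\n")
  construct
}

shacl_window_body <- function(rule) {
  paste(
    "CONSTRUCT {",
    sprintf("  ?p rdf:type em:%s .", rule$problem_type),
    "  ?p rdf:type ms:Problem .",
    "  ?p rdf:type dul:Situation .",
    "  ?p em:hasView ?v .",
    "  ?p dul:satisfies ?v .",
    "  ?p em:interprets ?hrObs .",
    "  ?p em:interprets ?stepObs .",
    "  ?p dul:isSettingFor ?hrObs .",
    "  ?p dul:isSettingFor ?stepObs .",
    "  ?v rdf:type ms:View .",
    "  ?v rdf:type dul:Description .",
    "  ?v dul:defines ms:movement .",
    "  ?v dul:defines ms:heart .",
    "  ms:movement rdf:type dul:Concept .",
    "  ms:heart rdf:type dul:Concept .",
    "  ms:movement dul:classifies ms:steps .",
    "  ms:heart dul:classifies ms:heart_rate .",
    "} WHERE {",
    "  ?hrObs rdf:type sosa:Observation .",
    "  ?hrObs sosa:observedProperty ms:heart_rate .",
    "  ?hrObs sosa:hasSimpleResult ?hr .",
    sprintf("  FILTER(?hr %s %s)", rule$hr_comparator, rule$hr_threshold),
    "  ?stepObs rdf:type sosa:Observation .",
    "  ?stepObs sosa:observedProperty ms:steps .",
    "  ?stepObs sosa:hasSimpleResult ?steps .",
    sprintf("  # cumulative over the maximal run: SUM(?steps) %s %s, run > %s min",
            rule$steps_comparator, rule$steps_threshold,
            rule$window_min_duration),
    "}",
    sep = "\n")
}

#' Export the rule base as a SHACL-SPARQL rule document
#'
#' Produces one `sh:SPARQLRule` per daily/session rule, with a CONSTRUCT
#' body generating the DnS problem shape (problem node typed with the
#' problem class, view/defines/classifies/interprets triples) and a WHERE
#' clause matching SOSA observations under the rule's numeric filter.
#' Window-scope rules exceed a single SPARQL pattern (they need maximal-run
#' temporal aggregation), so they are exported as explanatory comments; the
#' native engine remains authoritative for them.
#'
#' @param rulebase A `rulebase`.
#' @return Turtle text.
#' @export
export_shacl_rules <- function(rulebase) {
  ns <- wkg_namespaces()
  out <- c(sprintf("@prefix %s: <%s> .", names(ns), ns), "")
  for (rule in rulebase$rules) {
    pt <- rule$problem_type
    shape <- sprintf("em:%sRuleShape", pt)
    rnode <- sprintf("em:%sRule", pt)
    if (identical(rule$scope, "window")) {
      out <- c(out,
        sprintf("# %s: window-scope rule (cumulative steps %s %s, per-minute HR %s %s,",
                pt, rule$steps_comparator, rule$steps_threshold,
                rule$hr_comparator, rule$hr_threshold),
        sprintf("#   maximal-run duration > %s min). The maximal-run temporal semantics",
                rule$window_min_duration),
        "#   exceed a single SPARQL graph pattern; the CONSTRUCT below shows the",
        "#   per-observation filters, and the native engine remains authoritative.",
        sprintf("%s rdf:type sh:NodeShape .", shape),
        sprintf("%s sh:targetClass sosa:Observation .", shape),
        sprintf("%s sh:rule %s .", shape, rnode),
        sprintf("%s rdf:type sh:SPARQLRule .", rnode),
        sprintf("%s sh:construct \"%s\" .", rnode,
                ttl_escape(shacl_window_body(rule))),
        "")
      next
    }
    out <- c(out,
      sprintf("%s rdf:type sh:NodeShape .", shape),
      sprintf("%s sh:targetClass sosa:Observation .", shape),
      sprintf("%s sh:rule %s .", shape, rnode),
      sprintf("%s rdf:type sh:SPARQLRule .", rnode),
      sprintf("%s sh:construct \"%s\" .", rnode,
              ttl_escape(shacl_daily_bodies(rule))),
      "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
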