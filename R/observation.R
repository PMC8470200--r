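# SOSA-style observation model: typed inputs become observation records with
# a feature of interest (movement / sleep / heart), an observed property from
# a fixed controlled vocabulary, a numeric result and a half-open minute
# interval. A finite hierarchy of class axioms (equivalence of "observes
# property P of feature F") classifies every observation; classification is
# forward evaluation of the axiom predicates, which is exact because every
# axiom is an intersection of nominals and one-property existentials.

movement_properties <- c("steps", "distance", "elevation", "floors",
                         "fair_activity", "high_activity", "light_activity",
                         "sedentary")
sleep_properties <- c("asleep_count", "asleep_duration", "awake_count",
                      "awake_duration",
                      # extensions so the sleep rules have typed inputs
                      "minutes_to_fall_asleep", "efficiency")
heart_properties <- c("heart_rate", "cardio", "fat_burn", "peak")

#' Controlled vocabulary of observed properties
#' @return Character vector of the 18 recognised observed-property names.
#' @export
observed_properties <- function() {
  c(movement_properties, sleep_properties, heart_properties)
}

#' Features of interest
#' @return Character vector: movement, sleep, heart.
#' @export
features_of_interest <- function() c("movement", "sleep", "heart")

#' The observation class hierarchy
#'
#' Each class is defined by its parent plus a membership predicate over
#' `(feature_of_interest, observed_property)`: the branch classes
#' (MovementObservation, SleepObservation, HeartObservation) require the
#' matching feature instance and a property from the branch's property class;
#' leaf classes restrict the observed property to an enumerated set (e.g.
#' WalkingFeature to distance/elevation/floors/steps). Membership of a class
#' implies membership of its parent.
#'
#' @return A named list of class definitions, each with `parent`, `feature`
#'   (`NA` = any) and `properties` (`NULL` = any).
#' @export
observation_hierarchy <- function() {
  def <- function(parent, feature, properties) {
    list(parent = parent, feature = feature, properties = properties)
  }
  list(
    Observation         = def(NA, NA, NULL),
    MovementObservation = def("Observation", "movement", movement_properties),
    WalkingFeature      = def("MovementObservation", "movement",
                              c("distance", "elevation", "floors", "steps")),
    MovementIntensity   = def("MovementObservation", "movement",
                              c("fair_activity", "high_activity",
                                "light_activity", "sedentary")),
    SleepObservation    = def("Observation", "sleep", sleep_properties),
    AsleepCount         = def("SleepObservation", "sleep", "asleep_count"),
    AsleepDuration      = def("SleepObservation", "sleep", "asleep_duration"),
    AwakeCount          = def("SleepObservation", "sleep", "awake_count"),
    AwakeDuration       = def("SleepObservation", "sleep", "awake_duration"),
    HeartObservation    = def("Observation", "heart", heart_properties),
    Cardio              = def("HeartObservation", "heart", "cardio"),
    FatBurn             = def("HeartObservation", "heart", "fat_burn"),
    HeartRate           = def("HeartObservation", "heart", "heart_rate"),
    Peak                = def("HeartObservation", "heart", "peak")
  )
}

# Membership predicate of one class for vectors of (feature, property).
class_member <- function(def, feature, property) {
  ok <- rep(TRUE, length(feature))
  if (!is.na(def$feature)) ok <- ok & feature == def$feature
  if (!is.null(def$properties)) ok <- ok & property %in% def$properties
  ok
}

#' Classify one observation against the hierarchy
#'
#' Returns every class whose membership predicate holds for the observation's
#' `(feature_of_interest, observed_property)` pair, closed under parent
#' classes. An observation matching no branch axiom classifies as
#' `"Observation"` only.
#'
#' @param obs A one-row observation data frame (see [to_observations()]) or a
#'   list with `feature_of_interest` and `observed_property`.
#' @param hierarchy A hierarchy from [observation_hierarchy()].
#' @return Sorted character vector of class names (always contains
#'   `"Observation"`).
#' @export
classify_observation <- function(obs, hierarchy = observation_hierarchy()) {
  feature <- obs$feature_of_interest[1]
  property <- obs$observed_property[1]
  hit <- names(hierarchy)[vapply(hierarchy, class_member, TRUE,
                                 feature = feature, property = property)]
  # close under parents (redundant for this hierarchy, but required by the
  # contract and robust to user-extended hierarchies)
  closed <- hit
  repeat {
    parents <- unlist(lapply(closed, function(cl) hierarchy[[cl]]$parent))
    parents <- parents[!is.na(parents)]
    grown <- union(closed, parents)
    if (length(grown) == length(closed)) break
    closed <- grown
  }
  sort(unique(c("Observation", closed)))
}

# Vectorized classification: one class-set string per (feature, property)
# pair, memoised over the 3 x 18 grid.
classify_pairs <- function(feature, property, hierarchy = observation_hierarchy()) {
  key <- paste(feature, property)
  uk <- unique(key)
  sets <- lapply(uk, function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    classify_observation(list(feature_of_interest = parts[1],
                              observed_property = parts[2]), hierarchy)
  })
  names(sets) <- uk
  sets[key]
}

obs_id <- function(subject_id, property, start) {
  sprintf("ms:obs-%s-%s-%s", subject_id, property,
          format(start, "%Y%m%dT%H%M%S", tz = WKG_TZ))
}

empty_observations <- function() {
  out <- data.frame(id = character(), subject_id = character(),
                    feature_of_interest = character(),
                    observed_property = character(),
                    result = numeric(), unit = character(),
                    start = as.POSIXct(character(), tz = WKG_TZ),
                    end = as.POSIXct(character(), tz = WKG_TZ))
  out$classes <- list()
  class(out) <- c("observations", "data.frame")
  out
}

make_observations <- function(subject_id, feature, property, result, unit,
                              start, end) {
  if (!length(result)) return(empty_observations())
  out <- data.frame(id = obs_id(subject_id, property, start),
                    subject_id = subject_id, feature_of_interest = feature,
                    observed_property = property, result = as.numeric(result),
                    unit = unit, start = start, end = end,
                    stringsAsFactors = FALSE)
  out$classes <- classify_pairs(out$feature_of_interest, out$observed_property)
  class(out) <- c("observations", "data.frame")
  out
}

#' Map wearable inputs to classified observations
#'
#' Per-minute samples become one observation each over the half-open minute
#' interval `[t, t + 1 min)`; a sleep session yields one observation per
#' derived property (`asleep_duration`, `awake_count`, `awake_duration`,
#' `minutes_to_fall_asleep`, `efficiency`) over `[start, end)`. Observation
#' ids are deterministic functions of (subject, property, interval start), so
#' identical inputs always produce identical ids. The `classes` list-column
#' holds the inferred class set of each observation.
#'
#' @param x A [sample_stream()] or a `sleep_sessions` data frame.
#' @param subject_id Optional override of the subject identifier.
#' @return An `observations` data frame (possibly zero rows).
#' @export
to_observations <- function(x, subject_id = NULL) {
  UseMethod("to_observations")
}

#' @export
to_observations.sample_stream <- function(x, subject_id = NULL) {
  subj <- subject_id %||% x$subject_id
  s <- x$samples
  if (!nrow(s)) return(empty_observations())
  prop <- switch(x$kind, steps = "steps", heart_rate = "heart_rate",
                 stop("unknown stream kind: ", x$kind, call. = FALSE))
  unit <- switch(x$kind, steps = "steps", heart_rate = "bpm")
  feat <- if (x$kind == "steps") "movement" else "heart"
  make_observations(subj, feat, prop, s$value, unit,
                    s$timestamp, s$timestamp + 60)
}

#' @export
to_observations.sleep_sessions <- function(x, subject_id = NULL) {
  if (!nrow(x)) return(empty_observations())
  asleep <- session_asleep_minutes(x)
  per_prop <- list(
    asleep_duration = list(v = asleep, u = "min"),
    awake_count = list(v = x$awakenings_count, u = "count"),
    awake_duration = list(v = x$minutes_awake, u = "min"),
    minutes_to_fall_asleep = list(v = x$minutes_to_fall_asleep, u = "min"),
    efficiency = list(v = x$efficiency, u = "percent")
  )
  parts <- lapply(names(per_prop), function(p) {
    subj <- subject_id %||% x$subject_id
    make_observations(subj, "sleep", p, per_prop[[p]]$v, per_prop[[p]]$u,
                      x$start, x$end)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observations", "data.frame")
  out
}

#' @export
to_observations.data.frame <- function(x, subject_id = NULL) {
  stop("unknown input kind: pass a sample_stream or sleep_sessions object",
       call. = FALSE)
}

#' Bind several observation tables
#' @param ... `observations` data frames.
#' @return One combined `observations` data frame, sorted by start then id.
#' @export
bind_observations <- function(...) {
  parts <- Filter(function(d) nrow(d) > 0, list(...))
  if (!length(parts)) return(empty_observations())
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observations", "data.frame")
  out
}

# CURIE for an inferred class: the core observation class lives in sosa:,
# the domain hierarchy in em:.
class_curie <- function(cl) {
  ifelse(cl == "Observation", "sosa:Observation", paste0("em:", cl))
}

#' Build the RDF knowledge graph of a set of observations
#'
#' Per observation the graph receives: one `rdf:type` triple per inferred
#' class, one `rdf:type dul:Event` triple (observations are events under the
#' upper-ontology alignment), `sosa:observedProperty`,
#' `sosa:hasFeatureOfInterest`, `sosa:hasSimpleResult` and the interval
#' bounds — i.e. `n_classes + 6` triples per observation.
#'
#' @param observations An `observations` data frame (classified).
#' @param kg Optionally an existing `kg` to enrich.
#' @return A `kg`.
#' @export
build_graph <- function(observations, kg = kg_new()) {
  if (!nrow(observations)) return(kg)
  o <- observations
  nclass <- lengths(o$classes)
  type_s <- rep(o$id, nclass)
  type_o <- class_curie(unlist(o$classes))
  kg <- kg_add(kg, type_s, "rdf:type", type_o)
  kg <- kg_add(kg, o$id, "rdf:type", "dul:Event")
  kg <- kg_add(kg, o$id, "sosa:observedProperty",
               paste0("ms:", o$observed_property))
  kg <- kg_add(kg, o$id, "sosa:hasFeatureOfInterest",
               paste0("ms:", o$feature_of_interest))
  kg <- kg_add(kg, o$id, "sosa:hasSimpleResult",
               format(o$result, scientific = FALSE, trim = TRUE),
               lit = TRUE, dt = "decimal")
  kg <- kg_add(kg, o$id, "em:hasStartTime", wkg_format_time(o$start),
               lit = TRUE, dt = "dateTime")
  kg <- kg_add(kg, o$id, "em:hasEndTime", wkg_format_time(o$end),
               lit = TRUE, dt = "dateTime")
  kg
}
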