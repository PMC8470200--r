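# Descriptions-and-Situations layer: a detected problem is a situation that
# has a view (its descriptive context) and interprets one or more
# observations. The view defines domain concepts (the features of interest)
# which classify the observed-property entities, mirroring the DnS pattern of
# the upper ontology. Problems also map onto Web Annotation Data Model
# annotations: views become bodies, interpreted observations become targets.

#' Problem types known to the framework
#' @return Character vector of the 12 problem type names.
#' @export
problem_types <- function() names(problem_categories())

#' Problem type to category assignment
#'
#' Problems are grouped into sleep-, activity- and heart-related categories
#' according to the kind of observations that drive them. The assignment is
#' data (a named vector), so deployments can override it.
#'
#' @return Named character vector: problem type -> category.
#' @export
problem_categories <- function() {
  c(Insomnia = "SleepProblem", Restlessness = "SleepProblem",
    TooMuchSleep = "SleepProblem", LackOfSleep = "SleepProblem",
    IncreasedNapping = "SleepProblem", NapCloseToBedtime = "SleepProblem",
    LowSleepQuality = "SleepProblem",
    StressOrPain = "HeartProblem", LowHeartRate = "HeartProblem",
    Inactivity = "ActivityProblem", LackOfMovement = "ActivityProblem",
    LackOfExercise = "ActivityProblem")
}

#' Instantiate a problem situation over a set of observations
#'
#' Builds the DnS instantiation: the problem has one view; the view defines
#' one concept per distinct feature of interest among the supplied
#' observations, each concept classifying the corresponding observed-property
#' entities; the problem interprets every supplied observation. Node ids are
#' deterministic functions of (subject, problem type, extent start).
#'
#' @param problem_type One of [problem_types()].
#' @param observations Non-empty `observations` data frame, single subject.
#' @param temporal_extent Length-2 `POSIXct` (start, end): the day or window
#'   the problem covers.
#' @param categories Problem -> category map, default [problem_categories()].
#' @return An object of class `problem_situation`.
#' @export
instantiate_problem <- function(problem_type, observations, temporal_extent,
                                categories = problem_categories()) {
  wkg_stopifnot(problem_type %in% names(categories),
                paste0("unknown problem type: ", problem_type))
  wkg_stopifnot(nrow(observations) > 0,
                "a problem must interpret at least one observation")
  subj <- unique(observations$subject_id)
  wkg_stopifnot(length(subj) == 1L,
                "observations of a problem must share one subject")
  start <- temporal_extent[1]
  end <- temporal_extent[2]
  stamp <- format(start, "%Y%m%dT%H%M%S", tz = WKG_TZ)
  pid <- sprintf("ms:prob-%s-%s-%s", subj, problem_type, stamp)
  vid <- sprintf("ms:view-%s-%s-%s", subj, problem_type, stamp)
  pairs <- unique(observations[c("feature_of_interest", "observed_property")])
  concepts <- data.frame(concept = pairs$feature_of_interest,
                         entity = pairs$observed_property,
                         stringsAsFactors = FALSE)
  structure(
    list(id = pid, problem_type = problem_type,
         category = unname(categories[problem_type]), subject_id = subj,
         start = start, end = end,
         view = list(id = vid, defined_concepts = concepts),
         observation_ids = observations$id),
    class = "problem_situation"
  )
}

#' @export
print.problem_situation <- function(x, ...) {
  cat(sprintf("<problem_situation> %s [%s] %s  %s .. %s  (%d observations)\n",
              x$problem_type, x$category, x$subject_id,
              wkg_format_time(x$start), wkg_format_time(x$end),
              length(x$observation_ids)))
  invisible(x)
}

#' Add a problem situation to a knowledge graph
#'
#' Materialises the full DnS shape, including the subproperty entailments:
#' every `em:hasView` link is accompanied by `dul:satisfies`, every
#' `em:interprets` by `dul:isSettingFor`.
#'
#' @param problem A `problem_situation`.
#' @param kg A `kg` to enrich.
#' @return The enriched `kg`.
#' @export
problem_to_graph <- function(problem, kg = kg_new()) {
  p <- problem$id
  v <- problem$view$id
  kg <- kg_add(kg, p, "rdf:type",
               c(paste0("em:", problem$problem_type),
                 paste0("em:", problem$category),
                 "ms:Problem", "dul:Situation"))
  kg <- kg_add(kg, p, c("em:hasView", "dul:satisfies"), v)
  kg <- kg_add(kg, rep(p, length(problem$observation_ids)), "em:interprets",
               problem$observation_ids)
  kg <- kg_add(kg, rep(p, length(problem$observation_ids)), "dul:isSettingFor",
               problem$observation_ids)
  kg <- kg_add(kg, v, "rdf:type", c("ms:View", "dul:Description"))
  dc <- problem$view$defined_concepts
  cn <- paste0("ms:", dc$concept)
  en <- paste0("ms:", dc$entity)
  kg <- kg_add(kg, v, "dul:defines", unique(cn))
  kg <- kg_add(kg, unique(cn), "rdf:type", "dul:Concept")
  kg <- kg_add(kg, cn, "dul:classifies", en)
  kg <- kg_add(kg, p, "em:hasStartTime", wkg_format_time(problem$start),
               lit = TRUE, dt = "dateTime")
  kg <- kg_add(kg, p, "em:hasEndTime", wkg_format_time(problem$end),
               lit = TRUE, dt = "dateTime")
  kg
}

#' Validate the descriptive context of every problem in a graph
#'
#' Checks, per `ms:Problem` instance: at least one view; at least one
#' interpreted entity typed as an observation; every view defines at least
#' one concept; every defined concept classifies at least one entity; and
#' the subproperty entailments are materialised (`em:hasView` implies
#' `dul:satisfies`, `em:interprets` implies `dul:isSettingFor`). Failures
#' are report rows, not errors.
#'
#' @param kg A `kg` containing problem instances.
#' @return Data frame with columns `problem_id`, `check`, `message`; zero
#'   rows means the graph is structurally valid.
#' @export
validate_descriptive_context <- function(kg) {
  viol <- list()
  note <- function(pid, check, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(problem_id = pid, check = check,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  }
  probs <- unique(kg_match(kg, p = "rdf:type", o = "ms:Problem")$s)
  obs_nodes <- unique(kg_match(kg, p = "rdf:type", o = "sosa:Observation")$s)
  for (p in probs) {
    views <- kg_match(kg, s = p, p = "em:hasView")$o
    if (!length(views)) {
      note(p, "problem-structure", "problem has no view")
    }
    interp <- kg_match(kg, s = p, p = "em:interprets")$o
    if (!length(interp)) {
      note(p, "problem-structure", "problem interprets no entity")
    } else if (!any(interp %in% obs_nodes)) {
      note(p, "problem-structure",
           "problem interprets no entity typed as an observation")
    }
    sat <- kg_match(kg, s = p, p = "dul:satisfies")$o
    for (v in setdiff(views, sat)) {
      note(p, "subproperty-entailment",
           paste0("hasView ", v, " lacks the entailed dul:satisfies triple"))
    }
    setting <- kg_match(kg, s = p, p = "dul:isSettingFor")$o
    for (o in setdiff(interp, setting)) {
      note(p, "subproperty-entailment",
           paste0("interprets ", o, " lacks the entailed dul:isSettingFor triple"))
    }
    for (v in views) {
      defined <- kg_match(kg, s = v, p = "dul:defines")$o
      if (!length(defined)) {
        note(p, "view-structure", paste0("view ", v, " defines no concept"))
      }
      for (cpt in defined) {
        if (!nrow(kg_match(kg, s = cpt, p = "dul:classifies"))) {
          note(p, "view-structure",
               paste0("concept ", cpt, " classifies no entity"))
        }
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(problem_id = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Export a problem as a Web Annotation
#'
#' The problem becomes an annotation whose bodies are its views and whose
#' targets are the interpreted observations. The annotation model requires
#' zero or more bodies and one or more targets, so a problem without
#' interpreted observations is rejected.
#'
#' @param problem A `problem_situation`.
#' @return An object of class `wadm_annotation` with `id`, `bodies`,
#'   `targets`.
#' @export
export_wadm <- function(problem) {
  wkg_stopifnot(length(problem$observation_ids) >= 1,
                "annotation requires at least one target")
  structure(list(id = sub("^ms:prob-", "ms:anno-", problem$id),
                 bodies = list(problem$view$id),
                 targets = as.list(problem$observation_ids)),
            class = "wadm_annotation")
}

#' Serialize a Web Annotation to JSON-LD
#' @param annotation A `wadm_annotation`.
#' @return JSON-LD text (oa: vocabulary).
#' @export
wadm_to_jsonld <- function(annotation) {
  ns <- wkg_namespaces()
  doc <- list(`@context` = as.list(ns[c("oa", "ms")]),
              `@id` = annotation$id,
              `@type` = "oa:Annotation",
              `oa:hasBody` = lapply(annotation$bodies, function(b) list(`@id` = b)),
              `oa:hasTarget` = lapply(annotation$targets, function(t) list(`@id` = t)))
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
}

#' Parse a Web Annotation from JSON-LD written by [wadm_to_jsonld()]
#' @param text JSON-LD text.
#' @return A `wadm_annotation`.
#' @export
wadm_from_jsonld <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ann <- structure(
    list(id = doc$`@id`,
         bodies = lapply(doc$`oa:hasBody`, `[[`, "@id"),
         targets = lapply(doc$`oa:hasTarget`, `[[`, "@id")),
    class = "wadm_annotation")
  wkg_stopifnot(length(ann$targets) >= 1,
                "annotation requires at least one target")
  ann
}
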