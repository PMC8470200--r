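Package: wearkg
Title: Knowledge-Graph Based Detection of Health-Related Events from
    Wearable Lifestyle Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ingests per-minute step counts, per-minute heart-rate samples
    and session-structured sleep records from consumer wearables, maps them
    to SOSA-style observations in an RDF knowledge graph, classifies the
    observations against a finite hierarchy of observation-type axioms, and
    runs a configurable symbolic rule base (daily aggregation rules and
    step/heart-rate window rules) that emits "problem situations" following
    the Descriptions-and-Situations ontology pattern. Detected problems can
    be validated structurally, exported as Web Annotation Data Model
    annotations, serialized as Turtle or JSON-LD, and summarised through
    dashboard-style resampling reports. A seed-reproducible synthetic-data
    generator with problem-episode injection and a scalability benchmark
    harness make the whole pipeline testable without access to device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
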