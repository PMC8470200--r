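test_that("classification matches the exhaustive axiom oracle on all pairs", {
  for (f in features_of_interest()) {
    for (p in observed_properties()) {
      got <- classify_observation(list(feature_of_interest = f,
                                       observed_property = p))
      expect_identical(got, oracle_classes(f, p),
                       info = paste(f, p))
    }
  }
})

test_that("classification hits the documented anchor cases", {
  cls <- function(f, p) classify_observation(list(feature_of_interest = f,
                                                  observed_property = p))
  expect_setequal(cls("movement", "steps"),
                  c("Observation", "MovementObservation", "WalkingFeature"))
  expect_setequal(cls("heart", "heart_rate"),
                  c("Observation", "HeartObservation", "HeartRate"))
  # efficiency has no leaf axiom: branch class only
  expect_setequal(cls("sleep", "efficiency"),
                  c("Observation", "SleepObservation"))
  # mismatched feature/property falls through to the root
  expect_identical(cls("movement", "heart_rate"), "Observation")
  # idempotent: classifying an already classified observation changes nothing
  expect_identical(cls("movement", "steps"), sort(cls("movement", "steps")))
})

test_that("inputs map to observations with deterministic ids", {
  s <- minute_stream("steps", 300, from = "2021-03-01 09:00")
  obs <- to_observations(s)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$feature_of_interest, "movement")
  expect_equal(obs$observed_property, "steps")
  expect_equal(obs$result, 300)
  expect_equal(as.numeric(difftime(obs$end, obs$start, units = "mins")), 1)

  sess <- sleep_sessions(make_session("2021-03-01 23:00", "2021-03-02 07:00",
                                      awakenings = 3))
  sobs <- to_observations(sess)
  expect_equal(nrow(sobs), 5L)  # one per derived sleep property
  awake <- sobs[sobs$observed_property == "awake_count", ]
  expect_equal(awake$result, 3)

  expect_identical(to_observations(s)$id, obs$id)
  expect_error(to_observations(data.frame(x = 1)), "unknown input")
})

test_that("graph triples follow the per-observation counting law", {
  d <- generate_subject_days(synthetic_profile(), 1, seed = 3)
  obs <- bind_observations(to_observations(d$steps)[1:40, ],
                           to_observations(d$sessions))
  g <- build_graph(obs)
  expect_equal(kg_size(g), sum(lengths(obs$classes) + 6L))

  one <- to_observations(minute_stream("steps", 300))
  g1 <- build_graph(one)
  expect_true(any(g1$triples$s == one$id &
                    g1$triples$p == "sosa:observedProperty" &
                    g1$triples$o == "ms:steps"))
  expect_true(any(g1$triples$s == one$id & g1$triples$p == "rdf:type" &
                    g1$triples$o == "dul:Event"))
  expect_equal(kg_size(build_graph(to_observations(empty_steps()))), 0L)
})

test_that("serialization round-trips both formats and rejects unknown ones", {
  obs <- bind_observations(
    to_observations(minute_stream("steps", c(10, 0, 55))),
    to_observations(minute_stream("heart_rate", c(88.5, 61)))
  )
  g <- build_graph(obs)
  for (fmt in c("turtle", "json-ld")) {
    expect_true(kg_equal(g, parse_graph(serialize_graph(g, fmt), fmt)))
  }
  # empty graph is still a parseable document
  e <- kg_new()
  expect_true(kg_equal(e, parse_graph(serialize_graph(e, "turtle"), "turtle")))
  expect_error(serialize_graph(g, "rdfxml"))
})

test_that("the emitted Turtle is valid RDF for an independent parser", {
  py <- Sys.which("python")
  skip_if(py == "", "python not available")
  g <- build_graph(to_observations(minute_stream("steps", c(5, 7))))
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(serialize_graph(g, "turtle"), f)
  code <- sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))",
    f)
  n <- suppressWarnings(system2(py, c("-c", shQuote(code)), stdout = TRUE))
  skip_if(length(n) == 0 || is.na(suppressWarnings(as.integer(n[1]))),
          "python rdflib not available")
  expect_equal(as.integer(n[1]), kg_size(g))
})

test_that("triple addition is idempotent and size counts distinct triples", {
  g <- kg_new()
  g <- kg_add(g, "ms:a", "rdf:type", "sosa:Observation")
  g <- kg_add(g, "ms:a", "rdf:type", "sosa:Observation")
  expect_equal(kg_size(g), 1L)
  g <- kg_add(g, "ms:a", "sosa:hasSimpleResult", "3", lit = TRUE,
              dt = "decimal")
  expect_equal(kg_size(g), 2L)
})
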