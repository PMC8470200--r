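test_that("problem instantiation follows the description-situation shape", {
  obs <- to_observations(minute_stream("steps", 12))
  p <- instantiate_problem("LackOfMovement", obs,
                           c(t_at("2021-03-01 00:00"), t_at("2021-03-02 00:00")))
  expect_s3_class(p, "problem_situation")
  expect_equal(p$category, "ActivityProblem")
  # the view defines the feature as a concept classifying the property
  expect_equal(p$view$defined_concepts$concept, "movement")
  expect_equal(p$view$defined_concepts$entity, "steps")
  expect_equal(p$observation_ids, obs$id)

  sobs <- to_observations(sleep_sessions(
    make_session("2021-03-01 23:00", "2021-03-02 07:00")))
  asleep <- sobs[sobs$observed_property == "asleep_duration", ]
  q <- instantiate_problem("LackOfSleep", asleep,
                           c(t_at("2021-03-02 00:00"), t_at("2021-03-03 00:00")))
  expect_equal(q$view$defined_concepts$concept, "sleep")
  expect_equal(q$view$defined_concepts$entity, "asleep_duration")

  expect_error(instantiate_problem("LackOfSleep", asleep[0, ],
                                   c(t_at("2021-03-02 00:00"),
                                     t_at("2021-03-03 00:00"))),
               "at least one observation")
  expect_error(instantiate_problem("NotAProblem", asleep,
                                   c(t_at("2021-03-02 00:00"),
                                     t_at("2021-03-03 00:00"))),
               "unknown problem type")
})

test_that("category assignment covers all twelve problem types", {
  cats <- problem_categories()
  expect_length(cats, 12L)
  expect_setequal(unique(cats),
                  c("SleepProblem", "ActivityProblem", "HeartProblem"))
  expect_equal(unname(cats[c("Insomnia", "LowHeartRate", "Inactivity")]),
               c("SleepProblem", "HeartProblem", "ActivityProblem"))
})

test_that("descriptive-context validation accepts the canonical shape and
           pinpoints missing links", {
  obs <- to_observations(minute_stream("steps", 12))
  p <- instantiate_problem("LackOfMovement", obs,
                           c(t_at("2021-03-01 00:00"), t_at("2021-03-02 00:00")))
  g <- problem_to_graph(p, build_graph(obs))
  expect_equal(nrow(validate_descriptive_context(g)), 0L)

  # strip the interprets link: the situation axiom is violated
  g2 <- g
  g2$triples <- g2$triples[g2$triples$p != "em:interprets", ]
  v <- validate_descriptive_context(g2)
  expect_true(any(v$check == "problem-structure"))

  # strip the entailed dul:satisfies: subproperty closure violated
  g3 <- g
  g3$triples <- g3$triples[g3$triples$p != "dul:satisfies", ]
  v3 <- validate_descriptive_context(g3)
  expect_true(any(v3$check == "subproperty-entailment"))

  # strip the concept's classifies link: description axiom violated
  g4 <- g
  g4$triples <- g4$triples[g4$triples$p != "dul:classifies", ]
  v4 <- validate_descriptive_context(g4)
  expect_true(any(v4$check == "view-structure"))
})

test_that("annotation export maps views to bodies and observations to
           targets", {
  obs <- bind_observations(
    to_observations(minute_stream("steps", c(3, 4))))
  p <- instantiate_problem("LackOfMovement", obs,
                           c(t_at("2021-03-01 00:00"), t_at("2021-03-02 00:00")))
  a <- export_wadm(p)
  expect_length(a$bodies, 1L)
  expect_length(a$targets, 2L)

  # round trip through JSON-LD preserves ids and counts
  b <- wadm_from_jsonld(wadm_to_jsonld(a))
  expect_equal(b$id, a$id)
  expect_equal(b$bodies, a$bodies)
  expect_equal(b$targets, a$targets)

  p0 <- p
  p0$observation_ids <- character()
  expect_error(export_wadm(p0), "at least one target")
})

test_that("every detector-emitted problem validates and exports", {
  d <- generate_subject_days(synthetic_profile(), 3, seed = 5)
  d <- inject_problem_episode(d, "Restlessness", as.Date("2021-03-02"))
  d <- inject_problem_episode(d, "LowHeartRate", as.Date("2021-03-03"))
  res <- run_rulebase(d$steps, d$hr, d$sessions, graph = TRUE)
  expect_gt(length(res$problems), 0L)
  expect_equal(nrow(validate_descriptive_context(res$graph)), 0L)
  for (p in res$problems) {
    a <- export_wadm(p)
    expect_gte(length(a$targets), 1L)
  }
})
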