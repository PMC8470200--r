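test_that("day partition assigns samples by date and sessions by end date", {
  steps <- minute_stream("steps", c(1, 2), from = "2021-03-01 23:59")
  hr <- empty_hr()
  sess <- sleep_sessions(make_session("2021-03-01 23:00", "2021-03-02 07:00"))
  part <- partition_by_day(steps, hr, sess)
  expect_setequal(names(part), c("2021-03-01", "2021-03-02"))
  expect_equal(part[["2021-03-01"]]$steps$value, 1)   # 23:59 stays on Mar 1
  expect_equal(part[["2021-03-02"]]$steps$value, 2)
  expect_equal(nrow(part[["2021-03-02"]]$sessions), 1L)  # night ends Mar 2
  expect_equal(nrow(part[["2021-03-01"]]$sessions), 0L)
})

test_that("per-day step totals conserve the global total", {
  d <- generate_subject_days(synthetic_profile(), 4, seed = 9)
  part <- partition_by_day(d$steps, d$hr, d$sessions)
  per_day <- vapply(part, function(cx) sum(cx$steps$value), 0)
  expect_equal(sum(per_day), sum(d$steps$samples$value))
})

test_that("daily aggregates convert units and designate naps", {
  sess <- sleep_sessions(rbind(
    make_session("2021-03-01 23:00", "2021-03-02 07:00", fall = 31,
                 awakenings = 6, asleep = 420, awake = 29),
    make_session("2021-03-02 14:00", "2021-03-02 14:45", fall = 0,
                 awakenings = 5, asleep = 45, awake = 0)))
  part <- partition_by_day(empty_steps(), empty_hr(), sess)
  agg <- compute_daily_aggregates(part[["2021-03-02"]])
  expect_equal(agg$fall_asleep_seconds, 31 * 60)   # 1860
  expect_equal(agg$interruptions, 11)
  expect_equal(agg$nap_minutes, 45)                # 420-min session is main
  expect_equal(agg$sleep_minutes, 465)
  expect_true(agg$has_sleep_data)

  empty_day <- compute_daily_aggregates(
    partition_by_day(minute_stream("steps", 5, from = "2021-03-05 10:00"),
                     empty_hr(), sleep_sessions(NULL))[["2021-03-05"]])
  expect_false(empty_day$has_sleep_data)
})

test_that("daily rules use strict comparisons: at-threshold never fires", {
  # a day sitting exactly on every boundary is problem-free
  sess <- sleep_sessions(rbind(
    make_session("2021-03-01 22:30", "2021-03-02 07:00", fall = 30,
                 awakenings = 5, asleep = 380, awake = 60,
                 is_main = TRUE),
    make_session("2021-03-02 12:00", "2021-03-02 14:00", fall = 0,
                 awakenings = 5, asleep = 100, awake = 20, efficiency = 85,
                 is_main = FALSE)))
  steps <- minute_stream("steps", rep(100, 80), from = "2021-03-02 10:00")
  res <- detect(steps = steps, sessions = sess)
  # fall asleep 1800 s, interruptions 10, sleep 480, naps 100, efficiency 85
  # (nap) and 84.7 -> but main session efficiency is passed explicitly below
  agg <- compute_daily_aggregates(
    partition_by_day(steps, empty_hr(), sess)[["2021-03-02"]])
  expect_equal(agg$fall_asleep_seconds, 1800)
  expect_equal(agg$interruptions, 10)
  expect_equal(agg$sleep_minutes, 480)
  expect_equal(agg$nap_minutes, 100)
  expect_equal(agg$steps, 8000)
  day2 <- Filter(function(p) problem_day(p) == as.Date("2021-03-02"),
                 res$problems)
  types <- vapply(day2, `[[`, "", "problem_type")
  expect_false(any(c("Insomnia", "Restlessness", "TooMuchSleep",
                     "LackOfSleep", "IncreasedNapping",
                     "LackOfExercise") %in% types))
})

test_that("single-step past a boundary fires exactly the targeted rule", {
  expect_false(probe_fires("LackOfSleep", 300))
  expect_true(probe_fires("LackOfSleep", 299))
  res <- detect(sessions = sleep_sessions(make_session(
    "2021-03-01 21:00", "2021-03-02 11:00", asleep = 299, awake = 0,
    fall = 5, subject = "probe")))
  types <- fired_types(res)
  expect_true("LackOfSleep" %in% types)
  expect_false("TooMuchSleep" %in% types)

  expect_false(probe_fires("TooMuchSleep", 480))
  expect_true(probe_fires("TooMuchSleep", 481))
})

test_that("window search equals the brute-force oracle on crafted runs", {
  rule <- default_rulebase()$rules$LackOfMovement   # steps<500, HR<100, >800
  hr801 <- minute_stream("heart_rate", rep(90, 801), from = "2021-03-01 01:00")
  w <- find_hr_step_windows(empty_steps(), hr801, rule)
  expect_equal(nrow(w), 1L)
  expect_equal(w$length, 801L)

  hr800 <- minute_stream("heart_rate", rep(90, 800), from = "2021-03-01 01:00")
  expect_equal(nrow(find_hr_step_windows(empty_steps(), hr800, rule)), 0L)

  # one disqualifying minute splits the run into two 400-minute halves,
  # neither long enough for the 800-minute rule
  vals <- c(rep(90, 400), 120, rep(90, 400))
  hrsplit <- minute_stream("heart_rate", vals, from = "2021-03-01 01:00")
  expect_equal(nrow(find_hr_step_windows(empty_steps(), hrsplit, rule)), 0L)
  # the oracle agrees about the split
  loose <- rule; loose$window_min_duration <- 100
  expect_equal(find_hr_step_windows(empty_steps(), hrsplit, loose),
               oracle_windows(empty_steps(), hrsplit, loose))
})

test_that("window search equals the brute-force oracle on random streams", {
  set.seed(2024)
  rules <- default_rulebase()$rules[c("StressOrPain", "Inactivity",
                                      "LackOfMovement")]
  for (i in 1:40) {
    n <- sample(100:2000, 1)
    keep <- runif(n) > 0.08            # missing minutes break runs
    t0 <- t_at("2021-03-01 00:00") + sample(0:10000, 1) * 60
    ts <- (t0 + (seq_len(n) - 1) * 60)[keep]
    hr <- sample_stream("r", "heart_rate", ts,
                        round(runif(sum(keep), 50, 130)))
    skeep <- runif(n) > 0.3
    steps <- sample_stream("r", "steps", (t0 + (seq_len(n) - 1) * 60)[skeep],
                           rpois(sum(skeep), 4))
    rule <- rules[[sample(3, 1)]]
    rule$window_min_duration <- sample(c(5, 20, 60), 1)  # make hits likely
    expect_equal(find_hr_step_windows(steps, hr, rule),
                 oracle_windows(steps, hr, rule), info = paste("stream", i))
  }
})

test_that("low heart-rate runs are maximal and strictly sub-threshold", {
  hr <- minute_stream("heart_rate", c(59, 59, 61, 58))
  runs <- find_low_hr_runs(hr)
  expect_equal(runs$length, c(2L, 1L))
  expect_equal(nrow(find_low_hr_runs(minute_stream("heart_rate",
                                                   c(60, 72, 60)))), 0L)
})

test_that("per-subject overrides change only the targeted threshold", {
  rb <- default_rulebase()
  rb$overrides <- list(tms7 = list(LackOfExercise = list(threshold = 5000)))
  rules7 <- rulebase_for_subject(rb, "tms7")
  expect_equal(rules7$LackOfExercise$threshold, 5000)
  expect_equal(rules7$LackOfSleep$threshold, 300)
  expect_equal(rulebase_for_subject(rb, "tms6")$LackOfExercise$threshold, 8000)

  steps <- minute_stream("steps", rep(60, 100), from = "2021-03-01 10:00",
                         subject = "tms7")   # total 6000
  res <- run_rulebase(steps, empty_hr(), sleep_sessions(NULL), rulebase = rb,
                      graph = FALSE)
  expect_false("LackOfExercise" %in% fired_types(res))  # 6000 > 5000
  res_def <- run_rulebase(steps, empty_hr(), sleep_sessions(NULL),
                          graph = FALSE)
  expect_true("LackOfExercise" %in% fired_types(res_def))

  rb$overrides <- list(tms7 = list(NoSuchRule = list(threshold = 1)))
  expect_error(rulebase_for_subject(rb, "tms7"), "unknown rule id")
})

test_that("rulebase config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  rb <- default_rulebase()
  rb$rules$Insomnia$threshold <- 2400
  rb$overrides <- list(tms7 = list(LackOfSleep = list(threshold = 360)))
  write_rulebase(rb, f)
  back <- read_rulebase(f)
  expect_equal(back$rules$Insomnia$threshold, 2400)
  expect_equal(back$rules$LackOfExercise$threshold, 8000)
  expect_equal(back$overrides$tms7$LackOfSleep$threshold, 360)
})

test_that("detection is deterministic down to the serialized graph", {
  d <- generate_subject_days(synthetic_profile(), 2, seed = 21)
  d <- inject_problem_episode(d, "Inactivity", as.Date("2021-03-02"))
  r1 <- run_rulebase(d$steps, d$hr, d$sessions, graph = TRUE)
  r2 <- run_rulebase(d$steps, d$hr, d$sessions, graph = TRUE)
  expect_identical(serialize_graph(r1$graph, "turtle"),
                   serialize_graph(r2$graph, "turtle"))
  expect_identical(vapply(r1$problems, `[[`, "", "id"),
                   vapply(r2$problems, `[[`, "", "id"))
})

test_that("daily detections respond monotonically to their variable", {
  # raising steps can only remove the exercise problem
  fires_at <- function(total) probe_fires("LackOfExercise", total)
  expect_true(fires_at(4000))
  expect_true(fires_at(7999))
  expect_false(fires_at(8000))
  expect_false(fires_at(12000))
  # lowering sleep keeps an already-firing lack-of-sleep day firing
  expect_true(probe_fires("LackOfSleep", 299))
  expect_true(probe_fires("LackOfSleep", 150))
})

test_that("the SHACL export is a valid Turtle rule document", {
  doc <- export_shacl_rules(default_rulebase())
  g <- parse_graph(doc, "turtle")
  expect_gt(kg_size(g), 0L)
  expect_true(any(g$triples$o == "sh:SPARQLRule"))
  expect_match(doc, "em:Inactivity", fixed = TRUE)
  expect_match(doc, "CONSTRUCT", fixed = TRUE)

  empty_rb <- default_rulebase()
  empty_rb$rules <- list()
  doc0 <- export_shacl_rules(empty_rb)
  expect_equal(kg_size(parse_graph(doc0, "turtle")), 0L)
  expect_match(doc0, "@prefix sh:", fixed = TRUE)
})

test_that("evaluate_daily_rules rejects unknown rule ids", {
  sess <- sleep_sessions(make_session("2021-03-01 23:00", "2021-03-02 07:00"))
  agg <- compute_daily_aggregates(
    partition_by_day(empty_steps(), empty_hr(), sess)[["2021-03-02"]])
  bad <- list(Bogus = list(problem_type = "Bogus", scope = "daily",
                           variable = "steps", comparator = "<",
                           threshold = 1, unit = "steps"))
  expect_error(evaluate_daily_rules(agg, bad, subject_id = "tms6"),
               "unknown rule id")
})
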