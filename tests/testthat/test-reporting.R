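test_that("resampling aggregates into aligned buckets", {
  s <- minute_stream("steps", c(10, 20, 30), from = "2021-03-01 09:00")
  expect_equal(resample(s, "hour", "sum")$value, 60)
  expect_equal(resample(s, "hour", "average")$value, 20)
  expect_equal(resample(s, "hour", "sum")$bucket, t_at("2021-03-01 09:00"))

  # empty range -> empty series
  empty <- resample(s, "day", "sum",
                    date_range = c(t_at("2020-01-01 00:00"),
                                   t_at("2020-01-02 00:00")))
  expect_equal(nrow(empty), 0L)
  expect_error(resample(s, "fortnight", "sum"))
})

test_that("sum-resampling conserves totals at every resolution", {
  d <- generate_subject_days(synthetic_profile(), 3, seed = 14)
  total <- sum(d$steps$samples$value)
  for (res in c("minute", "hour", "day", "week", "month", "year")) {
    expect_equal(sum(resample(d$steps, res, "sum")$value), total, info = res)
  }
  # resample-then-sum equals direct sum over a sub-range too
  rng <- c(t_at("2021-03-02 00:00"), t_at("2021-03-03 00:00"))
  in_rng <- d$steps$samples$timestamp >= rng[1] &
    d$steps$samples$timestamp < rng[2]
  expect_equal(sum(resample(d$steps, "hour", "sum", rng)$value),
               sum(d$steps$samples$value[in_rng]))
})

test_that("weeks start on Monday", {
  # 2021-03-01 is a Monday; Sunday the 7th must land in the same bucket
  s <- sample_stream("x", "steps",
                     c(t_at("2021-03-01 10:00"), t_at("2021-03-07 10:00"),
                       t_at("2021-03-08 10:00")),
                     c(1, 2, 4))
  w <- resample(s, "week", "sum")
  expect_equal(w$value, c(3, 4))
  expect_equal(format(w$bucket[1], "%Y-%m-%d"), "2021-03-01")
})

test_that("summary statistics are exact and reject empty series", {
  one <- resample(minute_stream("steps", 60), "hour", "sum")
  expect_equal(summary_stats(one), list(average = 60, minimum = 60,
                                        maximum = 60))
  two <- resample(minute_stream("steps", c(0, 100)), "minute", "sum")
  st <- summary_stats(two)
  expect_equal(st$average, 50)
  expect_equal(st$minimum, 0)
  expect_equal(st$maximum, 100)
  expect_error(summary_stats(two[0, ]), "empty")
})

test_that("the problem timeline filters, orders and breaks ties by type", {
  obs <- to_observations(minute_stream("steps", 1, from = "2021-03-02 10:00"))
  mk <- function(type, start) {
    instantiate_problem(type, obs, c(t_at(start), t_at(start) + 3600))
  }
  probs <- list(mk("LackOfExercise", "2021-03-02 00:00"),
                mk("Inactivity", "2021-03-02 00:00"),
                mk("LackOfMovement", "2021-04-01 00:00"))
  tl <- problem_timeline(probs, c(t_at("2021-03-01 00:00"),
                                  t_at("2021-03-10 00:00")))
  expect_equal(nrow(tl), 2L)
  expect_equal(tl$problem_type, c("Inactivity", "LackOfExercise"))
  expect_equal(nrow(problem_timeline(list())), 0L)
})

test_that("the daily sleep series carries the stage breakdown", {
  sess <- sleep_sessions(rbind(
    make_session("2021-03-01 23:00", "2021-03-02 07:00", asleep = 400,
                 awake = 30, fall = 10),
    make_session("2021-03-02 14:00", "2021-03-02 14:40", asleep = 35,
                 awake = 5, fall = 0)))
  sl <- sleep_daily_series(sess)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$sleep_minutes, 435)
  expect_equal(sl$minutes_awake, 35)
  expect_equal(sl$minutes_deep + sl$minutes_light + sl$minutes_rem, 435)
})

test_that("reports bundle series, summaries and the timeline", {
  d <- generate_subject_days(synthetic_profile(), 2, seed = 6)
  di <- inject_problem_episode(d, "LackOfExercise", as.Date("2021-03-02"))
  res <- run_rulebase(di$steps, di$hr, di$sessions, graph = FALSE)
  rep <- build_report(res, di$steps, di$hr, di$sessions,
                      resolution = "day", agg = "sum")
  expect_equal(nrow(rep$steps$points), 2L)
  expect_true(all(c("average", "minimum", "maximum") %in%
                    names(rep$steps$summary)))
  expect_true("LackOfExercise" %in% rep$problems$problem_type)
  expect_equal(nrow(rep$sleep), 2L)
})
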