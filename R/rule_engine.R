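# Evaluation of the rule base over observation streams. Daily rules operate
# on per-calendar-day aggregates (sleep sessions are attributed to the day
# they end on); window rules search streams for maximal runs of minutes whose
# heart-rate samples satisfy a per-minute comparison, qualified by a
# cumulative step condition and a strict minimum duration.

wkg_cmp <- function(x, comparator, threshold) {
  switch(comparator,
         "<" = x < threshold,
         ">" = x > threshold,
         stop("comparator must be '<' or '>'", call. = FALSE))
}

sleep_rule_ids <- c("Insomnia", "Restlessness", "TooMuchSleep", "LackOfSleep",
                    "IncreasedNapping", "NapCloseToBedtime", "LowSleepQuality")

# Designate main sleep vs naps within one day's sessions: an explicit
# is_main_sleep flag wins; otherwise the session with the most asleep
# minutes (tie: earliest start) is main sleep, all others are naps.
flag_naps <- function(sessions) {
  if (!nrow(sessions)) {
    sessions$is_nap <- logical()
    return(sessions)
  }
  is_nap <- rep(TRUE, nrow(sessions))
  flagged <- which(!is.na(sessions$is_main_sleep) & sessions$is_main_sleep)
  if (length(flagged)) {
    is_nap[flagged] <- FALSE
  } else {
    asleep <- session_asleep_minutes(sessions)
    main <- order(-asleep, sessions$start)[1L]
    is_nap[main] <- FALSE
  }
  sessions$is_nap <- is_nap
  sessions
}

#' Partition streams and sessions into per-day contexts
#'
#' Samples belong to the calendar date of their timestamp; a sleep session
#' belongs to the date it ends on (so a 23:00-07:00 night is attributed to
#' the morning's date). Within each day, sessions are designated main sleep
#' or nap.
#'
#' @param steps,hr [sample_stream()] objects (may be empty).
#' @param sessions A `sleep_sessions` data frame.
#' @return Named list (key `"YYYY-MM-DD"`) of day contexts, each with
#'   `date`, `steps`, `hr` (sample data frames) and `sessions` (with an
#'   `is_nap` flag and a `session_index` into the input table).
#' @export
partition_by_day <- function(steps, hr, sessions) {
  sessions <- as.data.frame(sessions)
  sessions$session_index <- seq_len(nrow(sessions))
  s_date <- if (nrow(steps$samples)) wkg_date(steps$samples$timestamp) else as.Date(character())
  h_date <- if (nrow(hr$samples)) wkg_date(hr$samples$timestamp) else as.Date(character())
  sess_date <- if (nrow(sessions)) wkg_date(sessions$end) else as.Date(character())
  all_dates <- sort(unique(c(s_date, h_date, sess_date)))
  ctx <- lapply(all_dates, function(d) {
    day_sessions <- flag_naps(sessions[sess_date == d, , drop = FALSE])
    list(date = d,
         steps = steps$samples[s_date == d, , drop = FALSE],
         hr = hr$samples[h_date == d, , drop = FALSE],
         sessions = day_sessions)
  })
  names(ctx) <- as.character(all_dates)
  ctx
}

# Start instants of all main-sleep sessions across the whole record,
# used for the nap-close-to-bedtime gap.
main_sleep_starts <- function(day_contexts) {
  starts <- lapply(day_contexts, function(cx) {
    cx$sessions$start[!cx$sessions$is_nap]
  })
  sort(do.call(c, c(starts, list(as.POSIXct(character(), tz = WKG_TZ)))))
}

#' Compute the daily aggregate of one day context
#'
#' Aggregates: total asleep minutes over the day's sessions
#' (`sleep_minutes`), seconds to fall asleep summed over sessions
#' (`fall_asleep_seconds = 60 * sum(minutes_to_fall_asleep)`), total
#' awakenings (`interruptions`), asleep minutes of nap sessions
#' (`nap_minutes`), nap count, total steps, and the smallest gap in minutes
#' from a nap's end to the next main-sleep start anywhere in the record
#' (`nap_to_bed_gap_minutes`, `NA` when there is no nap or no later main
#' sleep). A day without sessions is flagged `has_sleep_data = FALSE`
#' (missing sleep data is non-adherence, not zero sleep).
#'
#' @param day_context One element of [partition_by_day()].
#' @param main_starts Optional `POSIXct` vector of all main-sleep starts (for
#'   the nap-to-bedtime gap across day boundaries); defaults to the day's own
#'   main sleep.
#' @return A list of class `daily_aggregate`.
#' @export
compute_daily_aggregates <- function(day_context, main_starts = NULL) {
  cx <- day_context
  sess <- cx$sessions
  if (is.null(main_starts)) main_starts <- sort(sess$start[!sess$is_nap])
  asleep <- session_asleep_minutes(sess)
  nap_gap <- NA_real_
  if (any(sess$is_nap) && length(main_starts)) {
    gaps <- vapply(sess$end[sess$is_nap], function(e) {
      later <- main_starts[main_starts >= e]
      if (!length(later)) return(NA_real_)
      as.numeric(difftime(later[1L], e, units = "mins"))
    }, 0)
    if (any(!is.na(gaps))) nap_gap <- min(gaps, na.rm = TRUE)
  }
  per_session <- data.frame(
    session_index = sess$session_index,
    start = sess$start, end = sess$end,
    efficiency = sess$efficiency, is_nap = sess$is_nap)
  structure(list(
    date = cx$date,
    has_sleep_data = nrow(sess) > 0,
    sleep_minutes = sum(asleep),
    fall_asleep_seconds = 60 * sum(sess$minutes_to_fall_asleep),
    interruptions = sum(sess$awakenings_count),
    nap_minutes = sum(asleep[sess$is_nap]),
    nap_count = sum(sess$is_nap),
    nap_to_bed_gap_minutes = nap_gap,
    steps = if (nrow(cx$steps)) sum(cx$steps$value) else NA_real_,
    n_step_samples = nrow(cx$steps),
    per_session = per_session), class = "daily_aggregate")
}

# Observed property whose observations a daily rule interprets.
daily_rule_property <- c(
  Insomnia = "minutes_to_fall_asleep", Restlessness = "awake_count",
  TooMuchSleep = "asleep_duration", LackOfSleep = "asleep_duration",
  IncreasedNapping = "asleep_duration", NapCloseToBedtime = "asleep_duration",
  LowSleepQuality = "efficiency", LackOfExercise = "steps")

day_extent <- function(date) {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = WKG_TZ)
  c(start, start + 86400)
}

# Select the day's observations that a rule interprets; fall back to a
# synthetic day-level aggregate observation when none are available.
rule_observations <- function(rule, agg, observations, subject_id,
                              value = NA_real_, sess_rows = NULL) {
  prop <- daily_rule_property[[rule$problem_type]]
  if (!is.null(observations) && nrow(observations)) {
    sel <- observations[observations$observed_property == prop, , drop = FALSE]
    if (!is.null(sess_rows)) {
      sel <- sel[sel$start %in% sess_rows$start, , drop = FALSE]
    }
    if (nrow(sel)) return(sel)
  }
  ext <- day_extent(agg$date)
  feat <- if (prop == "steps") "movement" else "sleep"
  make_observations(subject_id, feat, prop, value, rule$unit, ext[1], ext[2])
}

#' Evaluate the daily and per-session rules on one day's aggregate
#'
#' Comparisons are strict, exactly as the rule base prints them; a value at
#' the threshold never fires. Sleep rules are skipped on days without sleep
#' data; the step rule is skipped on days with zero step samples. Per daily
#' rule at most one problem per day; the per-session sleep-quality rule emits
#' one problem per failing session.
#'
#' @param agg A `daily_aggregate`.
#' @param rulebase A `rulebase`.
#' @param observations Optional `observations` of the day's subject, used as
#'   the interpreted observations of emitted problems.
#' @param subject_id Subject identifier (required if `observations` is
#'   `NULL`).
#' @return List of `problem_situation` objects.
#' @export
evaluate_daily_rules <- function(agg, rulebase, observations = NULL,
                                 subject_id = NULL) {
  stopifnot(inherits(agg, "daily_aggregate"))
  rules <- if (inherits(rulebase, "rulebase")) rulebase$rules else rulebase
  bad <- setdiff(names(rules), problem_types())
  wkg_stopifnot(!length(bad), paste0("unknown rule id: ", bad[1]))
  subject_id <- subject_id %||% observations$subject_id[1]
  ext <- day_extent(agg$date)
  problems <- list()
  emit <- function(rule, value, sess_rows = NULL, extent = ext) {
    obs <- rule_observations(rule, agg, observations, subject_id,
                             value = value, sess_rows = sess_rows)
    problems[[length(problems) + 1L]] <<-
      instantiate_problem(rule$problem_type, obs, extent)
  }
  for (rule in rules) {
    if (!rule$scope %in% c("daily", "session")) next
    pt <- rule$problem_type
    if (pt %in% sleep_rule_ids && !agg$has_sleep_data) next
    if (pt == "LackOfExercise" && agg$n_step_samples == 0) next
    if (rule$scope == "session") {  # sleep quality, one problem per session
      ps <- agg$per_session
      fail <- which(wkg_cmp(ps$efficiency, rule$comparator, rule$threshold))
      for (i in fail) {
        emit(rule, ps$efficiency[i], sess_rows = ps[i, , drop = FALSE],
             extent = c(ps$start[i], ps$end[i]))
      }
      next
    }
    value <- switch(rule$variable,
                    fall_asleep_seconds = agg$fall_asleep_seconds,
                    interruptions = agg$interruptions,
                    sleep_minutes = agg$sleep_minutes,
                    nap_minutes = agg$nap_minutes,
                    nap_to_bed_gap_minutes = agg$nap_to_bed_gap_minutes,
                    steps = agg$steps,
                    stop("unknown rule variable: ", rule$variable,
                         call. = FALSE))
    if (pt == "NapCloseToBedtime") {
      if (is.na(value) || value < 0) next  # gap must lie in [0, threshold)
    }
    if (!is.na(value) && wkg_cmp(value, rule$comparator, rule$threshold)) {
      emit(rule, value)
    }
  }
  problems
}

# Maximal runs of consecutive minute indices (strictly +1 steps).
runs_of <- function(idx) {
  if (!length(idx)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  idx <- sort(idx)
  grp <- cumsum(c(1L, as.integer(diff(idx) != 1L)))
  starts <- tapply(idx, grp, min)
  ends <- tapply(idx, grp, max)
  data.frame(start = as.integer(starts), end = as.integer(ends) + 1L,
             length = as.integer(ends - starts + 1L), row.names = NULL)
}

sum_steps_in <- function(steps_samples, start_idx, end_idx) {
  if (!nrow(steps_samples)) return(rep(0, length(start_idx)))
  idx <- wkg_minute_index(steps_samples$timestamp)
  ord <- order(idx)
  idx <- idx[ord]
  val <- steps_samples$value[ord]
  cs <- c(0, cumsum(val))
  lo <- findInterval(start_idx - 0.5, idx)
  hi <- findInterval(end_idx - 0.5, idx)
  cs[hi + 1L] - cs[lo + 1L]
}

#' Find qualifying step/heart-rate windows
#'
#' Windows are the maximal contiguous runs of minutes that each carry a
#' heart-rate sample satisfying the rule's per-minute HR comparison (a
#' missing minute breaks a run). A run qualifies when the cumulative step
#' count over the run satisfies the step comparison and the run is strictly
#' longer than the rule's minimum duration.
#'
#' @param steps,hr [sample_stream()] objects for one subject.
#' @param rule A window-scope rule spec (see [default_rulebase()]).
#' @return Data frame of qualifying windows: `start`, `end` (`POSIXct`,
#'   half-open), `length` (minutes), `total_steps`.
#' @export
find_hr_step_windows <- function(steps, hr, rule) {
  stopifnot(identical(rule$scope, "window"))
  h <- hr$samples
  empty <- data.frame(start = as.POSIXct(character(), tz = WKG_TZ),
                      end = as.POSIXct(character(), tz = WKG_TZ),
                      length = integer(), total_steps = numeric())
  if (!nrow(h)) return(empty)
  ok_idx <- wkg_minute_index(h$timestamp)[wkg_cmp(h$value, rule$hr_comparator,
                                                  rule$hr_threshold)]
  runs <- runs_of(ok_idx)
  if (!nrow(runs)) return(empty)
  runs$total_steps <- sum_steps_in(steps$samples, runs$start, runs$end)
  qual <- runs$length > rule$window_min_duration &
    wkg_cmp(runs$total_steps, rule$steps_comparator, rule$steps_threshold)
  runs <- runs[qual, , drop = FALSE]
  data.frame(start = wkg_minute_to_time(runs$start),
             end = wkg_minute_to_time(runs$end),
             length = runs$length, total_steps = runs$total_steps)
}

#' Find maximal runs of low heart-rate minutes
#'
#' Every maximal contiguous run of minutes whose heart-rate sample is
#' strictly below the threshold yields one window (no minimum duration); a
#' minute at the threshold is never included.
#'
#' @param hr A heart-rate [sample_stream()].
#' @param threshold Beats-per-minute threshold (default 60).
#' @return Data frame of runs: `start`, `end` (half-open), `length`.
#' @export
find_low_hr_runs <- function(hr, threshold = 60) {
  h <- hr$samples
  empty <- data.frame(start = as.POSIXct(character(), tz = WKG_TZ),
                      end = as.POSIXct(character(), tz = WKG_TZ),
                      length = integer())
  if (!nrow(h)) return(empty)
  runs <- runs_of(wkg_minute_index(h$timestamp)[h$value < threshold])
  data.frame(start = wkg_minute_to_time(runs$start),
             end = wkg_minute_to_time(runs$end), length = runs$length)
}

# Remove samples falling inside any sleep session interval [start, end).
# Composite activity windows describe waking behaviour; sleep minutes break
# their runs (low sleep-time heart rate would otherwise trivially satisfy
# the inactivity conditions every night).
mask_sleep_minutes <- function(stream, sessions) {
  if (!nrow(stream$samples) || !nrow(sessions)) return(stream)
  t <- stream$samples$timestamp
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sessions))) {
    inside <- inside | (t >= sessions$start[i] & t < sessions$end[i])
  }
  out <- stream
  out$samples <- stream$samples[!inside, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

window_observations <- function(observations, props, start, end) {
  sel <- observations[observations$observed_property %in% props &
                        observations$start >= start &
                        observations$start < end, , drop = FALSE]
  sel
}

#' Run the full rule base over one subject's data
#'
#' Pipeline: map inputs to classified observations, aggregate per day,
#' evaluate the daily/session rules, search the composite step/heart-rate
#' window rules over waking minutes (minutes inside a sleep session break
#' runs) and the low-heart-rate rule over the full stream, instantiate every
#' detection as a DnS problem situation, and (optionally) build the enriched
#' knowledge graph. Deterministic: identical inputs and configuration yield
#' identical problems and a byte-identical serialized graph. Problems are
#' returned sorted by (date, type, start).
#'
#' @param steps,hr [sample_stream()] objects.
#' @param sessions A `sleep_sessions` data frame.
#' @param rulebase A `rulebase` (per-subject overrides are applied).
#' @param graph Build the knowledge graph? (`TRUE` by default; skipping it
#'   makes large simulation sweeps much faster.)
#' @return List with `problems` (list of `problem_situation`), `graph` (`kg`
#'   or `NULL`), `aggregates` (list of `daily_aggregate`) and `observations`.
#' @export
run_rulebase <- function(steps, hr, sessions, rulebase = default_rulebase(),
                         graph = TRUE) {
  subj <- unique(stats::na.omit(c(steps$subject_id, hr$subject_id,
                                  if (nrow(sessions)) sessions$subject_id)))
  wkg_stopifnot(length(subj) <= 1L, "inputs mix multiple subjects")
  if (!length(subj)) subj <- "unknown"
  rules <- rulebase_for_subject(rulebase, subj)

  obs <- bind_observations(to_observations(steps, subj),
                           to_observations(hr, subj),
                           to_observations(sessions, subj))
  days <- partition_by_day(steps, hr, sessions)
  mains <- main_sleep_starts(days)

  problems <- list()
  # sample observations belong to the date of their start; sleep-session
  # observations to the date of their end, mirroring the day partition
  obs_date <- wkg_date(obs$start)
  is_sleep_obs <- obs$feature_of_interest == "sleep"
  obs_date[is_sleep_obs] <- wkg_date(obs$end[is_sleep_obs])
  for (key in names(days)) {
    agg <- compute_daily_aggregates(days[[key]], main_starts = mains)
    day_obs <- obs[obs_date == days[[key]]$date, , drop = FALSE]
    problems <- c(problems,
                  evaluate_daily_rules(agg, structure(list(rules = rules),
                                                      class = "rulebase"),
                                       observations = day_obs,
                                       subject_id = subj))
  }
  aggs <- lapply(days, compute_daily_aggregates, main_starts = mains)

  steps_wake <- mask_sleep_minutes(steps, sessions)
  hr_wake <- mask_sleep_minutes(hr, sessions)
  for (rule in rules) {
    if (!identical(rule$scope, "window")) next
    win <- find_hr_step_windows(steps_wake, hr_wake, rule)
    for (i in seq_len(nrow(win))) {
      wobs <- window_observations(obs, c("steps", "heart_rate"),
                                  win$start[i], win$end[i])
      problems[[length(problems) + 1L]] <-
        instantiate_problem(rule$problem_type, wobs,
                            c(win$start[i], win$end[i]))
    }
  }
  lhr <- rules$LowHeartRate
  if (!is.null(lhr)) {
    runs <- find_low_hr_runs(hr, threshold = lhr$threshold)
    for (i in seq_len(nrow(runs))) {
      wobs <- window_observations(obs, "heart_rate",
                                  runs$start[i], runs$end[i])
      problems[[length(problems) + 1L]] <-
        instantiate_problem("LowHeartRate", wobs,
                            c(runs$start[i], runs$end[i]))
    }
  }

  if (length(problems)) {
    ord <- order(vapply(problems, function(p) as.character(wkg_date(p$start)), ""),
                 vapply(problems, `[[`, "", "problem_type"),
                 vapply(problems, function(p) as.numeric(p$start), 0))
    problems <- problems[ord]
  }

  kg <- NULL
  if (graph) {
    kg <- build_graph(obs)
    for (p in problems) kg <- problem_to_graph(p, kg)
  }
  list(problems = problems, graph = kg, aggregates = aggs, observations = obs)
}
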