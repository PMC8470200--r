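# Seed-reproducible generator for wearable streams with the structure of the
# device's export: per-minute steps and heart rate, session-structured sleep.
# The default profile describes a compliant subject: nightly sleep of about
# 6.5-7 h in bed with good efficiency, regular daytime activity bouts keeping
# the daily step total above the exercise threshold, waking heart rate around
# the mid-80s with exercise elevations, sleeping heart rate in the mid-60s.
# Problem episodes satisfying specific rule conditions can be injected into
# single days; injections are local to the injected day.

#' Construct a synthetic subject profile
#'
#' Defaults describe a rule-compliant subject. Sleep: in bed 23:00-06:30,
#' 5-20 min to fall asleep, 10-35 awake minutes, at most 9 awakenings, so
#' nightly asleep minutes fall in roughly 395-435 and efficiency stays above
#' 85 %. Activity: 12-16 ten-minute walking bouts per day at 50-90 steps/min
#' over a 3 steps/min sedentary base, giving daily totals around 11,000
#' (never below ~8500). Heart rate: waking 84 +- 5 bpm clamped to
#' [76, 100] with bouts at 112 +- 8 clamped to [95, 135]; sleeping 66 +- 2
#' clamped to [62, 74], so the low-heart-rate threshold is never crossed.
#'
#' @param subject_id Subject identifier.
#' @param baseline_daily_steps List: `bout_rate` (expected bouts/day, capped
#'   to `bout_min`..`bout_max`), `bout_steps_mean`, `bout_steps_sd`,
#'   `base_rate` (sedentary steps/min).
#' @param sleep_schedule List: `bedtime`, `wake` (HH:MM), `fall_asleep_mean`.
#' @param hr_baseline List: `wake_mean`, `wake_sd`, `sleep_mean`, `sleep_sd`.
#' @param nap_propensity List: `prob`, `duration_mean`, `duration_sd`.
#' @return An object of class `synthetic_profile`.
#' @export
synthetic_profile <- function(subject_id = "tms6",
                              baseline_daily_steps = list(
                                bout_rate = 14, bout_min = 12, bout_max = 16,
                                bout_steps_mean = 65, bout_steps_sd = 10,
                                base_rate = 3),
                              sleep_schedule = list(
                                bedtime = "23:00", wake = "06:30",
                                fall_asleep_mean = 12),
                              hr_baseline = list(
                                wake_mean = 84, wake_sd = 5,
                                sleep_mean = 66, sleep_sd = 2),
                              nap_propensity = list(
                                prob = 0.15, duration_mean = 32,
                                duration_sd = 6)) {
  wkg_stopifnot(nap_propensity$prob >= 0 && nap_propensity$prob <= 1,
                "nap probability must lie in [0, 1]")
  structure(list(subject_id = subject_id,
                 baseline_daily_steps = baseline_daily_steps,
                 sleep_schedule = sleep_schedule,
                 hr_baseline = hr_baseline,
                 nap_propensity = nap_propensity),
            class = "synthetic_profile")
}

#' Read / write a synthetic profile (YAML or JSON)
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A `synthetic_profile`.
#' @export
read_profile <- function(path) {
  wkg_stopifnot(file.exists(path), paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(synthetic_profile, cfg)
}

#' @rdname read_profile
#' @param profile A `synthetic_profile`.
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(unclass(profile), path)
  invisible(path)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

hm_minutes <- function(hm) {
  parts <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1]])
  parts[1] * 60L + parts[2]
}

# One night session ending on `date` (in bed bedtime(prev day) .. wake).
gen_night_session <- function(profile, date) {
  ss <- profile$sleep_schedule
  bed_min <- hm_minutes(ss$bedtime)
  wake_min <- hm_minutes(ss$wake)
  start <- as.POSIXct(paste(date - 1, "00:00:00"), tz = WKG_TZ) + bed_min * 60
  end <- as.POSIXct(paste(date, "00:00:00"), tz = WKG_TZ) + wake_min * 60
  in_bed <- as.numeric(difftime(end, start, units = "mins"))
  fall <- round(clamp(stats::rnorm(1, ss$fall_asleep_mean, 4), 5, 20))
  awake <- round(clamp(stats::rnorm(1, 24, 6), 10, 35))
  awakenings <- min(stats::rpois(1, 5), 9L)
  asleep <- in_bed - fall - awake
  deep <- round(0.20 * asleep)
  rem <- round(0.22 * asleep)
  light <- asleep - deep - rem
  data.frame(subject_id = profile$subject_id,
             start = start, end = end, duration_ms = in_bed * 60000,
             minutes_to_fall_asleep = fall, minutes_deep = deep,
             minutes_light = light, minutes_rem = rem, minutes_awake = awake,
             awakenings_count = awakenings, efficiency = NA_real_,
             is_main_sleep = TRUE)
}

gen_nap_session <- function(profile, date, start_min = NULL, duration = NULL,
                            fall = 2) {
  np <- profile$nap_propensity
  if (is.null(duration)) {
    duration <- round(clamp(stats::rnorm(1, np$duration_mean, np$duration_sd),
                            20, 40))
  }
  if (is.null(start_min)) start_min <- 13L * 60L + stats::rbinom(1, 60, 0.5)
  start <- as.POSIXct(paste(date, "00:00:00"), tz = WKG_TZ) + start_min * 60
  asleep <- duration - fall
  data.frame(subject_id = profile$subject_id,
             start = start, end = start + duration * 60,
             duration_ms = duration * 60000,
             minutes_to_fall_asleep = fall, minutes_deep = round(0.2 * asleep),
             minutes_light = asleep - round(0.2 * asleep) - round(0.2 * asleep),
             minutes_rem = round(0.2 * asleep), minutes_awake = 0,
             awakenings_count = 0L, efficiency = NA_real_,
             is_main_sleep = FALSE)
}

#' Generate synthetic wearable data for one subject
#'
#' Produces per-minute step and heart-rate streams covering every minute of
#' `n_days` consecutive dates (steps are zero and heart rate is at the
#' sleeping baseline during sleep sessions) plus one main sleep session per
#' date and occasional naps. A fixed seed yields identical output.
#'
#' @param profile A [synthetic_profile()].
#' @param n_days Number of days (>= 0).
#' @param seed Integer seed governing all draws.
#' @param start_date First date (default `"2021-03-01"`).
#' @return List with `steps` and `hr` ([sample_stream()]) and `sessions`
#'   (`sleep_sessions`).
#' @export
generate_subject_days <- function(profile, n_days, seed,
                                  start_date = "2021-03-01") {
  stopifnot(inherits(profile, "synthetic_profile"))
  wkg_stopifnot(n_days >= 0, "n_days must be non-negative")
  if (n_days == 0) {
    return(list(steps = sample_stream(profile$subject_id, "steps"),
                hr = sample_stream(profile$subject_id, "heart_rate"),
                sessions = sleep_sessions(NULL)))
  }
  set.seed(as.integer(seed))
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  bs <- profile$baseline_daily_steps
  hb <- profile$hr_baseline
  wake_min <- hm_minutes(profile$sleep_schedule$wake)
  bed_min <- hm_minutes(profile$sleep_schedule$bedtime)

  sessions <- list()
  steps_v <- hr_v <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    date <- dates[d]
    sess <- gen_night_session(profile, date)
    naps <- NULL
    if (stats::runif(1) < profile$nap_propensity$prob) {
      naps <- gen_nap_session(profile, date)
    }
    sessions[[d]] <- rbind(sess, naps)

    # minute grid for the calendar day
    minute <- 0:1439
    asleep_now <- minute < wake_min | minute >= bed_min
    if (!is.null(naps)) {
      nstart <- (as.numeric(naps$start) %% 86400) / 60
      nend <- nstart + naps$duration_ms / 60000
      asleep_now <- asleep_now | (minute >= nstart & minute < nend)
    }
    n_wake <- sum(!asleep_now)

    # activity bouts: 10-minute walking blocks at elevated step rate and HR,
    # one per chosen fully-waking hour block (disjoint by construction, so a
    # compliant day's step total cannot collapse through bout overlap)
    hour_starts <- seq(wake_min, bed_min - 60L, by = 60L)
    fully_awake <- vapply(hour_starts, function(h) {
      all(!asleep_now[(h + 1L):(h + 60L)])
    }, TRUE)
    blocks <- hour_starts[fully_awake]
    n_bouts <- clamp(stats::rpois(1, bs$bout_rate), bs$bout_min,
                     min(bs$bout_max, length(blocks)))
    anchors <- sort(sample(blocks, n_bouts)) +
      sample(0:49, n_bouts, replace = TRUE)
    in_bout <- rep(FALSE, 1440)
    for (a in anchors) in_bout[(a + 1L):(a + 10L)] <- TRUE
    in_bout <- in_bout & !asleep_now

    stepv <- integer(1440)
    stepv[!asleep_now] <- stats::rpois(n_wake, bs$base_rate)
    nb <- sum(in_bout)
    stepv[in_bout] <- round(clamp(stats::rnorm(nb, bs$bout_steps_mean,
                                               bs$bout_steps_sd), 50, 90))
    hrv <- numeric(1440)
    hrv[asleep_now] <- round(clamp(stats::rnorm(sum(asleep_now),
                                                hb$sleep_mean, hb$sleep_sd),
                                   62, 74))
    hrv[!asleep_now] <- round(clamp(stats::rnorm(n_wake, hb$wake_mean,
                                                 hb$wake_sd), 76, 100))
    hrv[in_bout] <- round(clamp(stats::rnorm(nb, 112, 8), 95, 135))

    steps_v[[d]] <- stepv
    hr_v[[d]] <- hrv
  }
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = WKG_TZ)
  ts <- t0 + (seq_len(n_days * 1440) - 1L) * 60
  list(steps = sample_stream(profile$subject_id, "steps", ts,
                             unlist(steps_v)),
       hr = sample_stream(profile$subject_id, "heart_rate", ts,
                          unlist(hr_v)),
       sessions = sleep_sessions(do.call(rbind, sessions)))
}

set_stream_values <- function(stream, from, to, value) {
  sel <- stream$samples$timestamp >= from & stream$samples$timestamp < to
  stream$samples$value[sel] <- value
  stream
}

# Recompute efficiency and duration after editing session fields.
refresh_session <- function(s) {
  dur <- as.numeric(difftime(s$end, s$start, units = "mins"))
  s$duration_ms <- dur * 60000
  asleep <- s$minutes_deep + s$minutes_light + s$minutes_rem
  s$efficiency <- round_half_away(100 * asleep / dur)
  s
}

day_time <- function(date, hm) {
  as.POSIXct(paste(date, "00:00:00"), tz = WKG_TZ) + hm_minutes(hm) * 60
}

#' Inject a problem episode into generated data
#'
#' Modifies the streams/sessions of one day so that the day provably
#' satisfies the target rule's condition (the templates place values well
#' past the threshold, e.g. 2400 s to fall asleep against the 1800 s insomnia
#' limit, or a 310-minute zero-step block against the 300-minute inactivity
#' window). Stream and session invariants are preserved and only the
#' injected day's data are touched, so detector output on all other days is
#' unchanged. An injected day may additionally trip neighbouring rules (for
#' example a long stress window also suppresses the day's step total); the
#' guarantee is that the target rule fires.
#'
#' @param data List as returned by [generate_subject_days()].
#' @param problem_type One of [problem_types()].
#' @param date `Date` (or string) within the generated range. The
#'   nap-close-to-bedtime template needs a following day's main sleep, so
#'   `date` must not be the last generated date for that type.
#' @param params Optional template tweaks (unused fields ignored).
#' @return The modified data list.
#' @export
inject_problem_episode <- function(data, problem_type, date, params = list()) {
  wkg_stopifnot(problem_type %in% problem_types(),
                paste0("unknown problem type: ", problem_type))
  date <- as.Date(date)
  dates <- unique(wkg_date(data$steps$samples$timestamp))
  wkg_stopifnot(date %in% dates,
                paste0("date ", date, " outside generated range"))
  sess <- as.data.frame(data$sessions)
  sess_date <- wkg_date(sess$end)
  main_row <- which(sess_date == date & sess$is_main_sleep)
  profile <- synthetic_profile(subject_id = sess$subject_id[1] %||%
                                 data$steps$subject_id)

  edit_main <- function(f) {
    wkg_stopifnot(length(main_row) == 1L,
                  "injected day has no main sleep session")
    sess[main_row, ] <<- refresh_session(f(sess[main_row, , drop = FALSE]))
  }
  block <- function(hm_from, minutes, hr_value, hr_boundary = NULL,
                    zero_steps = TRUE) {
    from <- day_time(date, hm_from)
    to <- from + minutes * 60
    data$hr <<- set_stream_values(data$hr, from, to, hr_value)
    if (!is.null(hr_boundary)) {
      data$hr <<- set_stream_values(data$hr, from - 60, from, hr_boundary)
      data$hr <<- set_stream_values(data$hr, to, to + 60, hr_boundary)
    }
    if (zero_steps) data$steps <<- set_stream_values(data$steps, from, to, 0)
  }

  switch(problem_type,
    Insomnia = edit_main(function(s) {
      delta <- 40 - s$minutes_to_fall_asleep
      s$minutes_to_fall_asleep <- 40          # 2400 s > 1800 s
      s$minutes_light <- s$minutes_light - delta
      s
    }),
    Restlessness = edit_main(function(s) {
      s$awakenings_count <- params$awakenings %||% 12L   # > 10
      s
    }),
    TooMuchSleep = edit_main(function(s) {
      s$end <- s$end + 90 * 60
      s$minutes_light <- s$minutes_light + 90  # asleep >= 485 > 480
      s
    }),
    LackOfSleep = edit_main(function(s) {
      s$end <- s$start + 300 * 60
      s$minutes_to_fall_asleep <- 10
      s$minutes_awake <- 15
      s$minutes_deep <- 55
      s$minutes_rem <- 55
      s$minutes_light <- 150                   # asleep 260 < 300
      s
    }),
    IncreasedNapping = {
      edit_main(function(s) {
        s$end <- s$end - 110 * 60
        s$minutes_light <- s$minutes_light - 110
        s
      })
      naps <- rbind(
        gen_nap_session(profile, date, start_min = 10 * 60, duration = 58,
                        fall = 3),
        gen_nap_session(profile, date, start_min = 15 * 60, duration = 58,
                        fall = 3))                 # 2 x 55 asleep > 100
      sess <- rbind(sess, naps)
    },
    NapCloseToBedtime = {
      wkg_stopifnot(date < max(dates),
                    "nap-close-to-bedtime needs a following main sleep")
      nap <- gen_nap_session(profile, date, start_min = 20 * 60 + 45,
                             duration = 35, fall = 3)  # ends 21:20, gap 100'
      sess <- rbind(sess, nap)
    },
    LowSleepQuality = edit_main(function(s) {
      delta <- 90 - s$minutes_awake
      s$minutes_awake <- 90
      s$minutes_light <- s$minutes_light - delta  # efficiency <= 80 < 85
      s
    }),
    # the composite-window templates drop the day's naps first: a nap inside
    # the injected block would mask out minutes and split the run
    StressOrPain = {
      sess <- sess[!(sess_date == date & !sess$is_main_sleep), , drop = FALSE]
      block("13:00", 310, hr_value = 95, hr_boundary = 85)
    },
    LowHeartRate = block("14:00", params$minutes %||% 15, hr_value = 55,
                         zero_steps = FALSE),
    Inactivity = {
      sess <- sess[!(sess_date == date & !sess$is_main_sleep), , drop = FALSE]
      block("13:00", 310, hr_value = 72, hr_boundary = 88)
    },
    LackOfMovement = {
      sess <- sess[!(sess_date == date & !sess$is_main_sleep), , drop = FALSE]
      block("07:00", 820, hr_value = 85, hr_boundary = 105)
    },
    LackOfExercise = {
      sel <- wkg_date(data$steps$samples$timestamp) == date
      v <- data$steps$samples$value[sel]
      total <- sum(v)
      if (total > 0) {
        data$steps$samples$value[sel] <- floor(v * 4000 / total)
      }
    })
  data$sessions <- sleep_sessions(sess)
  data
}

#' Generate standalone classified observations for benchmarking
#'
#' Draws `n` observations with a realistic property mix (mostly per-minute
#' steps and heart rate with a sleep-derived tail), consecutive minute
#' intervals, and runs the classifier on each.
#'
#' @param n Number of observations (>= 0).
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return An `observations` data frame with `n` rows.
#' @export
generate_benchmark_objects <- function(n, seed, subject_id = "bench") {
  wkg_stopifnot(n >= 0, "n must be non-negative")
  if (n == 0) return(empty_observations())
  set.seed(as.integer(seed))
  props <- c(steps = 0.42, heart_rate = 0.42, asleep_duration = 0.04,
             awake_count = 0.04, awake_duration = 0.04,
             minutes_to_fall_asleep = 0.02, efficiency = 0.02)
  prop <- sample(names(props), n, replace = TRUE, prob = props)
  feat <- ifelse(prop == "steps", "movement",
                 ifelse(prop == "heart_rate", "heart", "sleep"))
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = WKG_TZ)
  start <- t0 + (seq_len(n) - 1L) * 60
  value <- round(stats::runif(n, 0, 120))
  out <- do.call(rbind, lapply(unique(prop), function(p) {
    sel <- prop == p
    make_observations(subject_id, feat[sel][1], p, value[sel], "unit",
                      start[sel], start[sel] + 60)
  }))
  out <- out[order(out$start, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observations", "data.frame")
  out
}
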