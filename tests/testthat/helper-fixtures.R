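# Shared fixture builders. All timestamps are in the package's implicit
# timezone; helpers construct minimal valid inputs around a reference day.

t_at <- function(x) as.POSIXct(x, tz = "UTC",
                               tryFormats = c("%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%d %H:%M"))

# A stream of consecutive minutes starting at `from`.
minute_stream <- function(kind, values, from = "2021-03-01 08:00",
                          subject = "tms6") {
  ts <- t_at(from) + (seq_along(values) - 1L) * 60
  sample_stream(subject, kind, ts, values)
}

# empty streams carry no subject so they combine with any sessions input
empty_steps <- function(subject = NA_character_) sample_stream(subject, "steps")
empty_hr <- function(subject = NA_character_) sample_stream(subject, "heart_rate")

# One sleep session; stage minutes default to a consistent decomposition of
# `asleep` minutes within the in-bed interval.
make_session <- function(start, end, asleep = NULL, fall = 10, awake = 20,
                         awakenings = 5, efficiency = NA, subject = "tms6",
                         is_main = NA) {
  start <- t_at(start); end <- t_at(end)
  in_bed <- as.numeric(difftime(end, start, units = "mins"))
  if (is.null(asleep)) asleep <- in_bed - fall - awake
  deep <- floor(asleep * 0.2)
  rem <- floor(asleep * 0.2)
  data.frame(subject_id = subject, start = start, end = end,
             duration_ms = in_bed * 60000, minutes_to_fall_asleep = fall,
             minutes_deep = deep, minutes_light = asleep - deep - rem,
             minutes_rem = rem, minutes_awake = awake,
             awakenings_count = awakenings, efficiency = efficiency,
             is_main_sleep = is_main)
}

fired_types <- function(result) {
  vapply(result$problems, function(p) p$problem_type, "")
}

# Date a problem is attributed to: the last day its extent touches (daily
# extents end at the next midnight, so subtract a second).
problem_day <- function(p) as.Date(p$end - 1, tz = "UTC")

# Run the detector on streams/sessions given as plain pieces.
detect <- function(steps = empty_steps(), hr = empty_hr(),
                   sessions = sleep_sessions(NULL), ...) {
  run_rulebase(steps, hr, sessions, graph = FALSE, ...)
}
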