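# Detector-driven threshold probes: construct a minimal input in which one
# rule's decision variable takes a prescribed value, run the full detector,
# and report whether the rule fired. Used for boundary sweeps: the printed
# threshold must be the exact switch point of each strict comparison.

probe_subject <- "probe"

# Sessions for the daily sleep-rule probes; the session ends on 2021-03-02.
probe_fires <- function(problem_type, value) {
  ss <- function(df) sleep_sessions(df)
  res <- switch(problem_type,
    Insomnia = detect(sessions = ss(make_session(
      "2021-03-01 23:00", "2021-03-02 06:30", fall = value / 60,
      subject = probe_subject))),
    Restlessness = detect(sessions = ss(make_session(
      "2021-03-01 23:00", "2021-03-02 06:30", awakenings = value,
      subject = probe_subject))),
    TooMuchSleep = detect(sessions = ss(make_session(
      "2021-03-01 21:00", "2021-03-02 11:00", asleep = value, awake = 0,
      fall = 5, subject = probe_subject))),
    LackOfSleep = detect(sessions = ss(make_session(
      "2021-03-01 21:00", "2021-03-02 11:00", asleep = value, awake = 0,
      fall = 5, subject = probe_subject))),
    IncreasedNapping = detect(sessions = ss(rbind(
      make_session("2021-03-01 23:00", "2021-03-02 06:30", asleep = 400,
                   awake = 20, fall = 10, subject = probe_subject),
      make_session("2021-03-02 12:00", "2021-03-02 20:00", asleep = value,
                   awake = 0, fall = 5, subject = probe_subject)))),
    NapCloseToBedtime = detect(sessions = ss(rbind(
      make_session("2021-03-01 23:00", "2021-03-02 06:30",
                   subject = probe_subject, is_main = TRUE),
      make_session("2021-03-02 23:00", "2021-03-03 06:30",
                   subject = probe_subject, is_main = TRUE),
      make_session(t_at("2021-03-02 23:00") - (value + 40) * 60,
                   t_at("2021-03-02 23:00") - value * 60,
                   asleep = 35, awake = 0, fall = 5,
                   subject = probe_subject, is_main = FALSE)))),
    LowSleepQuality = detect(sessions = ss(make_session(
      "2021-03-01 23:00", "2021-03-02 06:30", efficiency = value,
      subject = probe_subject))),
    LackOfExercise = detect(steps = minute_stream(
      "steps", value, from = "2021-03-01 10:00", subject = probe_subject)),
    LowHeartRate = detect(hr = minute_stream(
      "heart_rate", value, from = "2021-03-01 10:00",
      subject = probe_subject)),
    stop("no scalar probe for ", problem_type))
  problem_type %in% fired_types(res)
}

# Composite window probes: run of `run_len` minutes with constant HR
# `hr_value` and `step_total` steps placed inside the run.
window_probe_fires <- function(problem_type, hr_value, step_total, run_len) {
  hr <- minute_stream("heart_rate", rep(hr_value, run_len),
                      from = "2021-03-01 00:30", subject = probe_subject)
  steps <- if (step_total > 0) {
    minute_stream("steps", step_total, from = "2021-03-01 00:31",
                  subject = probe_subject)
  } else empty_steps(probe_subject)
  res <- detect(steps = steps, hr = hr)
  problem_type %in% fired_types(res)
}

# Largest integer argument for which the probe does NOT fire, given that
# firing is monotone increasing in the argument (">"-style rules); binary
# search over [lo, hi].
recover_gt_threshold <- function(fires, lo, hi) {
  stopifnot(!fires(lo), fires(hi))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (fires(mid)) hi <- mid else lo <- mid
  }
  lo
}

# Smallest integer argument for which the probe does NOT fire ("<"-style).
recover_lt_threshold <- function(fires, lo, hi) {
  stopifnot(fires(lo), !fires(hi))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (fires(mid)) lo <- mid else hi <- mid
  }
  hi
}
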