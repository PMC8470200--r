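# Dashboard-style data transformations: resampling a per-minute stream to a
# coarser resolution with sum or average aggregation, min/avg/max summaries,
# a daily sleep series with stage breakdown, and a problem timeline.

bucket_start <- function(t, resolution) {
  switch(resolution,
    minute = as.POSIXct(trunc(t, "mins"), tz = WKG_TZ),
    hour = as.POSIXct(trunc(t, "hours"), tz = WKG_TZ),
    day = as.POSIXct(trunc(t, "days"), tz = WKG_TZ),
    week = {
      d <- wkg_date(t)
      monday <- d - (as.integer(format(d, "%u")) - 1L)
      as.POSIXct(paste(monday, "00:00:00"), tz = WKG_TZ)
    },
    month = as.POSIXct(paste0(format(t, "%Y-%m"), "-01 00:00:00"), tz = WKG_TZ),
    year = as.POSIXct(paste0(format(t, "%Y"), "-01-01 00:00:00"), tz = WKG_TZ),
    stop("invalid resolution: ", resolution, call. = FALSE))
}

#' Resample a per-minute stream
#'
#' Buckets are aligned to calendar boundaries (weeks start Monday); empty
#' buckets are omitted; `sum` aggregation conserves the in-range total.
#'
#' @param stream A [sample_stream()].
#' @param resolution One of `"minute"`, `"hour"`, `"day"`, `"week"`,
#'   `"month"`, `"year"`.
#' @param agg `"sum"` or `"average"`.
#' @param date_range Optional length-2 `POSIXct` (or `Date`) filter,
#'   half-open `[from, to)`.
#' @return A `resampled_series`: data frame (`bucket`, `value`) with
#'   attributes `resolution` and `agg`, ordered by bucket.
#' @export
resample <- function(stream, resolution, agg = c("sum", "average"),
                     date_range = NULL) {
  agg <- match.arg(agg)
  resolution <- match.arg(resolution,
                          c("minute", "hour", "day", "week", "month", "year"))
  s <- stream$samples
  if (!is.null(date_range)) {
    from <- as.POSIXct(date_range[1], tz = WKG_TZ)
    to <- as.POSIXct(date_range[2], tz = WKG_TZ)
    s <- s[s$timestamp >= from & s$timestamp < to, , drop = FALSE]
  }
  if (!nrow(s)) {
    out <- data.frame(bucket = as.POSIXct(character(), tz = WKG_TZ),
                      value = numeric())
  } else {
    b <- bucket_start(s$timestamp, resolution)
    f <- if (agg == "sum") sum else mean
    agg_v <- tapply(s$value, as.numeric(b), f)
    out <- data.frame(
      bucket = as.POSIXct(as.numeric(names(agg_v)), origin = "1970-01-01",
                          tz = WKG_TZ),
      value = as.numeric(agg_v))
    out <- out[order(out$bucket), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, resolution = resolution, agg = agg,
            class = c("resampled_series", "data.frame"))
}

#' Average, minimum and maximum of a resampled series
#' @param series A `resampled_series` (or any data frame with a `value`
#'   column); must be non-empty.
#' @return List with `average`, `minimum`, `maximum`.
#' @export
summary_stats <- function(series) {
  wkg_stopifnot(nrow(series) > 0, "summary of an empty series")
  list(average = mean(series$value), minimum = min(series$value),
       maximum = max(series$value))
}

#' Daily sleep series with stage breakdown
#'
#' One row per day (sessions attributed to the day they end on): total
#' asleep minutes plus per-stage payload columns.
#'
#' @param sessions A `sleep_sessions` data frame.
#' @return Data frame: `date`, `sleep_minutes`, `minutes_deep`,
#'   `minutes_light`, `minutes_rem`, `minutes_awake`.
#' @export
sleep_daily_series <- function(sessions) {
  if (!nrow(sessions)) {
    return(data.frame(date = as.Date(character()), sleep_minutes = numeric(),
                      minutes_deep = numeric(), minutes_light = numeric(),
                      minutes_rem = numeric(), minutes_awake = numeric()))
  }
  d <- wkg_date(sessions$end)
  agg <- function(v) as.numeric(tapply(v, d, sum))
  out <- data.frame(date = sort(unique(d)),
                    sleep_minutes = agg(session_asleep_minutes(sessions)),
                    minutes_deep = agg(sessions$minutes_deep),
                    minutes_light = agg(sessions$minutes_light),
                    minutes_rem = agg(sessions$minutes_rem),
                    minutes_awake = agg(sessions$minutes_awake))
  rownames(out) <- NULL
  out
}

#' Problem timeline
#'
#' Filters detected problems to a date range and orders them by start time,
#' breaking ties by problem type name.
#'
#' @param problems List of `problem_situation` objects.
#' @param date_range Optional length-2 bound (`[from, to)`) on the problem
#'   start.
#' @return Data frame: `start`, `end`, `problem_type`, `category`,
#'   `subject_id`, `id`.
#' @export
problem_timeline <- function(problems, date_range = NULL) {
  if (!length(problems)) {
    return(data.frame(start = as.POSIXct(character(), tz = WKG_TZ),
                      end = as.POSIXct(character(), tz = WKG_TZ),
                      problem_type = character(), category = character(),
                      subject_id = character(), id = character()))
  }
  df <- do.call(rbind, lapply(problems, function(p) {
    data.frame(start = p$start, end = p$end, problem_type = p$problem_type,
               category = p$category, subject_id = p$subject_id, id = p$id,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(date_range)) {
    from <- as.POSIXct(date_range[1], tz = WKG_TZ)
    to <- as.POSIXct(date_range[2], tz = WKG_TZ)
    df <- df[df$start >= from & df$start < to, , drop = FALSE]
  }
  df <- df[order(df$start, df$problem_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a front-end-consumable report
#'
#' Bundles resampled step and heart-rate series (with min/avg/max
#' summaries), the daily sleep series and the problem timeline for one
#' subject and range.
#'
#' @param detection Result of [run_rulebase()].
#' @param steps,hr [sample_stream()] inputs.
#' @param sessions `sleep_sessions` input.
#' @param resolution,agg Passed to [resample()].
#' @param date_range Optional range filter.
#' @return A list ready for `jsonlite::write_json()`.
#' @export
build_report <- function(detection, steps, hr, sessions,
                         resolution = "day", agg = "sum", date_range = NULL) {
  series <- function(stream) {
    rs <- resample(stream, resolution, agg, date_range)
    list(points = data.frame(bucket = wkg_format_time(rs$bucket),
                             value = rs$value),
         summary = if (nrow(rs)) summary_stats(rs) else NULL)
  }
  tl <- problem_timeline(detection$problems, date_range)
  tl$start <- wkg_format_time(tl$start)
  tl$end <- wkg_format_time(tl$end)
  sl <- sleep_daily_series(sessions)
  sl$date <- as.character(sl$date)
  list(resolution = resolution, aggregation = agg,
       steps = series(steps), heart_rate = series(hr),
       sleep = sl, problems = tl)
}
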