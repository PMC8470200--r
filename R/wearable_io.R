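# Readers and writers for the wearable data streams: per-minute sample
# streams (steps, heart rate), session-structured sleep records, and the
# problem records produced by the rule engine. Missing minutes are represented
# by absence, never by zero.

#' Construct a per-minute sample stream
#'
#' A sample stream holds one subject's per-minute measurements of a single
#' kind: `"steps"` (non-negative integer step counts) or `"heart_rate"`
#' (non-negative beats per minute). Timestamps must be strictly increasing at
#' minute resolution; samples are sorted by timestamp before validation.
#'
#' @param subject_id Subject identifier.
#' @param kind `"steps"` or `"heart_rate"`.
#' @param timestamps `POSIXct` vector (minute resolution, single implicit
#'   timezone).
#' @param values Numeric vector, same length as `timestamps`; values must be
#'   non-negative and, for steps, whole numbers.
#' @return An object of class `sample_stream`: a list with `subject_id`,
#'   `kind` and a `samples` data frame (`timestamp`, `value`).
#' @export
sample_stream <- function(subject_id, kind = c("steps", "heart_rate"),
                          timestamps = as.POSIXct(character(), tz = WKG_TZ),
                          values = numeric()) {
  kind <- match.arg(kind)
  wkg_stopifnot(length(timestamps) == length(values),
                "timestamps and values must have equal length")
  ord <- order(timestamps)
  timestamps <- timestamps[ord]
  values <- as.numeric(values[ord])
  if (anyDuplicated(timestamps)) {
    dup <- timestamps[duplicated(timestamps)][1L]
    stop("duplicate timestamp: ", wkg_format_time(dup), call. = FALSE)
  }
  if (length(values) && any(values < 0)) {
    stop("negative value in ", kind, " stream", call. = FALSE)
  }
  if (kind == "steps" && length(values) && any(values != floor(values))) {
    stop("steps values must be integers", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), kind = kind,
         samples = data.frame(timestamp = timestamps, value = values)),
    class = "sample_stream"
  )
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("<sample_stream> subject=%s kind=%s n=%d\n",
              x$subject_id, x$kind, nrow(x$samples)))
  if (nrow(x$samples)) {
    cat(sprintf("  range %s .. %s\n",
                wkg_format_time(min(x$samples$timestamp)),
                wkg_format_time(max(x$samples$timestamp))))
  }
  invisible(x)
}

#' Read a per-minute sample stream from CSV
#'
#' The CSV dialect is comma-separated with a mandatory header row
#' `subject_id,timestamp,value`, UTF-8, ISO-8601 timestamps without a
#' timezone designator. Rows are sorted by timestamp before the invariants
#' are checked; duplicate timestamps, negative values and malformed rows are
#' rejected.
#'
#' @param path CSV file path.
#' @param kind `"steps"` or `"heart_rate"`.
#' @return A [sample_stream()]. An empty file (header only, or zero bytes)
#'   yields an empty stream with `subject_id = NA`.
#' @export
read_sample_stream <- function(path, kind = c("steps", "heart_rate")) {
  kind <- match.arg(kind)
  wkg_stopifnot(file.exists(path), paste0("file not found: ", path))
  if (file.size(path) == 0) return(sample_stream(NA_character_, kind))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("subject_id", "timestamp", "value")
  wkg_stopifnot(all(need %in% names(df)),
                paste0("CSV must have columns ", paste(need, collapse = ",")))
  if (!nrow(df)) return(sample_stream(NA_character_, kind))
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals)) {
    stop("malformed row ", which(is.na(vals))[1L] + 1L,
         ": non-numeric value '", df$value[which(is.na(vals))[1L]], "'",
         call. = FALSE)
  }
  subj <- unique(df$subject_id)
  wkg_stopifnot(length(subj) == 1L, "stream file mixes multiple subjects")
  ts <- tryCatch(wkg_parse_time(df$timestamp), error = function(e) {
    stop("malformed row: ", conditionMessage(e), call. = FALSE)
  })
  sample_stream(subj, kind, ts, vals)
}

#' Write a sample stream to CSV
#'
#' Inverse of [read_sample_stream()]: `read_sample_stream(write_sample_stream(s))`
#' reproduces `s` exactly.
#'
#' @param stream A [sample_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sample_stream"))
  df <- data.frame(subject_id = rep(stream$subject_id, nrow(stream$samples)),
                   timestamp = wkg_format_time(stream$samples$timestamp),
                   value = stream$samples$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sleep_session_cols <- c("subject_id", "start", "end", "duration_ms",
                        "minutes_to_fall_asleep", "minutes_deep",
                        "minutes_light", "minutes_rem", "minutes_awake",
                        "awakenings_count", "efficiency", "is_main_sleep")

#' Construct a table of sleep sessions
#'
#' Each row is one continuous sleep session. Minutes asleep is the sum of the
#' deep, light and REM stage minutes; time in bed is `end - start`. When
#' `efficiency` is absent it is computed as
#' `round(100 * minutes asleep / minutes in bed)` with ties rounded away from
#' zero. Sessions are returned sorted by `start`.
#'
#' @param df Data frame with columns `subject_id`, `start`, `end` (`POSIXct`
#'   or ISO-8601 strings), `minutes_to_fall_asleep`, `minutes_deep`,
#'   `minutes_light`, `minutes_rem`, `minutes_awake`, `awakenings_count`, and
#'   optionally `duration_ms`, `efficiency` (percent, 0-100) and
#'   `is_main_sleep` (logical).
#' @return A data frame of class `sleep_sessions`, sorted by `start`, with
#'   all of the above columns plus a computed `efficiency` where missing.
#' @export
sleep_sessions <- function(df) {
  if (is.null(df) || !nrow(df)) {
    out <- data.frame(subject_id = character(),
                      start = as.POSIXct(character(), tz = WKG_TZ),
                      end = as.POSIXct(character(), tz = WKG_TZ),
                      duration_ms = numeric(), minutes_to_fall_asleep = numeric(),
                      minutes_deep = numeric(), minutes_light = numeric(),
                      minutes_rem = numeric(), minutes_awake = numeric(),
                      awakenings_count = integer(), efficiency = numeric(),
                      is_main_sleep = logical())
    class(out) <- c("sleep_sessions", "data.frame")
    return(out)
  }
  df <- as.data.frame(df)
  if (is.character(df$start)) df$start <- wkg_parse_time(df$start)
  if (is.character(df$end)) df$end <- wkg_parse_time(df$end)
  if (is.null(df$efficiency)) df$efficiency <- NA_real_
  if (is.null(df$is_main_sleep)) df$is_main_sleep <- NA
  if (is.null(df$duration_ms)) df$duration_ms <- NA_real_

  dur_min <- as.numeric(difftime(df$end, df$start, units = "mins"))
  if (any(dur_min <= 0)) stop("sleep session with end <= start", call. = FALSE)
  stage_cols <- c("minutes_deep", "minutes_light", "minutes_rem", "minutes_awake")
  for (cc in c(stage_cols, "minutes_to_fall_asleep")) {
    if (any(df[[cc]] < 0)) stop("negative stage minutes: ", cc, call. = FALSE)
  }
  if (any(df$awakenings_count < 0)) {
    stop("negative awakenings_count", call. = FALSE)
  }
  stage_sum <- rowSums(df[stage_cols])
  if (any(stage_sum > dur_min + 1)) {
    stop("stage minutes exceed session duration", call. = FALSE)
  }
  df$duration_ms <- ifelse(is.na(df$duration_ms), dur_min * 60000, df$duration_ms)
  asleep <- df$minutes_deep + df$minutes_light + df$minutes_rem
  eff <- round_half_away(100 * asleep / dur_min)
  df$efficiency <- ifelse(is.na(df$efficiency), eff, df$efficiency)
  if (any(df$efficiency < 0 | df$efficiency > 100)) {
    stop("efficiency outside [0, 100]", call. = FALSE)
  }
  df <- df[order(df$start), sleep_session_cols]
  rownames(df) <- NULL
  class(df) <- c("sleep_sessions", "data.frame")
  df
}

# Minutes asleep for each session (deep + light + REM).
session_asleep_minutes <- function(sessions) {
  sessions$minutes_deep + sessions$minutes_light + sessions$minutes_rem
}

#' Read sleep sessions from a JSON file
#'
#' Expects a JSON array of session records with fields `subject_id`, `start`,
#' `end`, `minutes_to_fall_asleep`, `minutes_deep`, `minutes_light`,
#' `minutes_rem`, `minutes_awake`, `awakenings_count` and optionally
#' `efficiency` and `is_main_sleep`. Validation and efficiency computation as
#' in [sleep_sessions()].
#'
#' @param path JSON file path.
#' @return A `sleep_sessions` data frame sorted by `start`.
#' @export
read_sleep_sessions <- function(path) {
  wkg_stopifnot(file.exists(path), paste0("file not found: ", path))
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(recs) || (is.data.frame(recs) && !nrow(recs)) ||
      (is.list(recs) && !length(recs))) {
    return(sleep_sessions(NULL))
  }
  sleep_sessions(as.data.frame(recs))
}

#' Write sleep sessions to JSON
#'
#' @param sessions A `sleep_sessions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_sessions <- function(sessions, path) {
  df <- as.data.frame(sessions)
  df$start <- wkg_format_time(df$start)
  df$end <- wkg_format_time(df$end)
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

problem_record <- function(p) {
  data.frame(id = p$id, problem_type = p$problem_type, category = p$category,
             subject_id = p$subject_id,
             start = wkg_format_time(p$start), end = wkg_format_time(p$end),
             observation_ids = paste(p$observation_ids, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write detected problems to JSON or CSV
#'
#' One record per problem with its type, category, subject, temporal extent
#' and the ids of the interpreted observations. The JSON form round-trips
#' through [read_problems()].
#'
#' @param problems List of `problem_situation` objects (see
#'   [instantiate_problem()]).
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_problems <- function(problems, path, format = c("json", "csv")) {
  format <- match.arg(format)
  recs <- if (length(problems)) {
    do.call(rbind, lapply(problems, problem_record))
  } else {
    data.frame(id = character(), problem_type = character(),
               category = character(), subject_id = character(),
               start = character(), end = character(),
               observation_ids = character())
  }
  if (format == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(recs, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read problem records written by [write_problems()]
#'
#' @param path JSON or CSV path.
#' @param format `"json"` or `"csv"`.
#' @return Data frame with one row per problem.
#' @export
read_problems <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  wkg_stopifnot(file.exists(path), paste0("file not found: ", path))
  if (format == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(df)) df <- as.data.frame(df)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  df
}
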