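# Internal helpers shared across modules. All instants are minute-resolution
# POSIXct in a single implicit timezone (represented as UTC).

WKG_TZ <- "UTC"

wkg_parse_time <- function(x) {
  # ISO-8601 without timezone designator, "T" or " " separator.
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = WKG_TZ,
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (anyNA(out) && !anyNA(x)) {
    bad <- which(is.na(out))[1L]
    stop("malformed timestamp: '", x[bad], "'", call. = FALSE)
  }
  out
}

wkg_format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = WKG_TZ)

#' @keywords internal
wkg_date <- function(t) as.Date(t, tz = WKG_TZ)

# Minutes since epoch; the canonical minute index used by the window search.
wkg_minute_index <- function(t) as.integer(floor(as.numeric(t) / 60))

wkg_minute_to_time <- function(idx) {
  as.POSIXct(as.numeric(idx) * 60, origin = "1970-01-01", tz = WKG_TZ)
}

# round() in R is round-half-even; sleep efficiency uses ties away from zero
# so that integer thresholds behave predictably.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

wkg_stopifnot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
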