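# Small clock-time helpers shared across modules. All timestamps in the
# package are POSIXct in UTC on a 1-minute grid; "clock hours" are decimal
# hours of day in [0, 24).

#' Decimal clock hour of a timestamp
#'
#' @param time POSIXct vector.
#' @return Numeric vector of hours of day in `[0, 24)`.
#' @keywords internal
clock_hour <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Format a decimal clock hour as "HH:MM"
#'
#' @param h Numeric hours of day; values are wrapped modulo 24.
#' @return Character vector like `"21:05"`.
#' @export
#' @examples
#' format_clock(21.0833)
format_clock <- function(h) {
  h <- h %% 24
  mins <- round(h * 60)
  sprintf("%02d:%02d", (mins %/% 60) %% 24, mins %% 60)
}

#' Parse "HH:MM" clock strings to decimal hours
#'
#' @param x Character vector like `"18:30"`.
#' @return Numeric hours of day.
#' @export
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L) abort(paste0("malformed clock time: ", paste(p, collapse = ":")))
    as.numeric(p[1]) + as.numeric(p[2]) / 60
  }, numeric(1))
}

# TRUE when clock hour h falls in the (possibly midnight-crossing) interval
# [from, to], e.g. from = 18, to = 6.
clock_in_window <- function(h, from, to) {
  h <- h %% 24
  if (from <= to) h >= from & h <= to else h >= from | h <= to
}

# Minute-of-day index (0..1439) of a POSIXct vector.
minute_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 60L + lt$min
}

# Date of the noon that starts the noon-to-noon day containing `time`.
noon_date <- function(time) {
  as.Date(time, tz = "UTC") - (clock_hour(time) < 12)
}
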