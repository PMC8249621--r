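#' Construct an epoch series
#'
#' An epoch series is one participant-location actigraphy recording: a
#' gap-free 1-minute grid of nonnegative integer activity counts, with an
#' off-wrist flag per epoch and participant metadata carried as attributes.
#'
#' @param counts Nonnegative integer activity counts, one per minute.
#' @param start_time POSIXct (UTC) of the first epoch, minute resolution.
#' @param participant_id Character scalar.
#' @param gender `"woman"` or `"man"`.
#' @param location `"village"` or `"forest"`.
#' @param age Age in whole years, `>= 0`.
#' @param offwrist Optional logical vector, same length as `counts`; epochs
#'   flagged off-wrist are scored wake by [score_epochs()].
#' @return A tibble of class `epoch_series` with columns `timestamp`, `count`,
#'   `offwrist` and metadata attributes (`participant_id`, `gender`,
#'   `location`, `age`).
#' @export
#' @examples
#' s <- epoch_series(c(0, 5, 0), as.POSIXct("2017-07-15 12:00", tz = "UTC"),
#'                   "P01", "woman", "village", 30)
#' nrow(s)
epoch_series <- function(counts, start_time, participant_id, gender, location,
                         age, offwrist = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) abort("counts must be non-empty")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be nonnegative integers")
  }
  if (!gender %in% c("woman", "man")) abort("gender must be 'woman' or 'man'")
  if (!location %in% c("village", "forest")) abort("location must be 'village' or 'forest'")
  if (is.na(age) || age < 0) abort("age must be a nonnegative number of years")
  if (is.null(offwrist)) offwrist <- rep(FALSE, length(counts))
  if (length(offwrist) != length(counts)) {
    abort("offwrist mask must have the same length as counts")
  }
  start_time <- as.POSIXct(start_time, tz = "UTC")
  start_time <- trunc(start_time, units = "mins")
  out <- tibble(
    timestamp = start_time + 60 * (seq_along(counts) - 1L),
    count = as.integer(counts),
    offwrist = as.logical(offwrist)
  )
  structure(out,
    class = c("epoch_series", class(out)),
    participant_id = as.character(participant_id),
    gender = gender, location = location, age = as.integer(age)
  )
}

#' Participant metadata of an epoch series
#'
#' @param series An `epoch_series`.
#' @return One-row tibble with `participant_id`, `gender`, `location`, `age`.
#' @export
series_meta <- function(series) {
  tibble(
    participant_id = attr(series, "participant_id"),
    gender = attr(series, "gender"),
    location = attr(series, "location"),
    age = attr(series, "age")
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  m <- series_meta(x)
  cat(sprintf(
    "<epoch_series> %s (%s, %s, age %d): %d one-minute epochs from %s\n",
    m$participant_id, m$gender, m$location, m$age, nrow(x),
    format(x$timestamp[1], "%Y-%m-%d %H:%M", tz = "UTC")
  ))
  invisible(x)
}

#' Read an epoch CSV file
#'
#' The on-disk dialect is UTF-8, comma-separated, with a header row and
#' columns `timestamp` (ISO-8601, minute resolution), `count` and optionally
#' `offwrist`. Interior gaps up to `max_gap` minutes are filled with
#' zero-count, off-wrist-flagged epochs; longer gaps are an error, since
#' silently fabricating sleep is worse than a loud failure.
#'
#' @param path File path.
#' @param participant_id,gender,location,age Participant metadata (the dialect
#'   stores the series, not the descriptor).
#' @param max_gap Largest interior gap, in minutes, to impute (default 10).
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, participant_id, gender, location, age,
                           max_gap = 10) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    count = readr::col_double(),
    .default = readr::col_guess()
  ), progress = FALSE)
  if (!all(c("timestamp", "count") %in% names(raw))) {
    abort("epoch CSV must have 'timestamp' and 'count' columns")
  }
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- NULL
  for (f in fmts) {
    cand <- as.POSIXct(raw$timestamp, tz = "UTC", format = f)
    if (!anyNA(cand)) { ts <- cand; break }
    if (is.null(ts) || sum(is.na(cand)) < sum(is.na(ts))) ts <- cand
  }
  if (anyNA(ts)) {
    bad <- raw$timestamp[which(is.na(ts))[1]]
    abort(paste0("malformed timestamp: ", bad))
  }
  step <- as.numeric(diff(ts), units = "mins")
  if (any(step <= 0)) {
    abort(paste0("timestamps are not strictly increasing at row ",
                 which(step <= 0)[1] + 1L))
  }
  off <- if ("offwrist" %in% names(raw)) as.logical(raw$offwrist) else rep(FALSE, nrow(raw))
  gaps <- which(step > 1)
  if (length(gaps)) {
    too_big <- step[gaps] - 1 > max_gap
    if (any(too_big)) {
      i <- gaps[too_big][1]
      abort(sprintf("gap of %d min between %s and %s exceeds max_gap = %d",
                    as.integer(step[i] - 1),
                    format(ts[i], "%Y-%m-%d %H:%M", tz = "UTC"),
                    format(ts[i + 1], "%Y-%m-%d %H:%M", tz = "UTC"),
                    as.integer(max_gap)))
    }
    full <- seq(ts[1], ts[length(ts)], by = "1 min")
    idx <- match(full, ts)
    counts <- ifelse(is.na(idx), 0L, raw$count[idx])
    offw <- ifelse(is.na(idx), TRUE, off[idx])
    ts <- full
  } else {
    counts <- raw$count
    offw <- off
  }
  epoch_series(counts, ts[1], participant_id, gender, location, age,
               offwrist = offw)
}

#' Write an epoch CSV file
#'
#' Output is byte-stable for a fixed series: fixed column order
#' (`timestamp,count,offwrist`), ISO-8601 minute timestamps, LF line endings.
#'
#' @param series An [epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  out <- tibble(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:00", tz = "UTC"),
    count = series$count,
    offwrist = ifelse(series$offwrist, "TRUE", "FALSE")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble a cohort from epoch series and weather records
#'
#' @param series List of [epoch_series()] objects.
#' @param weather Tibble of nightly weather with columns `location`,
#'   `night_date`, `temp_2100`, `temp_0000`, `temp_0300`, `temp_0600`,
#'   `hum_2100`, `hum_0000`, `hum_0300`, `hum_0600`, `rainfall_mm`,
#'   `moon_phase`, `sunrise`, `sunset`. Temperature samples are taken at
#'   21:00, 00:00, 03:00 and 06:00; nightly means are their arithmetic mean.
#' @return A `sleep_cohort` list with elements `series` and `weather`.
#' @export
sleep_cohort <- function(series, weather) {
  stopifnot(is.list(series), length(series) >= 1L)
  ok <- vapply(series, inherits, logical(1), what = "epoch_series")
  if (!all(ok)) abort("all elements of series must be epoch_series objects")
  if (any(weather$moon_phase < 0 | weather$moon_phase > 1)) {
    abort("moon_phase must lie in [0, 1]")
  }
  hum <- as.matrix(weather[, c("hum_2100", "hum_0000", "hum_0300", "hum_0600")])
  if (any(hum < 0 | hum > 100)) abort("humidity samples must lie in [0, 100]")
  structure(list(series = series, weather = as_tibble(weather)),
            class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  meta <- list_rbind(map(x$series, series_meta))
  cat(sprintf("<sleep_cohort> %d series (%d village, %d forest), %d weather nights\n",
              nrow(meta), sum(meta$location == "village"),
              sum(meta$location == "forest"), nrow(x$weather)))
  invisible(x)
}

#' Night-level weather covariates for every participant-night
#'
#' Expands each series into its noon-to-noon nights and joins the location's
#' weather record, averaging the four nightly temperature and humidity
#' samples (21:00, 00:00, 03:00, 06:00) into `temperature` and `humidity`.
#'
#' @param cohort A [sleep_cohort()].
#' @return Tibble with one row per (participant, location, night_date) and
#'   columns `temperature` (deg C), `humidity` (%RH), `rainfall_mm`,
#'   `moon_phase`.
#' @export
attach_weather <- function(cohort) {
  nights <- list_rbind(map(cohort$series, function(s) {
    # a night is the noon-to-noon day that starts it, dated by its first noon
    nd <- sort(unique(noon_date(s$timestamp)))
    dplyr::cross_join(series_meta(s), tibble(night_date = nd))
  }))
  w <- cohort$weather %>%
    mutate(
      temperature = (.data$temp_2100 + .data$temp_0000 + .data$temp_0300 + .data$temp_0600) / 4,
      humidity = (.data$hum_2100 + .data$hum_0000 + .data$hum_0300 + .data$hum_0600) / 4
    ) %>%
    select("location", "night_date", "temperature", "humidity",
           "rainfall_mm", "moon_phase")
  out <- left_join(nights, w, by = c("location", "night_date"))
  if (anyNA(out$temperature)) {
    miss <- out %>% filter(is.na(.data$temperature)) %>% slice(1)
    abort(sprintf("no weather record for %s night %s",
                  miss$location, format(miss$night_date)))
  }
  out
}
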