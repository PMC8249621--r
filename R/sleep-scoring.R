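#' Scoring configuration
#'
#' Parameters of the weighted moving-window sleep/wake classifier and of the
#' rest-period detector. The classifier is of the Cole--Kripke family: a
#' minute is scored sleep when the weighted sum of activity counts in a
#' centred window falls at or below a threshold. All weights and the
#' threshold are exposed so users can calibrate against their device.
#'
#' @param window_weights Nonnegative weights over a centred window; odd
#'   length. Default is a 7-minute window peaked at the centre.
#' @param threshold Weighted-count cutoff (same arbitrary units as the device
#'   counts); must be `> 0`.
#' @param rest_block_min Minutes of consecutive sleep-scored epochs required
#'   to open or close a rest period (default 10).
#' @param night_window Clock interval (decimal hours, may cross midnight)
#'   within which the main sleep bout must start; default 18:00--06:00.
#' @param nap_min_duration Minimum nap length in minutes (default 20).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(window_weights = c(0.04, 0.08, 0.2, 1, 0.2, 0.08, 0.04),
                           threshold = 100,
                           rest_block_min = 10,
                           night_window = c(18, 6),
                           nap_min_duration = 20) {
  if (length(window_weights) %% 2 == 0) abort("window_weights must have odd length")
  if (any(window_weights < 0)) abort("window_weights must be nonnegative")
  if (threshold <= 0) abort("threshold must be positive")
  if (rest_block_min < 1) abort("rest_block_min must be >= 1")
  structure(list(
    window_weights = window_weights, threshold = threshold,
    rest_block_min = as.integer(rest_block_min),
    night_window = night_window,
    nap_min_duration = as.integer(nap_min_duration)
  ), class = "scoring_config")
}

#' Score each epoch as sleep or wake
#'
#' Minute `i` is scored sleep iff the weighted sum of counts in the centred
#' window is `<= threshold`. Series edges are padded by replicating the first
#' and last count. Off-wrist minutes are always scored wake.
#'
#' @param series An [epoch_series()].
#' @param config A [scoring_config()].
#' @return The series tibble with an added `state` column (`"sleep"`/`"wake"`).
#' @export
#' @examples
#' s <- epoch_series(rep(0, 30), as.POSIXct("2017-07-15 12:00", tz = "UTC"),
#'                   "P01", "woman", "village", 30)
#' table(score_epochs(s, scoring_config())$state)
score_epochs <- function(series, config = scoring_config()) {
  w <- config$window_weights
  half <- (length(w) - 1L) %/% 2L
  n <- nrow(series)
  if (length(w) > n) abort("scoring window is longer than the series")
  xp <- c(rep(series$count[1], half), series$count, rep(series$count[n], half))
  s <- numeric(n)
  for (j in seq_along(w)) s <- s + w[j] * xp[j:(j + n - 1L)]
  state <- ifelse(s <= config$threshold, .SLEEP, .WAKE)
  state[series$offwrist] <- .WAKE
  out <- series
  out$state <- state
  out
}

# maximal runs of a logical vector; tibble of start index, length
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  tibble(start = ends - r$lengths + 1L, length = r$lengths, value = r$values) %>%
    filter(.data$value) %>% select("start", "length")
}

#' Locate the main nightly sleep period in each noon-to-noon day
#'
#' Within each noon-to-noon day, rest onset is the start of the first run of
#' at least `rest_block_min` consecutive sleep-scored minutes whose start
#' lies inside `night_window` (the main bout must start at night); rest end
#' is the end of the last rest run of at least `rest_block_min` minutes
#' before the following noon. Time in bed (TIB) is the onset-to-end span.
#' Days without a qualifying run, or with under 18 h of data, are dropped.
#'
#' @param scored Output of [score_epochs()].
#' @param config A [scoring_config()].
#' @return Tibble with one row per scored night: `night_date`, `onset`,
#'   `end` (POSIXct, `end` exclusive), `tib_h`.
#' @export
detect_main_sleep_period <- function(scored, config = scoring_config()) {
  nd <- noon_date(scored$timestamp)
  out <- map(split(seq_len(nrow(scored)), nd), function(idx) {
    if (length(idx) < 18 * 60) return(NULL)
    day <- scored[idx, ]
    runs <- runs_of(day$state == .SLEEP)
    runs <- runs[runs$length >= config$rest_block_min, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    h <- clock_hour(day$timestamp[runs$start])
    starters <- which(clock_in_window(h, config$night_window[1], config$night_window[2]))
    if (!length(starters)) return(NULL)
    onset <- day$timestamp[runs$start[starters[1]]]
    # end: last qualifying rest run at or after onset, before the next noon
    last <- nrow(runs)
    end <- day$timestamp[runs$start[last] + runs$length[last] - 1L] + 60
    tibble(night_date = noon_date(onset), onset = onset, end = end,
           tib_h = as.numeric(difftime(end, onset, units = "hours")))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    message(sprintf("%d day(s) without a qualifying main sleep period were excluded", dropped))
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

#' Detect daytime naps
#'
#' Naps are maximal sleep-scored runs of at least `nap_min_duration` minutes
#' lying outside the main sleep period, within the same noon-to-noon day.
#'
#' @param scored Output of [score_epochs()].
#' @param main Output of [detect_main_sleep_period()].
#' @param config A [scoring_config()].
#' @return Tibble with columns `night_date`, `start`, `end`, `minutes`.
#' @export
detect_naps <- function(scored, main, config = scoring_config()) {
  nd <- noon_date(scored$timestamp)
  out <- map(seq_len(nrow(main)), function(i) {
    day <- scored[nd == main$night_date[i], ]
    outside <- day$timestamp < main$onset[i] | day$timestamp >= main$end[i]
    runs <- runs_of(day$state == .SLEEP & outside)
    runs <- runs[runs$length >= config$nap_min_duration, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    tibble(
      night_date = main$night_date[i],
      start = day$timestamp[runs$start],
      end = day$timestamp[runs$start + runs$length - 1L] + 60,
      minutes = runs$length
    )
  })
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(night_date = as.Date(character()), start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"), minutes = integer()))
  }
  res
}

#' Sleep fragmentation index
#'
#' The index is the sum of two percentages over the main sleep period:
#' mobile (wake-scored) minutes as a percentage of inferred sleep time
#' (sleep-scored minutes), plus immobile bouts of length one minute or less
#' as a percentage of the total number of immobile bouts. Mobile/immobile
#' bouts are maximal runs of wake-/sleep-scored minutes.
#'
#' @param states Character vector of `"sleep"`/`"wake"` states within the
#'   main sleep period.
#' @return Nonnegative fragmentation score.
#' @export
#' @examples
#' fragmentation_index(rep("sleep", 60))  # 0: one long immobile bout
fragmentation_index <- function(states) {
  if (!length(states)) abort("empty sleep period")
  sleep <- states == .SLEEP
  n_sleep <- sum(sleep)
  if (n_sleep == 0) abort("no immobile bouts: fragmentation index undefined")
  r <- rle(sleep)
  imm <- r$lengths[r$values]
  100 * sum(!sleep) / n_sleep + 100 * sum(imm <= 1) / length(imm)
}

#' Per-night sleep quotas
#'
#' Scores a series, locates each night's main sleep period and naps, and
#' computes the nightly quotas: TST (sleep-scored time in the main period),
#' WASO (wake-scored time inside the main period), sleep efficiency
#' (100 * TST / TIB), fragmentation index, nap time and 24-h total sleep time
#' (TTST = TST + nap sleep).
#'
#' @param series An [epoch_series()].
#' @param config A [scoring_config()].
#' @return Tibble with one row per scored night: participant metadata,
#'   `night_date`, `onset`, `end`, `sleep_onset_h`, `sleep_end_h`, `tib_h`,
#'   `tst_h`, `waso_h`, `efficiency_pct`, `fragmentation`, `nap_h`, `ttst_h`.
#' @export
sleep_quotas <- function(series, config = scoring_config()) {
  scored <- score_epochs(series, config)
  main <- detect_main_sleep_period(scored, config)
  if (is.null(main) || nrow(main) == 0) {
    return(tibble())
  }
  naps <- detect_naps(scored, main, config)
  quotas <- list_rbind(map(seq_len(nrow(main)), function(i) {
    inside <- scored$timestamp >= main$onset[i] & scored$timestamp < main$end[i]
    st <- scored$state[inside]
    tst_h <- sum(st == .SLEEP) / 60
    waso_h <- sum(st == .WAKE) / 60
    nap_min <- sum(naps$minutes[naps$night_date == main$night_date[i]])
    tibble(
      night_date = main$night_date[i],
      onset = main$onset[i], end = main$end[i],
      sleep_onset_h = clock_hour(main$onset[i]),
      sleep_end_h = clock_hour(main$end[i]),
      tib_h = main$tib_h[i], tst_h = tst_h, waso_h = waso_h,
      efficiency_pct = 100 * tst_h / main$tib_h[i],
      fragmentation = fragmentation_index(st),
      nap_h = nap_min / 60,
      ttst_h = tst_h + nap_min / 60
    )
  }))
  dplyr::bind_cols(
    series_meta(series)[rep(1, nrow(quotas)), ],
    quotas
  )
}

#' Nightly quota and weather table for a cohort
#'
#' Runs [sleep_quotas()] on every series in a cohort and joins the nightly
#' weather covariates (mean of the four night samples for temperature and
#' humidity, plus rainfall and moon phase). This is the night-level table the
#' comparison and mixed-model stages consume.
#'
#' @param cohort A [sleep_cohort()].
#' @param config A [scoring_config()].
#' @return Tibble with one row per scored participant-night.
#' @export
cohort_quotas <- function(cohort, config = scoring_config()) {
  quotas <- list_rbind(map(cohort$series, sleep_quotas, config = config))
  w <- attach_weather(cohort) %>%
    select("participant_id", "location", "night_date",
           "temperature", "humidity", "rainfall_mm", "moon_phase")
  left_join(quotas, w, by = c("participant_id", "location", "night_date"))
}
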