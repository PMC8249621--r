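#' Hourly mean counts over whole recording days
#'
#' Truncates the series to whole noon-to-noon 24-h days and averages counts
#' within each clock hour. Non-parametric circadian rhythm analysis requires
#' at least seven complete consecutive days.
#'
#' @param series An [epoch_series()].
#' @param min_days Minimum number of complete days (default 7).
#' @return Numeric vector of `24 * D` hourly means.
#' @export
hourly_bin <- function(series, min_days = 7) {
  d <- floor(nrow(series) / 1440)
  if (d < min_days) {
    abort(sprintf("NPCRA needs >= %d complete days; series has %d", min_days, d))
  }
  x <- series$count[seq_len(d * 1440)]
  colMeans(matrix(x, nrow = 60))
}

#' Interdaily stability (IS)
#'
#' Day-to-day similarity of the 24-h activity profile: the variance of the
#' average day profile divided by the total variance,
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`.
#' 0 means no rhythm; 1 is perfect day-to-day stability.
#'
#' @param hourly Hourly (or other equal-bin) mean-count sequence whose
#'   length is a multiple of `period_bins`.
#' @param period_bins Bins per period (default 24 hourly bins per day).
#' @return IS in `[0, 1]`.
#' @export
interdaily_stability <- function(hourly, period_bins = 24) {
  n <- length(hourly)
  if (n %% period_bins != 0) abort("length of hourly must be a multiple of period_bins")
  tot <- sum((hourly - mean(hourly))^2)
  if (tot == 0) abort("constant sequence: IS undefined (0/0)")
  prof <- rowMeans(matrix(hourly, nrow = period_bins))
  n * sum((prof - mean(hourly))^2) / (period_bins * tot)
}

#' Intradaily variability (IV)
#'
#' Hour-to-hour fragmentation of the rest-activity rhythm: the mean squared
#' first difference divided by the overall variance,
#' `IV = (N * sum_i (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i - xbar)^2)`.
#' Values near 0 indicate a smooth rhythm; white noise gives about 2.
#'
#' @param hourly Equal-bin mean-count sequence, length at least 2.
#' @return Nonnegative IV.
#' @export
intradaily_variability <- function(hourly) {
  n <- length(hourly)
  if (n < 2) abort("need at least 2 bins")
  tot <- sum((hourly - mean(hourly))^2)
  if (tot == 0) abort("constant sequence: IV undefined (0/0)")
  n * sum(diff(hourly)^2) / ((n - 1) * tot)
}

#' Average 24-h minute profile
#'
#' Minute-of-day means across whole noon-to-noon days, indexed by clock
#' minute 0 (00:00) to 1439 (23:59).
#'
#' @inheritParams hourly_bin
#' @return Numeric vector of length 1440.
#' @export
average_day_profile <- function(series, min_days = 7) {
  d <- floor(nrow(series) / 1440)
  if (d < min_days) {
    abort(sprintf("NPCRA needs >= %d complete days; series has %d", min_days, d))
  }
  idx <- seq_len(d * 1440)
  mod <- minute_of_day(series$timestamp[idx])
  as.numeric(rowsum(series$count[idx], mod)) / d
}

#' Most-active 10 h and least-active 5 h of the average day
#'
#' Scans all 1440 circular start minutes of the average day profile for the
#' 10-h window with the highest mean (M10) and the 5-h window with the
#' lowest mean (L5). Ties are broken by the earliest clock time after 00:00.
#'
#' @param profile 1440-point average day profile from [average_day_profile()].
#' @return Tibble with `m10`, `m10_onset_h`, `l5`, `l5_onset_h` (onsets as
#'   decimal clock hours).
#' @export
m10_l5 <- function(profile) {
  if (length(profile) != 1440) abort("profile must have 1440 points")
  window_means <- function(width) {
    cs <- cumsum(c(0, rep(profile, 2)))
    (cs[(1:1440) + width] - cs[1:1440]) / width
  }
  m <- window_means(600)
  l <- window_means(300)
  i_m <- which.max(m) # which.max/min take the first index: earliest clock time
  i_l <- which.min(l)
  tibble(
    m10 = m[i_m], m10_onset_h = (i_m - 1) / 60,
    l5 = l[i_l], l5_onset_h = (i_l - 1) / 60
  )
}

#' Relative amplitude (RA)
#'
#' `RA = (M10 - L5) / (M10 + L5)`, a normalized rhythm strength in `[0, 1]`.
#'
#' @param m10,l5 Mean counts over the most active 10 h / least active 5 h.
#' @return RA in `[0, 1]`.
#' @export
relative_amplitude <- function(m10, l5) {
  if (m10 < l5 || l5 < 0) abort("need m10 >= l5 >= 0")
  if (m10 + l5 == 0) abort("m10 = l5 = 0: relative amplitude undefined")
  (m10 - l5) / (m10 + l5)
}

#' Non-parametric circadian rhythm metrics for one series
#'
#' Computes IS, IV (on hourly bins by default, or at epoch resolution),
#' M10, L5, their onsets, and relative amplitude for a recording of at
#' least `min_days` complete noon-to-noon days.
#'
#' @param series An [epoch_series()].
#' @param min_days Minimum complete days (default 7).
#' @param bin `"hour"` (classical hourly bins, the default) or `"epoch"`
#'   (IS/IV on the raw 1-min grid).
#' @return One-row tibble with participant metadata, `n_days`, `is`, `iv`,
#'   `m10`, `m10_onset_h`, `l5`, `l5_onset_h`, `ra`.
#' @export
npcra_metrics <- function(series, min_days = 7, bin = c("hour", "epoch")) {
  bin <- match.arg(bin)
  d <- floor(nrow(series) / 1440)
  x <- if (bin == "hour") hourly_bin(series, min_days) else {
    if (d < min_days) abort(sprintf("NPCRA needs >= %d complete days", min_days))
    series$count[seq_len(d * 1440)]
  }
  p <- if (bin == "hour") 24 else 1440
  prof <- average_day_profile(series, min_days)
  ml <- m10_l5(prof)
  dplyr::bind_cols(
    series_meta(series),
    tibble(
      n_days = d,
      is = interdaily_stability(x, p),
      iv = intradaily_variability(x)
    ),
    ml,
    tibble(ra = relative_amplitude(ml$m10, ml$l5))
  )
}

#' NPCRA metrics for every eligible series in a cohort
#'
#' Series with fewer than `min_days` complete days are skipped with a
#' message, mirroring the seven-consecutive-day inclusion rule.
#'
#' @param cohort A [sleep_cohort()].
#' @inheritParams npcra_metrics
#' @return Tibble, one row per eligible series.
#' @export
cohort_npcra <- function(cohort, min_days = 7, bin = "hour") {
  keep_rows <- list()
  skipped <- 0L
  for (s in cohort$series) {
    if (floor(nrow(s) / 1440) < min_days) { skipped <- skipped + 1L; next }
    keep_rows[[length(keep_rows) + 1L]] <- npcra_metrics(s, min_days, bin)
  }
  if (skipped > 0) {
    message(sprintf("%d series with < %d complete days excluded from NPCRA", skipped, min_days))
  }
  list_rbind(keep_rows)
}
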