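#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the design of a two-location (village/forest) field
#' actigraphy study: 39 village participants (20 men) and 23 forest
#' participants (10 men), 11 of whom take part in both locations (7 men),
#' 3--8 nights per participant summing to 226 village and 136 forest nights,
#' gender-by-location structure in sleep timing and duration (forest women
#' sleep longer; forest men's onset and end are far more variable), midday
#' naps, nocturnal arousals, bursty overdispersed daytime activity counts
#' around a smooth diurnal harmonic template, and nightly weather
#' (temperature means in the 21--25 degC band, mean humidity 84%, zero-
#' inflated rainfall, a 29.5-day moon illumination cycle).
#'
#' @param n_village_women,n_village_men,n_forest_women,n_forest_men
#'   Participants per gender-by-location cell.
#' @param n_shared_women,n_shared_men Subjects appearing in both locations.
#' @param nights_range Inclusive night range per participant.
#' @param nights_total Named total nights per location (`NULL` to skip the
#'   per-location total and use raw uniform draws).
#' @param cells Per-cell sleep parameters: mean/SD of onset and end clock
#'   times, mean target TST, mean nap duration, and an activity template
#'   multiplier. Defaults follow the gender-by-location contrasts of the
#'   emulated study design.
#' @param tst_sd_h Night-to-night SD of total sleep time (hours).
#' @param nap_probability Daily nap probability; naps fall in `nap_window`.
#' @param nap_window Clock window (hours) in which naps start.
#' @param day_level Peak scale of the diurnal count template (counts/min).
#' @param template_harmonics Fourier coefficients of the 24-h template shape
#'   (`a0`, then amplitude/phase-hour pairs).
#' @param count_dispersion Negative-binomial size for daytime counts; `Inf`
#'   gives deterministic counts equal to the template (useful for
#'   noise-free constructions).
#' @param sleep_count_rate Poisson rate of counts during sleep minutes
#'   (0 gives exactly zero counts).
#' @param wake_bout_mu,wake_edge_mu Mean counts in the interior / at the
#'   edges of nocturnal wake bouts.
#' @param weather Weather parameters (see defaults).
#' @param seed Integer seed; [generate_cohort()] is deterministic for a
#'   fixed config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_village_women = 19, n_village_men = 20,
                          n_forest_women = 13, n_forest_men = 10,
                          n_shared_women = 4, n_shared_men = 7,
                          nights_range = c(3, 8),
                          nights_total = c(village = 226, forest = 136),
                          cells = NULL,
                          tst_sd_h = 1.3,
                          nap_probability = 0.7,
                          nap_window = c(12, 15),
                          day_level = 2500,
                          template_harmonics = list(a0 = 0.55, a1 = 0.45,
                                                    peak_h = 13, a2 = 0.05,
                                                    peak2_h = 8),
                          count_dispersion = 4,
                          sleep_count_rate = 1,
                          wake_bout_mu = 500, wake_edge_mu = 150,
                          weather = list(temp_mean = 23, temp_night_sd = 1,
                                         sample_offsets = c(1.0, 0, -0.7, -1.2),
                                         sample_sd = 0.5,
                                         hum_mean = 84, hum_sd = 4,
                                         rain_prob = 0.45, rain_mean_mm = 8,
                                         moon_period = 29.5, moon_phase0 = 0.25),
                          seed = 1L) {
  if (is.null(cells)) {
    cells <- tibble(
      gender   = c("woman", "man", "woman", "man"),
      location = c("village", "village", "forest", "forest"),
      onset_mean_h = c(20 + 57 / 60, 21 + 18 / 60, 20 + 47 / 60, 21 + 17 / 60),
      onset_sd_min = c(85, 91, 84, 117),
      end_mean_h   = c(5 + 32 / 60, 5 + 35 / 60, 5 + 43 / 60, 6 + 9 / 60),
      end_sd_min   = c(28, 50, 29, 180),
      tst_mean_h   = c(5.91, 5.77, 6.53, 5.65),
      nap_mean_h   = c(0.69, 1.28, 0.90, 1.21),
      template_mult = c(1.25, 0.85, 1.35, 0.95)
    )
  }
  counts <- c(n_village_women, n_village_men, n_forest_women, n_forest_men)
  if (any(counts < 0)) abort("participant counts must be nonnegative")
  if (sum(counts) == 0) abort("empty design: no participants in any cell")
  if (nights_range[1] < 1 || nights_range[2] > 28 || nights_range[1] > nights_range[2]) {
    abort("nights_range must be an increasing interval within [1, 28]")
  }
  if (nap_probability < 0 || nap_probability > 1) abort("nap_probability must be in [0, 1]")
  if (tst_sd_h < 0 || any(cells$onset_sd_min < 0) || any(cells$end_sd_min < 0)) {
    abort("standard deviations must be nonnegative")
  }
  structure(list(
    n_village_women = n_village_women, n_village_men = n_village_men,
    n_forest_women = n_forest_women, n_forest_men = n_forest_men,
    n_shared_women = n_shared_women, n_shared_men = n_shared_men,
    nights_range = nights_range, nights_total = nights_total,
    cells = cells, tst_sd_h = tst_sd_h,
    nap_probability = nap_probability, nap_window = nap_window,
    day_level = day_level, template_harmonics = template_harmonics,
    count_dispersion = count_dispersion, sleep_count_rate = sleep_count_rate,
    wake_bout_mu = wake_bout_mu, wake_edge_mu = wake_edge_mu,
    weather = weather, seed = as.integer(seed)
  ), class = "cohort_config")
}

# diurnal template: expected counts/min at clock hour h
template_mu <- function(h, config, mult = 1) {
  th <- config$template_harmonics
  shape <- th$a0 + th$a1 * cos(2 * pi * (h - th$peak_h) / 24) +
    th$a2 * cos(4 * pi * (h - th$peak2_h) / 24)
  pmax(0.02, shape) * config$day_level * mult
}

# draw counts with the configured overdispersion; Inf = deterministic
draw_counts <- function(mu, config) {
  if (is.infinite(config$count_dispersion)) return(as.integer(round(mu)))
  rnbinom(length(mu), size = config$count_dispersion, mu = mu)
}

# split `total` into `k` parts each >= minimum, multinomially
split_total <- function(total, k, minimum) {
  extra <- total - k * minimum
  stopifnot(extra >= 0)
  if (k == 1) return(total)
  as.integer(minimum + rmultinom(1, extra, rep(1, k))[, 1])
}

#' Generate one participant's epoch series
#'
#' Builds an `n_nights`-day recording on a noon-to-noon grid: bursty
#' overdispersed daytime counts around the diurnal template (with the
#' cell's multiplier), a nightly sleep window from a drawn onset to a drawn
#' end with near-zero counts, interior wake bouts whose total equals the
#' window minus the drawn target TST, and optional midday naps. Uses the
#' current RNG state; wrap in [withr::with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param config A [cohort_config()].
#' @param gender,location Cell labels.
#' @param n_nights Number of noon-to-noon days (`>= 1`).
#' @param participant_id Identifier.
#' @param age Age in years.
#' @param start_date Date of the first noon.
#' @return An [epoch_series()] with a `truth` attribute: tibble of the
#'   generated per-night onset/end clock hours, window span, target TST,
#'   WASO and nap hours.
#' @export
generate_participant_series <- function(config, gender, location, n_nights,
                                        participant_id = "P1", age = 36,
                                        start_date = as.Date("2017-07-15")) {
  if (n_nights < 1) abort("n_nights must be >= 1")
  cell <- config$cells %>% filter(.data$gender == !!gender, .data$location == !!location)
  if (nrow(cell) != 1) abort("no cell parameters for this gender/location")
  total_min <- n_nights * 1440L
  start <- as.POSIXct(paste(start_date, "12:00:00"), tz = "UTC")
  clock <- ((12 * 60 + seq_len(total_min) - 1) %% 1440) / 60
  mu <- template_mu(clock, config, cell$template_mult)
  counts <- draw_counts(mu, config)

  truth <- list()
  for (d in seq_len(n_nights)) {
    day0 <- (d - 1L) * 1440L # index offset of this day's noon
    # onset/end in hours since this day's noon (12:00 -> 0)
    draw_window <- function() {
      onset <- rnorm(1, cell$onset_mean_h, cell$onset_sd_min / 60)
      end <- rnorm(1, cell$end_mean_h + 24, cell$end_sd_min / 60)
      c(onset, end)
    }
    tries <- 0
    repeat {
      w <- draw_window()
      onset_h <- min(max(w[1], 18.2), 28.5)
      end_h <- min(w[2], 35.4)
      tst_h <- rnorm(1, cell$tst_mean_h, config$tst_sd_h)
      tst_h <- max(tst_h, 0.75)
      end_h <- max(end_h, onset_h + tst_h)
      if (end_h > 35.4) { # cannot fit: shorten the night
        end_h <- 35.4
        tst_h <- end_h - onset_h
      }
      if (tst_h > 0.5) break
      tries <- tries + 1
      if (tries > 20) abort("could not draw a valid sleep window after 20 retries")
    }
    on_i <- day0 + round((onset_h - 12) * 60) + 1L
    en_i <- day0 + round((end_h - 12) * 60) # last sleep-window minute
    window_min <- en_i - on_i + 1L
    tst_min <- min(round(tst_h * 60), window_min)
    waso_min <- window_min - tst_min

    # partition the window: k wake bouts between k+1 sleep segments (each
    # segment >= 10 min so rest-period edges are detected at the window)
    k <- if (waso_min < 2) 0L else max(1L, round(waso_min / 15))
    k <- min(k, max(0L, tst_min %/% 12L - 1L), if (waso_min > 0) waso_min else 0L)
    minute_counts <- integer(window_min)
    if (k == 0L) {
      waso_min <- 0L
      tst_min <- window_min
      minute_counts[] <- rpois(window_min, config$sleep_count_rate)
    } else {
      sleep_seg <- split_total(tst_min, k + 1L, 10L)
      wake_seg <- split_total(waso_min, k, 1L)
      pos <- 0L
      for (j in seq_len(k + 1L)) {
        sl <- sleep_seg[j]
        minute_counts[pos + seq_len(sl)] <- rpois(sl, config$sleep_count_rate)
        pos <- pos + sl
        if (j <= k) {
          # arousal bouts ramp up and down: outer minutes low, next minutes
          # medium, interior fully mobile
          wl <- wake_seg[j]
          bout <- rnbinom(wl, size = 6, mu = config$wake_bout_mu)
          if (wl <= 3) {
            bout <- rpois(wl, 1.7 * config$wake_edge_mu)
          } else {
            bout[c(1, wl)] <- rpois(2, config$wake_edge_mu)
            bout[c(2, wl - 1)] <- rpois(2, 2 * config$wake_edge_mu)
          }
          minute_counts[pos + seq_len(wl)] <- bout
          pos <- pos + wl
        }
      }
    }
    counts[on_i:en_i] <- minute_counts

    # optional midday nap (low-count block) inside the nap window
    nap_h <- 0
    if (config$nap_probability > 0 && runif(1) < config$nap_probability) {
      nap_len <- round(60 * min(max(
        rnorm(1, cell$nap_mean_h / config$nap_probability, 0.3), 1 / 3), 3))
      nap_start_h <- runif(1, config$nap_window[1], config$nap_window[2])
      ns <- day0 + round((nap_start_h - 12) * 60) + 1L
      ne <- min(ns + nap_len - 1L, day0 + round((config$nap_window[2] + 0.75 - 12) * 60))
      counts[ns:ne] <- rpois(ne - ns + 1L, config$sleep_count_rate)
      nap_h <- (ne - ns + 1L) / 60
    }
    truth[[d]] <- tibble(
      night_date = start_date + (d - 1L),
      onset_h = onset_h %% 24, end_h = end_h %% 24,
      window_h = window_min / 60, tst_h = tst_min / 60,
      waso_h = waso_min / 60, nap_h = nap_h
    )
  }
  s <- epoch_series(counts, start, participant_id, gender, location, age)
  attr(s, "truth") <- list_rbind(truth)
  s
}

#' Generate nightly weather records
#'
#' Nightly temperature and humidity sampled at 21:00, 00:00, 03:00 and
#' 06:00 around a per-night base level, zero-inflated rainfall, and a
#' sinusoidal 29.5-day moon illumination cycle. Uses the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param n_nights Number of nights.
#' @param location Location label.
#' @param start_date Date of the first night.
#' @return Tibble of weather records matching [sleep_cohort()]'s schema.
#' @export
generate_weather <- function(config, n_nights, location = "village",
                             start_date = as.Date("2017-07-15")) {
  wp <- config$weather
  dates <- start_date + seq_len(n_nights) - 1L
  day_no <- as.numeric(dates - as.Date("2017-01-01"))
  base_t <- rnorm(n_nights, wp$temp_mean, wp$temp_night_sd)
  base_h <- pmin(100, pmax(0, rnorm(n_nights, wp$hum_mean, wp$hum_sd)))
  samp <- function(base, offs) pmax(0, base + offs + rnorm(length(base), 0, wp$sample_sd))
  hsamp <- function(base, offs) pmin(100, pmax(0, base + offs + rnorm(length(base), 0, wp$sample_sd)))
  tibble(
    location = location, night_date = dates,
    temp_2100 = samp(base_t, wp$sample_offsets[1]),
    temp_0000 = samp(base_t, wp$sample_offsets[2]),
    temp_0300 = samp(base_t, wp$sample_offsets[3]),
    temp_0600 = samp(base_t, wp$sample_offsets[4]),
    hum_2100 = hsamp(base_h, 0), hum_0000 = hsamp(base_h, 1),
    hum_0300 = hsamp(base_h, 1.5), hum_0600 = hsamp(base_h, 1),
    rainfall_mm = rbinom(n_nights, 1, wp$rain_prob) *
      rgamma(n_nights, shape = 1.2, scale = wp$rain_mean_mm / 1.2),
    moon_phase = moon_illumination(day_no, wp$moon_period, wp$moon_phase0),
    sunrise = "05:47", sunset = "17:58"
  )
}

#' Moon illumination fraction on a sinusoidal cycle
#'
#' @param day Day number (any numeric origin).
#' @param period Cycle length in days (default 29.5).
#' @param phase0 Cycle phase (fraction) at day 0.
#' @return Illuminated fraction in `[0, 1]`.
#' @export
moon_illumination <- function(day, period = 29.5, phase0 = 0) {
  (1 - cos(2 * pi * (day / period + phase0))) / 2
}

# draw per-participant night counts in [range] summing to `total` (when
# given), by unit adjustments of uniform draws
allocate_nights <- function(n, range, total = NULL) {
  vals <- seq(range[1], range[2])
  x <- vals[sample.int(length(vals), n, replace = TRUE)]
  if (is.null(total)) return(x)
  if (total < n * range[1] || total > n * range[2]) {
    abort("nights_total is not achievable within nights_range")
  }
  while (sum(x) != total) {
    d <- sign(total - sum(x))
    i <- sample(which(if (d > 0) x < range[2] else x > range[1]), 1)
    x[i] <- x[i] + d
  }
  x
}

#' Generate a synthetic cohort
#'
#' Deterministically (for a fixed config, including its seed) builds the
#' full study cohort: a subject roster with the configured overlap between
#' locations, per-participant night counts, epoch series from
#' [generate_participant_series()] and weather from [generate_weather()].
#'
#' @param config A [cohort_config()].
#' @return A [sleep_cohort()]; each series carries its generation `truth`
#'   attribute, and the cohort carries a `roster` attribute.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(
#'   n_village_women = 2, n_village_men = 2, n_forest_women = 2,
#'   n_forest_men = 2, n_shared_women = 1, n_shared_men = 1,
#'   nights_total = NULL, seed = 7))
#' coh
#' }
generate_cohort <- function(config = cohort_config()) {
  withr::with_seed(config$seed, {
    roster <- build_roster(config)
    start <- list(village = as.Date("2017-07-15"), forest = as.Date("2018-07-15"))
    series <- list()
    for (loc in c("village", "forest")) {
      part <- roster %>% filter(.data$location == loc)
      if (!nrow(part)) next
      tot <- if (is.null(config$nights_total)) NULL else config$nights_total[[loc]]
      nights <- allocate_nights(nrow(part), config$nights_range, tot)
      offsets <- sample(0:3, nrow(part), replace = TRUE)
      for (i in seq_len(nrow(part))) {
        series[[length(series) + 1L]] <- generate_participant_series(
          config, part$gender[i], loc, nights[i],
          participant_id = part$participant_id[i], age = part$age[i],
          start_date = start[[loc]] + offsets[i]
        )
      }
    }
    weather <- bind_rows(
      generate_weather(config, config$nights_range[2] + 5, "village", start$village),
      generate_weather(config, config$nights_range[2] + 5, "forest", start$forest)
    )
    coh <- sleep_cohort(series, weather)
    attr(coh, "roster") <- roster
    coh
  })
}

# subject roster with the configured between-location overlap
build_roster <- function(config) {
  n_shared <- c(woman = config$n_shared_women, man = config$n_shared_men)
  cells <- list(
    woman = c(village = config$n_village_women, forest = config$n_forest_women),
    man = c(village = config$n_village_men, forest = config$n_forest_men)
  )
  rows <- list()
  id_no <- 0L
  for (g in c("woman", "man")) {
    nv <- cells[[g]]["village"]; nf <- cells[[g]]["forest"]
    ns <- min(n_shared[[g]], nv, nf)
    n_unique <- nv + nf - ns
    ids <- sprintf("S%02d", id_no + seq_len(n_unique))
    id_no <- id_no + n_unique
    ages <- pmin(72L, pmax(17L, as.integer(round(rnorm(n_unique, 36, 13.75)))))
    vill_ids <- ids[seq_len(nv)]
    forest_ids <- c(ids[seq_len(ns)], ids[nv + seq_len(nf - ns)])
    rows[[g]] <- bind_rows(
      tibble(participant_id = vill_ids, gender = g, location = "village",
             age = ages[match(vill_ids, ids)]),
      tibble(participant_id = forest_ids, gender = g, location = "forest",
             age = ages[match(forest_ids, ids)])
    )
  }
  list_rbind(rows)
}
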