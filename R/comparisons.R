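# clock-valued quota columns, averaged and tested circularly
.CLOCK_VARS <- c("sleep_onset_h", "sleep_end_h", "m10_onset_h", "l5_onset_h")

#' Circular mean and dispersion of clock times
#'
#' Clock times are mapped to angles on a 24-h circle; the mean direction is
#' mapped back to a clock time and the circular standard deviation is
#' expressed in minutes. Needed because sleep onsets like 23:30 and 00:30
#' must average to 00:00, not 12:00.
#'
#' @param hours Clock times as decimal hours in `[0, 24)`.
#' @return One-row tibble with `mean_h`, `dispersion_min`, `n`.
#' @export
#' @examples
#' circular_time_stats(c(23, 1))$mean_h  # 0, i.e. midnight
circular_time_stats <- function(hours) {
  if (!length(hours)) abort("need at least one time")
  ang <- hours / 24 * 2 * pi
  s <- mean(sin(ang)); c <- mean(cos(ang))
  r <- sqrt(s^2 + c^2)
  if (r < 1e-10) abort("times are balanced around the circle: mean undefined")
  mean_h <- (atan2(s, c) / (2 * pi) * 24) %% 24
  if (24 - mean_h < 1e-9) mean_h <- 0 # guard against 24-epsilon wraparound
  sd_rad <- sqrt(pmax(0, -2 * log(min(r, 1))))
  tibble(mean_h = mean_h, dispersion_min = sd_rad * 24 * 60 / (2 * pi),
         n = length(hours))
}

# unwrap clock hours onto a line centred at their joint circular mean, so
# linear statistics (t, F) behave across midnight
unwrap_clock <- function(hours, centre = NULL) {
  if (is.null(centre)) centre <- circular_time_stats(hours)$mean_h
  centre + ((hours - centre + 12) %% 24) - 12
}

#' Per-subject aggregation of nightly quotas
#'
#' Averages a nightly variable to one value per subject per location,
#' controlling for repeated nights of the same subject before any group
#' test. Clock-time variables are averaged circularly.
#'
#' @param quotas Nightly quota table ([cohort_quotas()] output or similar),
#'   with `participant_id`, `gender`, `location` columns.
#' @param variable Name of the nightly column to aggregate.
#' @return Tibble with one row per (participant, location): metadata plus
#'   `value`.
#' @export
subject_aggregate <- function(quotas, variable) {
  circ <- variable %in% .CLOCK_VARS
  quotas %>%
    group_by(.data$participant_id, .data$gender, .data$location) %>%
    summarise(
      value = if (circ) circular_time_stats(.data[[variable]])$mean_h
              else mean(.data[[variable]]),
      n_nights = dplyr::n(), .groups = "drop"
    )
}

#' Default-prior (JZS) two-sample Bayes factor
#'
#' Bayes factor of a two-sided mean difference against the point null, under
#' the Jeffreys--Zellner--Siow default prior: a Cauchy prior with scale
#' `rscale` on the standardized effect size, equivalently an inverse-gamma
#' mixture over the effect variance `g`. Evaluated by adaptive quadrature of
#' the one-dimensional `g` integral. `BF > 1` favours a difference; `BF < 1`
#' favours the null.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @param rscale Cauchy prior scale on the standardized effect
#'   (default `sqrt(2)/2`).
#' @return Positive scalar Bayes factor (alternative vs null).
#' @export
#' @examples
#' bayes_factor_two_group(rnorm(20), rnorm(20))
bayes_factor_two_group <- function(a, b, rscale = sqrt(2) / 2) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values")
  v1 <- var(a); v2 <- var(b)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) abort("degenerate input: both groups constant and equal")
    return(Inf)
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  jzs_bf_from_t(t, nu, neff, rscale)
}

# JZS BF10 from a pooled t statistic: ratio of marginal likelihoods with the
# null density factored into the integrand for numerical stability.
jzs_bf_from_t <- function(t, nu, neff, rscale = sqrt(2) / 2) {
  log_ratio <- function(g) {
    -0.5 * log1p(neff * g) -
      (nu + 1) / 2 * (log1p(t^2 / ((1 + neff * g) * nu)) - log1p(t^2 / nu))
  }
  # g ~ inverse-gamma(1/2, rscale^2 / 2)
  log_prior <- function(g) {
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - rscale^2 / (2 * g)
  }
  val <- integrate(function(g) exp(log_ratio(g) + log_prior(g)),
                   lower = 0, upper = Inf, rel.tol = 1e-9)
  val$value
}

#' Interpret a Bayes factor on the Raftery scale
#'
#' Bands for evidence in favour of a difference: `(1, 3]` weak, `(3, 10]`
#' modest, `(10, 30]` strong, `> 30` very strong; `BF <= 1` favours the
#' null. Band edges belong to the lower band (left-closed convention).
#'
#' @param bf Positive Bayes factor.
#' @return One of `"null-favored"`, `"weak"`, `"modest"`, `"strong"`,
#'   `"very strong"`.
#' @export
#' @examples
#' interpret_bf(10.27)  # "strong"
interpret_bf <- function(bf) {
  if (is.na(bf) || bf <= 0) abort("Bayes factor must be positive")
  if (bf <= 1) "null-favored"
  else if (bf <= 3) "weak"
  else if (bf <= 10) "modest"
  else if (bf <= 30) "strong"
  else "very strong"
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test; clock-time inputs are circularly unwrapped about
#' their joint circular mean before testing.
#'
#' @param a,b Numeric samples (each `n >= 2`).
#' @param circular Treat values as clock hours on a 24-h circle.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b, circular = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (circular) {
    centre <- circular_time_stats(c(a, b))$mean_h
    a <- unwrap_clock(a, centre); b <- unwrap_clock(b, centre)
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                                          p_value = 1))
    abort("degenerate input: both groups constant")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' F-test of equality of variances
#'
#' `F = var(a) / var(b)` on `(n_a - 1, n_b - 1)` degrees of freedom with a
#' two-sided p-value; used to compare the variability of sleep timing
#' between groups.
#'
#' @inheritParams welch_t_test
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
variance_f_test <- function(a, b, circular = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (circular) {
    a <- unwrap_clock(a); b <- unwrap_clock(b)
  }
  if (var(b) == 0) abort("zero variance in denominator group")
  ht <- stats::var.test(a, b)
  tibble(statistic = unname(ht$statistic), df1 = unname(ht$parameter[1]),
         df2 = unname(ht$parameter[2]), p_value = ht$p.value)
}

#' Two-group contrast on a quota or rhythm metric
#'
#' Aggregates a nightly table to subject level, then contrasts the two
#' levels of a grouping factor with a JZS Bayes factor (the default for
#' magnitudes), a Welch t-test (the default for clock times), or a variance
#' F-test. Means and SDs of clock-time variables are circular.
#'
#' @param data Nightly quota/metric table with `participant_id`, `gender`,
#'   `location` and the target variable.
#' @param variable Column to contrast.
#' @param group Grouping column, e.g. `"location"` or `"gender"`.
#' @param method `"bf"`, `"t"`, or `"f"`; defaults to `"t"` for clock-time
#'   variables and `"bf"` otherwise.
#' @param aggregate Aggregate nights to subjects first (default TRUE).
#' @return One-row `GroupComparison` tibble: group labels, per-group n,
#'   mean, sd, `statistic_kind`, `value`, `p_value`, `bf_band`.
#' @export
compare_groups <- function(data, variable, group,
                           method = NULL, aggregate = TRUE) {
  circ <- variable %in% .CLOCK_VARS
  if (is.null(method)) method <- if (circ) "t" else "bf"
  method <- match.arg(method, c("bf", "t", "f"))
  vals <- if (aggregate) subject_aggregate(data, variable) else {
    data %>% mutate(value = .data[[variable]])
  }
  lv <- sort(unique(as.character(vals[[group]])))
  if (length(lv) != 2) abort(sprintf("grouping column '%s' must have exactly 2 levels", group))
  a <- vals$value[vals[[group]] == lv[1]]
  b <- vals$value[vals[[group]] == lv[2]]
  msd <- function(x) {
    if (circ) {
      cs <- circular_time_stats(x)
      c(cs$mean_h, cs$dispersion_min / 60)
    } else c(mean(x), sd(x))
  }
  ma <- msd(a); mb <- msd(b)
  res <- switch(method,
    bf = {
      bf <- bayes_factor_two_group(if (circ) unwrap_clock(a) else a,
                                   if (circ) unwrap_clock(b) else b)
      tibble(statistic_kind = "bayes_factor", value = bf,
             p_value = NA_real_, bf_band = interpret_bf(bf))
    },
    t = {
      ht <- welch_t_test(a, b, circular = circ)
      tibble(statistic_kind = "t", value = ht$statistic,
             p_value = ht$p_value, bf_band = NA_character_)
    },
    f = {
      ht <- variance_f_test(a, b, circular = circ)
      tibble(statistic_kind = "F", value = ht$statistic,
             p_value = ht$p_value, bf_band = NA_character_)
    }
  )
  dplyr::bind_cols(
    tibble(variable = variable,
           group_a = lv[1], group_b = lv[2],
           n_a = length(a), n_b = length(b),
           mean_a = ma[1], sd_a = ma[2], mean_b = mb[1], sd_b = mb[2]),
    res
  )
}
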