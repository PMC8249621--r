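# Fourier design matrix on a periodic grid of n points, K harmonics.
fourier_basis <- function(n, k) {
  t <- (seq_len(n) - 1) / n
  cols <- list(rep(1, n))
  for (h in seq_len(k)) {
    cols[[length(cols) + 1L]] <- cos(2 * pi * h * t)
    cols[[length(cols) + 1L]] <- sin(2 * pi * h * t)
  }
  do.call(cbind, cols)
}

# Least-squares projection of profile rows onto the Fourier basis.
fourier_smooth <- function(profile, k) {
  n <- length(profile)
  B <- fourier_basis(n, k)
  coefs <- solve(crossprod(B), crossprod(B, profile))
  as.numeric(B %*% coefs)
}

#' Build per-participant functional activity profiles
#'
#' For each series with at least `min_days` complete noon-to-noon days,
#' averages activity by minute of day and projects the 1440-point profile
#' onto a periodic Fourier basis (constant + `k` harmonics), giving a
#' smooth 24-h activity curve per participant.
#'
#' @param cohort A [sleep_cohort()] (or plain list of [epoch_series()]).
#' @param grouping `"gender"` or `"location"`: the label attached to each
#'   curve for group comparison.
#' @param k Number of Fourier harmonics (default 9, resolving features at
#'   roughly the 80-minute scale).
#' @param min_days Minimum complete days per participant (default 2);
#'   shorter series are excluded with a message.
#' @return Tibble with `participant_id`, `group`, `n_days`, and list-columns
#'   `raw` and `smooth` (1440-point profiles).
#' @export
build_profiles <- function(cohort, grouping = c("location", "gender"),
                           k = 9, min_days = 2) {
  grouping <- match.arg(grouping)
  series <- if (inherits(cohort, "sleep_cohort")) cohort$series else cohort
  rows <- list()
  skipped <- 0L
  for (s in series) {
    d <- floor(nrow(s) / 1440)
    if (d < min_days) { skipped <- skipped + 1L; next }
    raw_prof <- average_day_profile(s, min_days = min_days)
    smooth_prof <- fourier_smooth(raw_prof, k)
    rows[[length(rows) + 1L]] <- tibble(
      participant_id = attr(s, "participant_id"),
      group = attr(s, grouping),
      n_days = d,
      raw = list(raw_prof),
      smooth = list(smooth_prof)
    )
  }
  if (skipped > 0) {
    message(sprintf("%d series with < %d complete days excluded from FLM", skipped, min_days))
  }
  if (!length(rows)) abort("no series with enough complete days")
  list_rbind(rows)
}

# n x T matrix of smoothed curves from a profiles tibble
profiles_matrix <- function(profiles) {
  do.call(rbind, profiles$smooth)
}

# pointwise one-way F over the grid for a curve matrix and group labels
pointwise_f_matrix <- function(Y, g) {
  g <- as.character(g)
  lv <- unique(g)
  n <- nrow(Y)
  kg <- length(lv)
  grand <- colMeans(Y)
  ssb <- 0; ssw <- 0
  for (l in lv) {
    sel <- g == l
    m <- colMeans(Y[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - grand)^2
    ssw <- ssw + colSums((Y[sel, , drop = FALSE] - rep(m, each = sum(sel)))^2)
  }
  msb <- ssb / (kg - 1)
  msw <- ssw / (n - kg)
  f <- msb / msw
  zero_w <- msw == 0
  if (any(zero_w & msb > 0)) {
    warn("zero within-group variance at some time points; F set to Inf there")
    f[zero_w & msb > 0] <- Inf
  }
  f[zero_w & msb == 0] <- 0
  f
}

#' Pointwise F statistic between group mean curves
#'
#' At each grid point, the one-way ANOVA F of the smoothed curve values:
#' between-group mean square over within-group mean square.
#'
#' @param profiles Profiles tibble from [build_profiles()] (needs `group`
#'   and the `smooth` list-column; any grid length is accepted).
#' @return Numeric vector of F values over the grid.
#' @export
pointwise_F <- function(profiles) {
  if (length(unique(profiles$group)) < 2) abort("need at least 2 groups")
  if (any(table(profiles$group) < 2)) abort("each group needs at least 2 profiles")
  pointwise_f_matrix(profiles_matrix(profiles), profiles$group)
}

#' Pointwise permutation critical curve
#'
#' Randomly relabels participants to groups (group sizes preserved),
#' recomputes the pointwise F for each relabelling, and returns the
#' empirical `1 - alpha` quantile at each grid point. Deterministic for a
#' fixed seed. Relabellings are sampled with replacement; a warning is
#' issued when fewer distinct relabellings exist than `n_perm`.
#'
#' @inheritParams pointwise_F
#' @param alpha Pointwise significance level (default 0.05).
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @return Numeric critical curve over the grid.
#' @export
permutation_critical <- function(profiles, alpha = 0.05, n_perm = 500,
                                 seed = 1) {
  Y <- profiles_matrix(profiles)
  g <- as.character(profiles$group)
  n <- length(g)
  n_distinct <- tryCatch(choose(n, sum(g == g[1])), error = function(e) Inf)
  if (is.finite(n_distinct) && n_distinct < n_perm) {
    warn(sprintf("only %d distinct relabellings exist (< %d permutations); sampling with replacement",
                 n_distinct, n_perm))
  }
  perm_f <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pointwise_f_matrix(Y, sample(g))
    }, numeric(ncol(Y)))
  })
  apply(perm_f, 1, quantile, probs = 1 - alpha, names = FALSE)
}

#' Functional comparison of 24-h activity curves
#'
#' Full functional linear modelling contrast: smooth per-participant
#' profiles, group mean curves, observed pointwise F, permutation critical
#' curve, and the significance mask where the observed F exceeds the
#' critical value.
#'
#' @param cohort A [sleep_cohort()] or a profiles tibble from
#'   [build_profiles()].
#' @param grouping `"location"` or `"gender"` (ignored when a profiles
#'   tibble is supplied).
#' @param alpha Pointwise significance level (default 0.05).
#' @param n_perm Permutations (default 500).
#' @param seed Integer seed for the permutation draw.
#' @param k Fourier harmonics for smoothing (default 9).
#' @return Object of class `flm_result` with a tidy per-minute table.
#' @export
flm_compare <- function(cohort, grouping = c("location", "gender"),
                        alpha = 0.05, n_perm = 500, seed = 1, k = 9) {
  profiles <- if (is_tibble(cohort) && "smooth" %in% names(cohort)) cohort
              else build_profiles(cohort, grouping, k = k)
  if (length(unique(profiles$group)) < 2) abort("grouping has a single level")
  f_obs <- pointwise_F(profiles)
  crit <- permutation_critical(profiles, alpha, n_perm, seed)
  Y <- profiles_matrix(profiles)
  grid_n <- ncol(Y)
  means <- map(split(seq_len(nrow(Y)), profiles$group),
               function(i) colMeans(Y[i, , drop = FALSE]))
  tab <- tibble(
    minute = (seq_len(grid_n) - 1) * (1440 / grid_n),
    f_obs = f_obs, critical = crit,
    significant = f_obs > crit
  )
  for (gname in names(means)) tab[[paste0("mean_", gname)]] <- means[[gname]]
  structure(list(
    table = tab, alpha = alpha, n_perm = n_perm, seed = seed,
    groups = names(means),
    n_profiles = nrow(profiles)
  ), class = "flm_result")
}

#' @export
print.flm_result <- function(x, ...) {
  cat(sprintf(
    "<flm_result> %s vs %s: %d profiles, %.1f%% of the day significant (alpha = %g, %d permutations)\n",
    x$groups[1], x$groups[2], x$n_profiles,
    100 * mean(x$table$significant), x$alpha, x$n_perm
  ))
  invisible(x)
}

#' @rdname flm_compare
#' @param x An `flm_result`.
#' @param ... Unused.
#' @export
tidy.flm_result <- function(x, ...) x$table

#' @rdname flm_compare
#' @export
glance.flm_result <- function(x, ...) {
  tibble(n_profiles = x$n_profiles, alpha = x$alpha, n_perm = x$n_perm,
         significant_fraction = mean(x$table$significant))
}

#' @rdname flm_compare
#' @param object An `flm_result`.
#' @export
autoplot.flm_result <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute / 60)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_obs), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$critical), linetype = 3) +
    ggplot2::geom_rug(data = d[d$significant, ], sides = "b",
                      colour = "firebrick", alpha = 0.5) +
    ggplot2::labs(x = "clock hour", y = "pointwise F",
                  title = sprintf("%s vs %s (alpha = %g, %d permutations)",
                                  object$groups[1], object$groups[2],
                                  object$alpha, object$n_perm)) +
    ggplot2::theme_minimal()
}
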