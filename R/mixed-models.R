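#' Standardize model predictors
#'
#' Mean-centres and SD-scales continuous predictors so coefficients are
#' comparable, and codes the design factors 0/1 with the study's reference
#' levels: `gender` woman = 0, man = 1; `location` village = 0, forest = 1.
#'
#' @param data Night-level table.
#' @param continuous Character vector of continuous predictor columns.
#' @return The table with scaled continuous columns and numeric
#'   `gender_man`, `location_forest` indicators (when the factors exist).
#' @export
scale_predictors <- function(data,
                             continuous = c("rainfall_mm", "temperature",
                                            "humidity", "moon_phase", "age")) {
  continuous <- intersect(continuous, names(data))
  for (v in continuous) {
    s <- sd(data[[v]])
    if (is.na(s) || s == 0) abort(sprintf("predictor '%s' has zero variance", v))
    data[[v]] <- (data[[v]] - mean(data[[v]])) / s
  }
  if ("gender" %in% names(data)) {
    data$gender_man <- as.numeric(data$gender == "man")
  }
  if ("location" %in% names(data)) {
    data$location_forest <- as.numeric(data$location == "forest")
  }
  data
}

#' Fit one random-intercept linear mixed model
#'
#' Maximum-likelihood fit of `outcome ~ fixed terms + (1 | participant_id)`
#' via lme4, returning the pieces the model-averaging stage needs. ML (not
#' REML) is used so AIC is comparable across fixed-effect structures.
#'
#' @param data Night-level table containing the outcome, the terms and
#'   `participant_id`.
#' @param outcome Outcome column name.
#' @param terms Character vector of fixed-effect terms (e.g.
#'   `"gender_man:location_forest"` for the interaction); may be empty for
#'   the intercept-only model.
#' @return List of class `lmm_fit` with `coef` (tibble of term, beta, se),
#'   `aic`, `loglik`, `converged`, `terms`, `model`.
#' @export
fit_lmm <- function(data, outcome, terms = character()) {
  if (sd(data[[outcome]]) == 0) abort("outcome is constant: model degenerate")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- as.formula(paste0(outcome, " ~ ", rhs, " + (1 | participant_id)"))
  fit <- suppressMessages(lme4::lmer(form, data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(
    coef = tibble(term = names(fe), beta = unname(fe), se = unname(se)),
    aic = AIC(fit), loglik = as.numeric(logLik(fit)),
    converged = conv, terms = terms, model = fit
  ), class = "lmm_fit")
}

#' Enumerate the candidate fixed-effect structures
#'
#' All subsets of the supplied terms that respect marginality (an
#' interaction is only included together with both main effects), each
#' keeping the subject random intercept; the intercept-only model is
#' included.
#'
#' @param terms Character vector of fixed terms; interactions written as
#'   `"a:b"`.
#' @return List of character vectors, one per candidate model.
#' @export
candidate_set <- function(terms) {
  n <- length(terms)
  subsets <- map(seq_len(2^n) - 1L, function(mask) {
    terms[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
  })
  keep(subsets, function(sub) {
    inter <- grep(":", sub, value = TRUE)
    all(map_lgl(inter, function(tm) {
      all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% sub)
    }))
  })
}

#' AIC-weighted shrinkage (full) model averaging
#'
#' Retains candidates with `delta AIC < delta_max` from the best model,
#' weights them by Akaike weights `w ~ exp(-delta/2)`, and averages each
#' coefficient over all retained models with zero substituted where the
#' term is absent (full/shrinkage averaging, which pulls weakly supported
#' terms toward zero). The unconditional standard error combines
#' within-model variance and between-model spread; 95% CI is
#' `beta +/- 1.96 * SE`.
#'
#' @param fits List of [fit_lmm()] results.
#' @param delta_max AIC window relative to the best model (default 10).
#' @return Object of class `averaged_fit`: tibble of term-level results plus
#'   model bookkeeping.
#' @export
model_average_shrinkage <- function(fits, delta_max = 10) {
  fits <- keep(fits, function(f) isTRUE(f$converged))
  if (!length(fits)) abort("no converged candidate models")
  aics <- map_dbl(fits, "aic")
  delta <- aics - min(aics)
  fits <- fits[delta < delta_max]
  delta <- delta[delta < delta_max]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  all_terms <- unique(unlist(map(fits, function(f) f$coef$term)))
  rows <- map(all_terms, function(tm) {
    beta_m <- map_dbl(fits, function(f) {
      i <- match(tm, f$coef$term)
      if (is.na(i)) 0 else f$coef$beta[i]
    })
    var_m <- map_dbl(fits, function(f) {
      i <- match(tm, f$coef$term)
      if (is.na(i)) 0 else f$coef$se[i]^2
    })
    beta_bar <- sum(w * beta_m)
    se_u <- sqrt(sum(w * (var_m + (beta_m - beta_bar)^2)))
    tibble(
      term = tm, beta = beta_bar, se = se_u,
      ci_low = beta_bar - 1.96 * se_u, ci_high = beta_bar + 1.96 * se_u,
      weight_sum = sum(w[map_lgl(fits, function(f) tm %in% f$coef$term)])
    )
  })
  structure(list(
    terms = list_rbind(rows),
    n_models = length(fits),
    weights = w, delta = delta, delta_max = delta_max
  ), class = "averaged_fit")
}

#' Fit and AIC-average mixed models of a sleep quota
#'
#' Convenience wrapper: standardizes predictors (and optionally the
#' outcome, the default, so coefficients are reported on the standardized
#' scale), enumerates the marginality-respecting candidate set, fits each
#' by ML with a subject random intercept, and shrinkage-averages the
#' retained models.
#'
#' @param data Night-level table (e.g. [cohort_quotas()] output).
#' @param outcome Outcome column, e.g. `"tst_h"`.
#' @param terms Fixed terms of the full model. The default mirrors a field
#'   model of sleep on ecology and demography: rainfall, temperature,
#'   humidity, moon phase, age, gender, location and the gender-by-location
#'   interaction.
#' @param delta_max AIC retention window (default 10).
#' @param standardize_outcome Z-score the outcome before fitting
#'   (default TRUE).
#' @return An `averaged_fit` object; see [model_average_shrinkage()].
#' @export
sleep_lmm_average <- function(data, outcome,
                              terms = c("rainfall_mm", "temperature", "humidity",
                                        "moon_phase", "age", "gender_man",
                                        "location_forest",
                                        "gender_man:location_forest"),
                              delta_max = 10,
                              standardize_outcome = TRUE) {
  data <- scale_predictors(data)
  if (standardize_outcome) {
    s <- sd(data[[outcome]])
    if (is.na(s) || s == 0) abort("outcome is constant")
    data[[outcome]] <- (data[[outcome]] - mean(data[[outcome]])) / s
  }
  cands <- candidate_set(terms)
  fits <- list()
  for (sub in cands) {
    f <- tryCatch(fit_lmm(data, outcome, sub), error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  out <- model_average_shrinkage(fits, delta_max)
  out$outcome <- outcome
  out$n_candidates <- length(cands)
  out
}

#' @export
print.averaged_fit <- function(x, ...) {
  cat(sprintf("<averaged_fit>%s %d retained model(s) of %s candidates (dAIC < %g)\n",
              if (is.null(x$outcome)) "" else paste0(" ", x$outcome, ":"),
              x$n_models,
              if (is.null(x$n_candidates)) "?" else x$n_candidates,
              x$delta_max))
  print(x$terms)
  invisible(x)
}

#' @rdname sleep_lmm_average
#' @param x An `averaged_fit` object.
#' @param ... Unused.
#' @export
tidy.averaged_fit <- function(x, ...) {
  rename(x$terms, estimate = "beta", std.error = "se",
         conf.low = "ci_low", conf.high = "ci_high")
}

#' @rdname sleep_lmm_average
#' @export
glance.averaged_fit <- function(x, ...) {
  tibble(n_models = x$n_models,
         n_candidates = if (is.null(x$n_candidates)) NA_integer_ else x$n_candidates,
         delta_max = x$delta_max,
         max_weight = max(x$weights))
}

#' @rdname sleep_lmm_average
#' @param object An `averaged_fit` object.
#' @export
autoplot.averaged_fit <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "standardized coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
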