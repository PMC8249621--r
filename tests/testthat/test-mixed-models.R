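# small simulated night table for model tests
sim_table <- function(n_subj = 30, nights = 6, beta_int = 0, sd_re = 0.5,
                      sd_eps = 1) {
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = nights)
  gender <- rep(rep(c("woman", "man"), length.out = n_subj), each = nights)
  location <- rep(rep(c("village", "forest"), each = nights / 2), n_subj)
  re <- rep(rnorm(n_subj, 0, sd_re), each = nights)
  g <- as.numeric(gender == "man"); l <- as.numeric(location == "forest")
  tibble::tibble(
    participant_id = subj, gender = gender, location = location,
    age = rep(round(runif(n_subj, 18, 70)), each = nights),
    temperature = rnorm(n_subj * nights, 23, 1),
    humidity = rnorm(n_subj * nights, 84, 4),
    rainfall_mm = rexp(n_subj * nights, 1 / 4),
    moon_phase = runif(n_subj * nights),
    tst_h = 6 + beta_int * g * l + re + rnorm(n_subj * nights, 0, sd_eps)
  )
}

test_that("scale_predictors standardizes and codes references correctly", {
  d <- tibble::tibble(temperature = c(21, 23, 25), humidity = c(80, 84, 88),
                      gender = c("woman", "man", "woman"),
                      location = c("village", "forest", "forest"))
  s <- scale_predictors(d, continuous = c("temperature", "humidity"))
  expect_equal(mean(s$temperature), 0)
  expect_equal(sd(s$temperature), 1)
  expect_equal(s$gender_man, c(0, 1, 0))
  expect_equal(s$location_forest, c(0, 1, 1))
  # idempotence on an already standardized column
  s2 <- scale_predictors(s, continuous = "temperature")
  expect_equal(s2$temperature, s$temperature, tolerance = 1e-12)
  d$temperature <- 22
  expect_error(scale_predictors(d, continuous = "temperature"), "zero variance")
})

test_that("with no between-subject variance the LMM matches OLS", {
  set.seed(41)
  d <- sim_table(20, 4, beta_int = 0.5, sd_re = 0)
  d <- scale_predictors(d)
  fit <- fit_lmm(d, "tst_h", c("gender_man", "location_forest",
                               "gender_man:location_forest"))
  ols <- stats::lm(tst_h ~ gender_man + location_forest +
                     gender_man:location_forest, data = d)
  expect_equal(fit$coef$beta, unname(coef(ols)), tolerance = 1e-5)
  expect_error(fit_lmm(dplyr::mutate(d, tst_h = 1), "tst_h", "gender_man"),
               "constant")
})

test_that("candidate enumeration respects marginality", {
  expect_length(candidate_set(c("a", "b")), 4L)
  cands <- candidate_set(c("g", "l", "g:l"))
  expect_length(cands, 5L)
  for (sub in cands) {
    if ("g:l" %in% sub) expect_true(all(c("g", "l") %in% sub))
  }
  # full 8-term model: oracle enumeration of valid subsets
  terms <- c("rain", "temp", "hum", "moon", "age", "g", "l", "g:l")
  oracle_count <- 0L
  for (mask in 0:(2^8 - 1)) {
    sub <- terms[bitwAnd(mask, 2^(0:7)) > 0]
    if ("g:l" %in% sub && !all(c("g", "l") %in% sub)) next
    oracle_count <- oracle_count + 1L
  }
  expect_length(candidate_set(terms), oracle_count)
  expect_equal(oracle_count, 2^5 * 5L)
})

test_that("shrinkage averaging follows the Akaike-weight arithmetic", {
  mk_fit <- function(terms, betas, ses, aic) {
    structure(list(
      coef = tibble::tibble(term = names(betas), beta = unname(betas),
                            se = unname(ses)),
      aic = aic, loglik = NA_real_, converged = TRUE, terms = terms
    ), class = "lmm_fit")
  }
  # single retained model: averaged coefficients equal that model's
  f1 <- mk_fit("x", c("(Intercept)" = 0.2, x = 1), c("(Intercept)" = 0.1, x = 0.3), 100)
  avg1 <- model_average_shrinkage(list(f1))
  expect_equal(avg1$terms$beta[avg1$terms$term == "x"], 1)
  # two equal-AIC models, term present in one with beta 1 -> average 0.5
  f0 <- mk_fit(character(), c("(Intercept)" = 0.2), c("(Intercept)" = 0.1), 100)
  avg2 <- model_average_shrinkage(list(f1, f0))
  expect_equal(avg2$terms$beta[avg2$terms$term == "x"], 0.5)
  expect_equal(sum(avg2$weights), 1)
  expect_equal(avg2$terms$weight_sum[avg2$terms$term == "x"], 0.5)
  # dAIC = 20 under a dAIC < 10 filter excludes the second model
  f_bad <- mk_fit("x", c("(Intercept)" = 0, x = 9), c("(Intercept)" = 1, x = 1), 120)
  avg3 <- model_average_shrinkage(list(f1, f_bad))
  expect_equal(avg3$n_models, 1L)
  expect_equal(avg3$terms$beta[avg3$terms$term == "x"], 1)
  # CI identity
  tt <- avg2$terms
  expect_equal(tt$ci_low, tt$beta - 1.96 * tt$se, tolerance = 1e-9)
  expect_equal(tt$ci_high, tt$beta + 1.96 * tt$se, tolerance = 1e-9)
  expect_error(model_average_shrinkage(list()), "no converged")
})

test_that("shrinkage estimates are bounded by the largest conditional estimate", {
  set.seed(55)
  d <- scale_predictors(sim_table(24, 4, beta_int = 0.6))
  avg <- sleep_lmm_average(d, "tst_h",
                           terms = c("gender_man", "location_forest",
                                     "gender_man:location_forest"))
  expect_equal(sum(avg$weights), 1)
  expect_equal(avg$n_candidates, 5L)
  td <- tidy(avg)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  g <- glance(avg)
  expect_equal(g$n_models, avg$n_models)
})

test_that("the interaction coefficient is recovered and signed correctly", {
  set.seed(61)
  n_rep <- 40
  hits <- 0; neg <- 0
  for (r in seq_len(n_rep)) {
    d <- sim_table(40, 6, beta_int = -0.74)
    truth <- -0.74 / sd(d$tst_h) # standardized-outcome scale
    d2 <- scale_predictors(d)
    d2$tst_h <- as.numeric(scale(d2$tst_h))
    fit <- fit_lmm(d2, "tst_h", c("gender_man", "location_forest",
                                  "gender_man:location_forest"))
    i <- match("gender_man:location_forest", fit$coef$term)
    est <- fit$coef$beta[i]; se <- fit$coef$se[i]
    if (abs(est - truth) <= 2 * se) hits <- hits + 1
    if (est < 0) neg <- neg + 1
  }
  expect_gte(hits / n_rep, 0.9)
  expect_gte(neg / n_rep, 0.9)
})

test_that("autoplot on an averaged fit returns a ggplot", {
  set.seed(9)
  d <- scale_predictors(sim_table(16, 4, beta_int = 0.4))
  avg <- sleep_lmm_average(d, "tst_h",
                           terms = c("gender_man", "location_forest",
                                     "gender_man:location_forest"))
  expect_s3_class(autoplot(avg), "ggplot")
})
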