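test_that("the default design reproduces the study roster exactly", {
  cc <- cohort_config(seed = 11)
  coh <- generate_cohort(cc)
  meta <- dplyr::bind_rows(lapply(coh$series, series_meta))
  expect_equal(sum(meta$location == "village"), 39L)
  expect_equal(sum(meta$location == "village" & meta$gender == "man"), 20L)
  expect_equal(sum(meta$location == "forest"), 23L)
  expect_equal(sum(meta$location == "forest" & meta$gender == "man"), 10L)
  expect_equal(length(unique(meta$participant_id)), 51L)
  # per-location night totals and the 3-8 range
  nights <- vapply(coh$series, function(s) nrow(attr(s, "truth")), integer(1))
  expect_true(all(nights >= 3 & nights <= 8))
  expect_equal(sum(nights[meta$location == "village"]), 226L)
  expect_equal(sum(nights[meta$location == "forest"]), 136L)
  expect_true(all(meta$age >= 17 & meta$age <= 72))
})

test_that("generation is deterministic for a fixed seed", {
  c1 <- generate_cohort(cohort_config(
    n_village_women = 3, n_village_men = 2, n_forest_women = 2, n_forest_men = 2,
    n_shared_women = 1, n_shared_men = 1, nights_total = NULL, seed = 99))
  c2 <- generate_cohort(cohort_config(
    n_village_women = 3, n_village_men = 2, n_forest_women = 2, n_forest_men = 2,
    n_shared_women = 1, n_shared_men = 1, nights_total = NULL, seed = 99))
  expect_identical(lapply(c1$series, function(s) s$count),
                   lapply(c2$series, function(s) s$count))
  expect_identical(c1$weather, c2$weather)
})

test_that("counts are nonnegative integers and nights stay inside their day", {
  set.seed(23)
  s <- generate_participant_series(cohort_config(), "man", "forest", 4)
  expect_true(all(s$count >= 0))
  expect_true(all(s$count == floor(s$count)))
  tr <- attr(s, "truth")
  # sleep window within noon-to-noon: onset after 18:00, end before 11:30
  expect_true(all(tr$onset_h >= 18 | tr$onset_h <= 4.5))
  expect_true(all(tr$end_h < 11.5))
  expect_true(all(tr$tst_h <= tr$window_h + 1e-9))
  expect_error(generate_participant_series(cohort_config(), "man", "forest", 0),
               "n_nights")
})

test_that("config validation rejects impossible designs", {
  expect_error(cohort_config(n_village_women = 0, n_village_men = 0,
                             n_forest_women = 0, n_forest_men = 0),
               "empty design")
  expect_error(cohort_config(nights_range = c(0, 8)), "nights_range")
  expect_error(cohort_config(nap_probability = 1.4), "nap_probability")
  expect_error(cohort_config(tst_sd_h = -1), "nonnegative")
})

test_that("scored TST difference between forest women and men matches the configured offset", {
  set.seed(5)
  cc <- cohort_config()
  sim_cell <- function(g) {
    q <- lapply(1:63, function(i) sleep_quotas(
      generate_participant_series(cc, g, "forest", 8,
                                  participant_id = paste0(g, i))))
    dplyr::bind_rows(q)
  }
  qw <- sim_cell("woman"); qm <- sim_cell("man")
  expect_gte(nrow(qw), 500); expect_gte(nrow(qm), 500)
  diff <- mean(qw$tst_h) - mean(qm$tst_h)
  expect_equal(diff, 6.53 - 5.65, tolerance = 0.15 / 0.88)
  # forest men's sleep timing is more variable than women's
  aw <- subject_aggregate(qw, "sleep_end_h")$value
  am <- subject_aggregate(qm, "sleep_end_h")$value
  expect_gt(variance_f_test(am, aw, circular = TRUE)$statistic, 1)
})

test_that("weather obeys its physical bounds and the moon cycle is periodic", {
  cc <- cohort_config(seed = 2)
  w <- withr::with_seed(2, generate_weather(cc, 1000))
  hum <- rowMeans(as.matrix(w[, c("hum_2100", "hum_0000", "hum_0300", "hum_0600")]))
  expect_true(all(hum >= 0 & hum <= 100))
  tmean <- rowMeans(as.matrix(w[, c("temp_2100", "temp_0000", "temp_0300", "temp_0600")]))
  expect_true(mean(tmean) >= 21 && mean(tmean) <= 25)
  expect_true(all(w$rainfall_mm >= 0))
  expect_true(all(w$moon_phase >= 0 & w$moon_phase <= 1))
  expect_equal(moon_illumination(0), moon_illumination(29.5), tolerance = 1e-6)
  expect_equal(moon_illumination(3.2, period = 29.5),
               moon_illumination(3.2 + 29.5, period = 29.5), tolerance = 1e-6)
})

test_that("a constant template makes rhythm amplitude come from the sleep window alone", {
  cc <- cohort_config(template_harmonics = list(a0 = 1, a1 = 0, peak_h = 13,
                                                a2 = 0, peak2_h = 8),
                      count_dispersion = Inf, sleep_count_rate = 0,
                      nap_probability = 0, tst_sd_h = 0)
  cc$cells$onset_sd_min <- 0
  cc$cells$end_sd_min <- 0
  cc$cells$tst_mean_h <- (cc$cells$end_mean_h + 24) - cc$cells$onset_mean_h
  set.seed(31)
  s <- generate_participant_series(cc, "woman", "village", 7)
  prof <- average_day_profile(s)
  ml <- m10_l5(prof)
  # daytime level is flat, sleep window is exactly zero
  expect_equal(ml$l5, 0)
  expect_equal(ml$m10, max(prof))
  tr <- attr(s, "truth")
  # L5 onset falls inside the (deterministic) sleep window
  expect_true(clock_in_window(ml$l5_onset_h, tr$onset_h[1], tr$end_h[1] - 5))
})

test_that("the full pipeline recovers the configured gender-location TST interaction", {
  # reduced-size replicate study: generate -> score -> quotas -> LMM
  n_rep <- 12
  hits <- 0; neg <- 0
  for (r in seq_len(n_rep)) {
    cc <- cohort_config(n_village_women = 8, n_village_men = 8,
                        n_forest_women = 8, n_forest_men = 8,
                        n_shared_women = 4, n_shared_men = 4,
                        nights_total = NULL, nights_range = c(4, 6),
                        seed = 1000 + r)
    coh <- generate_cohort(cc)
    q <- suppressMessages(cohort_quotas(coh))
    truth_raw <- (5.65 - 6.53) - (5.77 - 5.91) # cell-mean interaction, hours
    truth <- truth_raw / sd(q$tst_h)
    d <- scale_predictors(q)
    d$tst_h <- as.numeric(scale(d$tst_h))
    fit <- fit_lmm(d, "tst_h", c("gender_man", "location_forest",
                                 "gender_man:location_forest"))
    i <- match("gender_man:location_forest", fit$coef$term)
    if (abs(fit$coef$beta[i] - truth) <= 2 * fit$coef$se[i]) hits <- hits + 1
    if (fit$coef$beta[i] < 0) neg <- neg + 1
  }
  expect_gte(hits / n_rep, 0.85)
  expect_gte(neg / n_rep, 0.85)
})
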