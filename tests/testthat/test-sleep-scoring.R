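test_that("zero activity scores all sleep and saturated activity all wake", {
  cfg <- scoring_config()
  s0 <- make_series(rep(0L, 60))
  expect_true(all(score_epochs(s0, cfg)$state == "sleep"))
  s1 <- make_series(rep(5000L, 60))
  expect_true(all(score_epochs(s1, cfg)$state == "wake"))
})

test_that("a single spike is scored wake over exactly the weighted reach", {
  x <- rep(0L, 20); x[10] <- 1000L
  s <- make_series(x)
  # default weights: centre 1 and first neighbours 0.2 push the sum over
  # threshold 100; the 0.08/0.04 neighbours stay under
  st <- score_epochs(s, scoring_config())$state
  expect_equal(which(st == "wake"), 9:11)
  # unit centre weight: only the spike minute itself
  st1 <- score_epochs(s, unit_scoring())$state
  expect_equal(which(st1 == "wake"), 10L)
})

test_that("off-wrist minutes are always scored wake", {
  s <- make_series(rep(0L, 30), offwrist = c(rep(FALSE, 10), TRUE, rep(FALSE, 19)))
  st <- score_epochs(s, scoring_config())$state
  expect_equal(which(st == "wake"), 11L)
})

test_that("main sleep period edges follow the rest-run rule", {
  cfg <- unit_scoring()
  # clean night 21:00-05:30
  s <- make_series(day_counts(21, 5.5))
  m <- detect_main_sleep_period(score_epochs(s, cfg), cfg)
  expect_equal(clock_hour(m$onset), 21)
  expect_equal(clock_hour(m$end), 5.5)
  expect_equal(m$tib_h, 8.5)

  # an interior 30-min wake bout does not move the edges
  s2 <- make_series(day_counts(21, 5.5, extra = list(c(2, 2.5, 1000))))
  m2 <- detect_main_sleep_period(score_epochs(s2, cfg), cfg)
  expect_equal(clock_hour(m2$onset), 21)
  expect_equal(clock_hour(m2$end), 5.5)
  expect_equal(m2$tib_h, 8.5)

  # two candidate runs starting 19:00 and 23:00: first qualifying wins
  s3 <- make_series(day_counts(23, 5.5, extra = list(c(19, 19.5, 0))))
  m3 <- detect_main_sleep_period(score_epochs(s3, cfg), cfg)
  expect_equal(clock_hour(m3$onset), 19)
})

test_that("interior wake splits TST and WASO without changing TIB", {
  cfg <- unit_scoring()
  s <- make_series(day_counts(21, 5.5, extra = list(c(2, 2.5, 1000))))
  q <- sleep_quotas(s, cfg)
  expect_equal(q$tib_h, 8.5)
  expect_equal(q$tst_h, 8.0)
  expect_equal(q$waso_h, 0.5)
  expect_equal(q$efficiency_pct, 100 * 8 / 8.5)
  expect_equal(q$ttst_h, q$tst_h + q$nap_h)
})

test_that("perfect sleep gives WASO 0 and efficiency 100", {
  q <- sleep_quotas(make_series(day_counts(21, 5.5)), unit_scoring())
  expect_equal(q$waso_h, 0)
  expect_equal(q$efficiency_pct, 100)
})

test_that("quota identities hold on generated nights", {
  set.seed(42)
  s <- generate_participant_series(cohort_config(), "man", "forest", 5)
  q <- sleep_quotas(s)
  expect_true(all(q$tst_h + q$waso_h <= q$tib_h + 1e-9))
  expect_true(all(q$nap_h >= 0))
  expect_equal(q$ttst_h - q$tst_h, q$nap_h)
  expect_true(all(q$efficiency_pct >= 0 & q$efficiency_pct <= 100))
  # appending daytime epochs after the final day must not change quotas
  s_ext <- make_series(c(s$count, rep(2000L, 120)), id = "P1",
                       gender = "man", location = "forest")
  q_ext <- sleep_quotas(s_ext)
  expect_equal(q_ext$tst_h, q$tst_h)
  expect_equal(q_ext$nap_h, q$nap_h)
})

test_that("raising the threshold never decreases scored sleep or TST", {
  set.seed(7)
  s <- generate_participant_series(cohort_config(), "woman", "village", 3)
  for (thr in list(c(50, 100), c(100, 300))) {
    st_lo <- score_epochs(s, scoring_config(threshold = thr[1]))$state
    st_hi <- score_epochs(s, scoring_config(threshold = thr[2]))$state
    expect_true(all(st_hi[st_lo == "sleep"] == "sleep"))
    q_lo <- sleep_quotas(s, scoring_config(threshold = thr[1]))
    q_hi <- sleep_quotas(s, scoring_config(threshold = thr[2]))
    expect_true(all(q_hi$tst_h >= q_lo$tst_h - 1e-9))
  }
})

test_that("fragmentation index matches hand-enumerated bout arithmetic", {
  # fully immobile period: one long bout, nothing mobile
  expect_equal(fragmentation_index(rep("sleep", 120)), 0)

  # 100 immobile minutes in 5 bouts (2 of length 1) + 10 mobile minutes:
  # 100*(10/100) + 100*(2/5) = 50
  states <- c(rep("sleep", 40), rep("wake", 4), "sleep", rep("wake", 2),
              rep("sleep", 30), rep("wake", 2), "sleep", rep("wake", 2),
              rep("sleep", 28))
  expect_equal(fragmentation_index(states), 50)
  expect_equal(fragmentation_index(states), fragmentation_oracle(states))

  # strict 60-min alternation: 100*(30/30) + 100*(30/30) = 200
  alt <- rep(c("sleep", "wake"), 30)
  expect_equal(fragmentation_index(alt), 200)
  expect_equal(fragmentation_index(alt), fragmentation_oracle(alt))

  # random sequences agree with the brute-force oracle
  set.seed(1)
  for (i in 1:25) {
    st <- sample(c("sleep", "wake"), 200, replace = TRUE, prob = c(0.8, 0.2))
    if (!any(st == "sleep")) next
    expect_equal(fragmentation_index(st), fragmentation_oracle(st))
  }

  expect_error(fragmentation_index(rep("wake", 10)), "no immobile bouts")
})

test_that("nap detection applies the minimum-duration rule", {
  cfg <- unit_scoring()
  # no sleep outside the main period
  sc <- score_epochs(make_series(day_counts(21, 5.5)), cfg)
  main <- detect_main_sleep_period(sc, cfg)
  expect_equal(nrow(detect_naps(sc, main, cfg)), 0L)

  # one 40-min midday block -> one nap
  s2 <- make_series(day_counts(21, 5.5, extra = list(c(13, 13 + 40 / 60, 0))))
  sc2 <- score_epochs(s2, cfg)
  n2 <- detect_naps(sc2, detect_main_sleep_period(sc2, cfg), cfg)
  expect_equal(nrow(n2), 1L)
  expect_equal(n2$minutes, 40L)

  # runs of 25 and 15 min with a 20-min floor -> exactly one nap
  s3 <- make_series(day_counts(21, 5.5, extra = list(
    c(13, 13 + 25 / 60, 0), c(15, 15 + 15 / 60, 0))))
  sc3 <- score_epochs(s3, cfg)
  n3 <- detect_naps(sc3, detect_main_sleep_period(sc3, cfg), cfg)
  expect_equal(n3$minutes, 25L)
  q3 <- sleep_quotas(s3, cfg)
  expect_equal(q3$nap_h, 25 / 60)
  expect_equal(q3$ttst_h, q3$tst_h + 25 / 60)
})

test_that("noise-free synthetic nights reproduce the generator's truth exactly", {
  cc <- cohort_config(count_dispersion = Inf, sleep_count_rate = 0,
                      nap_probability = 0, tst_sd_h = 0)
  cc$cells$onset_sd_min <- 0
  cc$cells$end_sd_min <- 0
  # make the whole window sleep: target TST = onset-to-end span
  cc$cells$tst_mean_h <- (cc$cells$end_mean_h + 24) - cc$cells$onset_mean_h
  set.seed(3)
  s <- generate_participant_series(cc, "woman", "village", 3)
  q <- sleep_quotas(s, unit_scoring())
  tr <- attr(s, "truth")
  expect_equal(q$sleep_onset_h, tr$onset_h, tolerance = 1e-9)
  expect_equal(q$sleep_end_h, tr$end_h, tolerance = 1e-9)
  expect_equal(q$tst_h, tr$window_h, tolerance = 1e-9)
  expect_equal(q$waso_h, rep(0, 3))
})
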