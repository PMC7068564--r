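test_that("generators are pure functions of (params, seed)", {
  a <- gen_rr_series(seed = 12)
  b <- gen_rr_series(seed = 12)
  expect_identical(a$rr, b$rr)
  expect_identical(a$beat_time, b$beat_time)
  c <- gen_rr_series(seed = 13)
  expect_false(identical(a$rr, c$rr))

  la <- gen_exposure_log(60, seed = 4)
  lb <- gen_exposure_log(60, seed = 4)
  expect_identical(la$pm25, lb$pm25)
  expect_false(identical(la$pm25, gen_exposure_log(60, seed = 5)$pm25))

  s1 <- gen_study(n_participants = 2, n_days = 1, seed = 6)
  s2 <- gen_study(n_participants = 2, n_days = 1, seed = 6)
  expect_identical(s1$rr[[1]]$rr, s2$rr[[1]]$rr)
  expect_identical(s1$bouts, s2$bouts)
})

test_that("zero-modulation, zero-noise parameters give a flat tachogram", {
  s <- gen_rr_series(rr_gen_params(a_lf = 0, a_hf = 0, noise_sd = 0,
                                   duration_s = 600), seed = 1)
  expect_equal(unique(s$rr), 870)
  seg <- segment_rr(s)[[1]]
  expect_equal(time_domain_metrics(seg)$sdnn, 0)
})

test_that("an HF-only generator yields an HF-dominated spectrum downstream", {
  s <- gen_rr_series(rr_gen_params(a_lf = 0, a_hf = 50, noise_sd = 5,
                                   duration_s = 320), seed = 2)
  fd <- frequency_domain_metrics(segment_rr(s, min_beats = 50)[[1]])
  expect_lt(fd$lfhf, 0.1)
})

test_that("parameters implying non-positive RR are rejected", {
  expect_error(rr_gen_params(mean_rr = 400, a_lf = 200, a_hf = 150,
                             noise_sd = 40), "non-positive")
})

test_that("cleaning recovers at least 90% of inserted ectopics", {
  s <- gen_rr_series(rr_gen_params(duration_s = 2400, ectopy_rate = 0.02),
                     seed = 8)
  ect <- attr(s, "ectopic")
  expect_gt(length(ect), 20)
  cleaned <- clean_rr(s)
  # an inserted ectopic is recovered if its time stamp is gone
  surviving <- sum(s$beat_time[ect] %in% cleaned$beat_time)
  recall <- 1 - surviving / length(ect)
  expect_gte(recall, 0.9)
})

test_that("zero-SD exposure parameters give a constant log and exact dose", {
  log <- gen_exposure_log(120, pm25_sd = 0, pm10_sdlog = 0, noise_sd = 0,
                          ve_sd = 0, seed = 1)
  expect_equal(unique(log$pm25), 4.1)
  expect_equal(unique(log$ve), 40)
  expect_equal(as.numeric(cumulative_inhaled_dose(log, "pm25")),
               120 * 40 * 0.001 * 4.1)
})

test_that("default exposure logs give noise doses in the observed envelope", {
  doses <- vapply(1:100, function(seed) {
    log <- gen_exposure_log(180, seed = seed)
    noise_dose(log$laeq, 1 / 60, noise_dose_params(70, 24, 10))
  }, numeric(1))
  expect_true(all(doses >= 9 & doses <= 37))
})

test_that("study-level doses and deltas have realistic scales", {
  study <- default_study("study")
  expect_equal(nrow(study$bouts), 4 * 5 * 2)
  # bout doses within a plausible envelope of the emulated conditions
  expect_true(all(study$bouts$noise_dose > 5 & study$bouts$noise_dose < 60))
  expect_true(all(study$bouts$cum_pm25 > 0.5 & study$bouts$cum_pm25 < 150))
  expect_true(all(study$bouts$cum_pm25 <= study$bouts$cum_pm10))
})

test_that("a null-truth, low-noise study yields near-zero mean deltas", {
  zero <- setNames(rep(0, 7), velohrv:::OUTCOMES)
  truth <- study_truth(
    beta_pm25 = zero, conf_day = zero,
    sigma = setNames(c(0.5, 2, 1, 2, 30, 25, 0.2), velohrv:::OUTCOMES)
  )
  study <- gen_study(truth = truth, n_participants = 2, n_days = 2,
                     dropout = 0, seed = 17)
  rows <- study_analysis_rows(study)
  expect_lt(abs(mean(rows$d_hr)), 1)
})

test_that("injected effects are self-consistent at the delta scale", {
  # regenerating with the same truth reproduces the linear dose dependence:
  # the slope of d_hr on cum_pm25 is close to the injected 0.5 per ug
  rows <- default_study("rows")
  slope <- coef(lm(d_hr ~ cum_pm25 + day + factor(participant),
                   data = rows))[["cum_pm25"]]
  expect_gt(slope, 0.35)
  expect_lt(slope, 0.65)
})
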