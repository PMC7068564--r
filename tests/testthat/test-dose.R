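test_that("per-minute inhaled dose arithmetic", {
  expect_equal(inhaled_dose_minute(0, 10), 0)
  expect_equal(inhaled_dose_minute(20, 5), 0.1)
  expect_error(inhaled_dose_minute(-1, 5), class = "velohrv_domain_error")
})

test_that("cumulative dose sums minutes and matches the loop oracle", {
  log1 <- exposure_log(1, pm25 = 10, pm10 = 30, laeq = 70, ve = 10)
  expect_equal(as.numeric(cumulative_inhaled_dose(log1, "pm25")), 0.1)

  # constant 180-min bout: 180 * 20 * 0.001 * 8.9 = 32.04 ug
  logc <- exposure_log(1:180, pm25 = rep(8.9, 180), pm10 = rep(30, 180),
                       laeq = rep(70, 180), ve = rep(20, 180))
  expect_equal(as.numeric(cumulative_inhaled_dose(logc, "pm25")), 32.04)

  set.seed(5)
  log2 <- gen_exposure_log(180, seed = 5)
  expect_equal(as.numeric(cumulative_inhaled_dose(log2, "pm25")),
               brute_cumulative_dose(log2$ve, log2$pm25))

  # additivity over concatenated bouts
  a <- gen_exposure_log(60, seed = 1)
  b <- gen_exposure_log(90, seed = 2)
  both <- exposure_log(1:150, c(a$pm25, b$pm25), c(a$pm10, b$pm10),
                       c(a$laeq, b$laeq), c(a$ve, b$ve))
  expect_equal(as.numeric(cumulative_inhaled_dose(both, "pm25")),
               as.numeric(cumulative_inhaled_dose(a, "pm25")) +
                 as.numeric(cumulative_inhaled_dose(b, "pm25")))
})

test_that("missing minutes are skipped and reported", {
  log <- exposure_log(1:10, pm25 = c(rep(5, 9), NA), pm10 = rep(15, 10),
                      laeq = rep(70, 10), ve = rep(20, 10))
  d <- cumulative_inhaled_dose(log, "pm25")
  expect_equal(as.numeric(d), 9 * 20 * 0.001 * 5)
  expect_equal(attr(d, "coverage")[["minutes_skipped"]], 1)
})

test_that("noise dose reproduces the reference cases", {
  # 65 dB(A) for 3 h at the 53 dB(A)/24 h criterion, q = 10
  expect_equal(round(noise_dose(65, 3, noise_dose_params(53, 24, 10))), 198)
  # criterion level held for the criterion duration = 100 %
  expect_equal(noise_dose(70, 24, noise_dose_params(70, 24, 10)), 100)
  # 70 dB(A) for 3 h at its own cutoff: 100 * 3/24
  expect_equal(noise_dose(70, 3, noise_dose_params(70, 24, 10)), 12.5)
  # per-minute series equals the constant-level closed form
  expect_equal(noise_dose(rep(65, 180), 1 / 60, noise_dose_params(53, 24, 10)),
               noise_dose(65, 3, noise_dose_params(53, 24, 10)))
  expect_warning(d0 <- noise_dose(numeric(0)), "empty")
  expect_equal(d0, 0)
})

test_that("exchange-rate law and additivity hold exactly", {
  set.seed(8)
  laeq <- rnorm(180, 72, 2)
  p <- noise_dose_params(70, 24, 10)
  base <- noise_dose(laeq, 1 / 60, p)
  expect_equal(noise_dose(laeq + 10, 1 / 60, p), 10 * base)
  expect_equal(noise_dose(laeq + 3.0103, 1 / 60, p), 2 * base,
               tolerance = 1e-5)
  # additivity over any partition of the series
  cut <- 71
  expect_equal(noise_dose(laeq[1:cut], 1 / 60, p) +
                 noise_dose(laeq[(cut + 1):180], 1 / 60, p), base)
})

test_that("inhaled dose is linear in VE and concentration, PM2.5 <= PM10", {
  set.seed(9)
  log <- gen_exposure_log(120, seed = 9)
  d <- as.numeric(cumulative_inhaled_dose(log, "pm25"))
  log2 <- log
  log2$ve <- 3 * log2$ve
  expect_equal(as.numeric(cumulative_inhaled_dose(log2, "pm25")), 3 * d)
  log3 <- log
  log3$pm25 <- 5 * log3$pm25
  expect_equal(as.numeric(cumulative_inhaled_dose(log3, "pm25")), 5 * d)
  # minute-wise pm25 <= pm10 forces the cumulative ordering
  expect_true(all(log$pm25 <= log$pm10))
  expect_lte(d, as.numeric(cumulative_inhaled_dose(log, "pm10")))
})

test_that("threshold curve decreases in the cutoff with the forced ratio", {
  set.seed(10)
  laeq <- rnorm(180, 71.9, 1.2)
  curve <- dose_threshold_curve(laeq, cutoffs = c(53, 55, 65, 70, 75))
  expect_true(all(diff(curve$dose_pct) < 0))
  # dose(53) = dose(70) * 10^(17/10) exactly
  expect_equal(curve$dose_pct[curve$cutoff_dba == 53],
               curve$dose_pct[curve$cutoff_dba == 70] * 10^1.7)
  # constant 71.9 dB(A) for 3 h at the 70 cutoff: 12.5 * 10^0.19
  d <- dose_threshold_curve(71.9, cutoffs = 70, t_hours = 3)
  expect_equal(d$dose_pct, 12.5 * 10^0.19)
  expect_equal(d$dose_pct, 19.36, tolerance = 1e-3)
})
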