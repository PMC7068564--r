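mk_metrics <- function(participant = 1, day = 1, period = "AM",
                       rests = c("I", "II"), lags = 1:8, hr = 70,
                       jitter = 0) {
  rows <- expand.grid(rest = rests, lag = lags, stringsAsFactors = FALSE)
  tibble::tibble(
    participant = participant, day = day, period = period,
    rest = rows$rest, lag = rows$lag, valid = TRUE, n_beats = 300L,
    hr = hr + ifelse(rows$rest %in% c("II", "IV"), 6, 0) +
      jitter * rows$lag,
    sdnn = 50, pnn50 = 30, rmssd = 40, lf = 1000, hf = 500, lfhf = 2
  )
}

test_that("pairing uses post minus pre with the rest-label convention", {
  m <- mk_metrics()  # pre HR 70, post HR 76 at every lag
  d <- pair_rest_periods(m)
  expect_equal(nrow(d), 8)
  expect_true(all(d$d_hr == 6))
  expect_true(all(d$d_sdnn == 0))

  # PM pairs Rest IV minus Rest III
  m_pm <- mk_metrics(period = "PM", rests = c("III", "IV"))
  d_pm <- pair_rest_periods(m_pm)
  expect_true(all(d_pm$d_hr == 6))
})

test_that("identical pre and post give all-zero deltas", {
  m <- mk_metrics()
  m$hr <- 70  # override: no post shift
  d <- pair_rest_periods(m)
  expect_true(all(as.matrix(d[, c("d_hr", "d_sdnn", "d_pnn50", "d_rmssd",
                                  "d_lf", "d_hf", "d_lfhf")]) == 0))
})

test_that("unmatched lags are dropped and counted", {
  pre <- mk_metrics(rests = "I", lags = 1:8)
  post <- mk_metrics(rests = "II", lags = 1:6)
  d <- pair_rest_periods(dplyr::bind_rows(pre, post))
  expect_equal(nrow(d), 6)
  expect_equal(attr(d, "dropped"), 2)
})

test_that("swapping pre/post labels negates every delta exactly", {
  set.seed(21)
  m <- mk_metrics(jitter = 0.5)
  m$sdnn <- m$sdnn + rnorm(nrow(m), 0, 5)
  d <- pair_rest_periods(m)
  swapped <- m
  swapped$rest <- c(I = "II", II = "I")[m$rest]
  d2 <- pair_rest_periods(swapped)
  for (col in c("d_hr", "d_sdnn")) {
    expect_equal(d2[[col]], -d[[col]])
  }
})

test_that("doses join many-to-one: deleting a lag changes no dose value", {
  study <- gen_study(n_participants = 2, n_days = 1, dropout = 0, seed = 3)
  rows <- study_analysis_rows(study)
  rows_minus <- rows[-5, ]
  joined <- dplyr::distinct(rows_minus, .data$participant, .data$day,
                            .data$period, .data$cum_pm25, .data$noise_dose)
  full <- dplyr::distinct(rows, .data$participant, .data$day, .data$period,
                          .data$cum_pm25, .data$noise_dose)
  expect_equal(joined, full)
  # doses constant within a (participant, day, period) block
  per_block <- dplyr::summarise(
    dplyr::group_by(rows, .data$participant, .data$day, .data$period),
    n_pm = dplyr::n_distinct(.data$cum_pm25),
    n_nd = dplyr::n_distinct(.data$noise_dose), .groups = "drop"
  )
  expect_true(all(per_block$n_pm == 1) && all(per_block$n_nd == 1))
})

test_that("descriptive report uses linear-interpolation quantiles", {
  df <- data.frame(x = 1:100)
  rep1 <- descriptive_report(df, "x")
  expect_equal(rep1$p50, 50.5)
  expect_equal(rep1$iqr, rep1$p75 - rep1$p25)

  dfc <- data.frame(x = rep(7, 12))
  repc <- descriptive_report(dfc, "x")
  expect_equal(repc$sd, 0)
  expect_equal(repc$iqr, 0)
  expect_true(all(unlist(repc[c("min", "p25", "p50", "p75", "max")]) == 7))
})

test_that("correlation report handles exact and sampled correlations", {
  set.seed(30)
  x <- rnorm(200)
  df <- data.frame(a = x, b = -x, c = rnorm(200))
  cr <- correlation_report(df)
  expect_equal(cr$r["a", "a"], 1)
  expect_equal(cr$r["a", "b"], -1)
  expect_equal(cr$stars["a", "b"], "***")

  # bivariate normal with rho = 0.9: sample r close to 0.9 at n = 200
  z <- rnorm(200)
  y <- 0.9 * x[1:200] + sqrt(1 - 0.81) * z
  cr2 <- correlation_report(data.frame(x = x, y = y))
  expect_gt(cr2$r["x", "y"], 0.85)
  expect_lt(cr2$r["x", "y"], 0.94)

  dfz <- data.frame(a = rnorm(10), b = rep(1, 10))
  crz <- correlation_report(dfz)
  expect_true(is.na(crz$r["a", "b"]))
  expect_error(correlation_report(data.frame(a = 1:2, b = 2:1)), "3 complete")
})

test_that("analysis rows respect the design ceiling", {
  rows <- default_study("rows")
  expect_lte(nrow(rows), 4 * 5 * 2 * 8)
  expect_gte(nrow(rows), 280)   # 5% independent segment dropout
})
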