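tone_segment <- function(a_lf, a_hf, noise_sd = 0, seed = 1) {
  s <- gen_rr_series(
    rr_gen_params(a_lf = a_lf, a_hf = a_hf, noise_sd = noise_sd,
                  duration_s = 320),
    seed = seed
  )
  segment_rr(s, min_beats = 50)[[1]]
}

test_that("an HF-band tone concentrates power in the HF band", {
  seg <- tone_segment(a_lf = 0, a_hf = 50)
  fd <- frequency_domain_metrics(seg)
  expect_gt(fd$hf, fd$lf * 10)
  expect_lt(fd$lfhf, 0.1)
  # within 25% of the direct periodogram oracle on the same resampled signal
  ip <- velohrv:::interpolate_tachogram(seg$beat_time, seg$rr, 4)
  x <- velohrv:::detrend_linear(ip$x)
  oracle <- periodogram_band_power(x, 4, c(0.15, 0.40))
  expect_lt(abs(fd$hf / oracle - 1), 0.25)
})

test_that("an LF-band tone gives a large LF/HF ratio", {
  seg <- tone_segment(a_lf = 50, a_hf = 0)
  fd <- frequency_domain_metrics(seg)
  expect_gt(fd$lfhf, 10)
  ip <- velohrv:::interpolate_tachogram(seg$beat_time, seg$rr, 4)
  x <- velohrv:::detrend_linear(ip$x)
  oracle <- periodogram_band_power(x, 4, c(0.04, 0.15))
  expect_lt(abs(fd$lf / oracle - 1), 0.25)
})

test_that("a constant tachogram has (numerically) zero band power", {
  seg <- make_segment(rep(900, 340))
  fd <- frequency_domain_metrics(seg)
  expect_lt(fd$lf, 1e-6)
  expect_lt(fd$hf, 1e-6)
  expect_true(is.na(fd$lfhf))  # undefined, not infinite
})

test_that("band powers respect the Parseval budget", {
  for (seed in 1:5) {
    seg <- segment_rr(gen_rr_series(seed = seed), min_beats = 50)[[1]]
    ip <- velohrv:::interpolate_tachogram(seg$beat_time, seg$rr, 4)
    x <- velohrv:::detrend_linear(ip$x)
    ps <- welch_psd(x, 4, 512, 0.5)
    total <- sum(ps$psd[-1]) * (ps$freq[2] - ps$freq[1])
    fd <- frequency_domain_metrics(seg)
    expect_lte(fd$lf + fd$hf, total * (1 + 1e-9))
    expect_lt(abs(total / mean(x^2) - 1), 0.10)
  }
})

test_that("welch_psd recovers a pure sine's power", {
  fs <- 4
  t <- seq(0, 300, by = 1 / fs)
  x <- 30 * sin(2 * pi * 0.12 * t)
  ps <- welch_psd(x, fs)
  got <- sum(ps$psd[-1]) * (ps$freq[2] - ps$freq[1])
  expect_lt(abs(got / (30^2 / 2) - 1), 0.05)
})
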