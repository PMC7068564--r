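#' Spectral estimation parameters
#'
#' The RR tachogram (irregularly sampled in time) is cubic-spline
#' interpolated onto an even grid, linearly detrended, and its power
#' spectral density estimated by Welch's method (Hann-tapered segments,
#' 50 percent overlap). Band powers are integrated by the rectangle rule.
#'
#' @param interp_hz Resampling rate of the tachogram, Hz.
#' @param seg_len_s Welch segment length, seconds.
#' @param overlap Fractional overlap between Welch segments.
#' @param lf_band,hf_band Frequency bands, Hz; integrated as half-open
#'   intervals `[lo, hi)`.
#' @return A list of class `spectral_params`.
#' @export
spectral_params <- function(interp_hz = 4, seg_len_s = 128, overlap = 0.5,
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40)) {
  stopifnot(interp_hz > 0, seg_len_s > 0, overlap >= 0, overlap < 1,
            length(lf_band) == 2, length(hf_band) == 2)
  structure(
    list(interp_hz = interp_hz, seg_len_s = seg_len_s, overlap = overlap,
         lf_band = lf_band, hf_band = hf_band),
    class = "spectral_params"
  )
}

#' Welch power spectral density estimate
#'
#' One-sided PSD in units of `x`-squared per Hz. Segments of `seg_len`
#' samples with fractional `overlap` are Hann-tapered; segment periodograms
#' are normalised by `fs * sum(w^2)` and averaged. If the signal is shorter
#' than `seg_len`, a single full-length segment is used.
#'
#' @param x Evenly sampled numeric signal.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length, samples.
#' @param overlap Fractional overlap.
#' @return A list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = 512L, overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 8, fs > 0)
  L <- min(as.integer(seg_len), n)
  step <- max(1L, as.integer(floor(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  U <- sum(w^2)
  half <- floor(L / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    acc <- acc + P[seq_len(half)]
  }
  psd <- acc / length(starts)
  # one-sided: double the interior bins (not DC; not Nyquist when L even)
  interior <- 2:(half - 1L)
  if (L %% 2 == 1L) interior <- 2:half
  psd[interior] <- 2 * psd[interior]
  list(freq = (seq_len(half) - 1) * fs / L, psd = psd)
}

band_power <- function(freq, psd, band) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= band[1] & freq < band[2]]) * df
}

#' Frequency-domain HRV metrics for one 5-minute segment
#'
#' Interpolates the RR tachogram to an even grid (cubic spline at
#' `spec$interp_hz`), removes a linear trend, estimates the PSD by Welch's
#' method, and integrates the low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.40 Hz) bands, in ms-squared.
#'
#' @param segment A valid `rr_segment`.
#' @param spec A [spectral_params()] object.
#' @return A named list with `lf`, `hf` (ms^2) and `lfhf`; `lfhf` is `NA`
#'   when the HF power is below numerical floor (rather than infinity).
#' @export
frequency_domain_metrics <- function(segment, spec = spectral_params()) {
  stopifnot(inherits(segment, "rr_segment"), inherits(spec, "spectral_params"))
  if (!segment$valid) stop_insufficient_beats(segment)
  ip <- interpolate_tachogram(segment$beat_time, segment$rr, spec$interp_hz)
  x <- detrend_linear(ip$x)
  ps <- welch_psd(x, fs = spec$interp_hz,
                  seg_len = as.integer(round(spec$seg_len_s * spec$interp_hz)),
                  overlap = spec$overlap)
  lf <- band_power(ps$freq, ps$psd, spec$lf_band)
  hf <- band_power(ps$freq, ps$psd, spec$hf_band)
  list(lf = lf, hf = hf,
       lfhf = if (hf > 1e-12) lf / hf else NA_real_)
}

interpolate_tachogram <- function(beat_time, rr, fs) {
  grid <- seq(beat_time[1], beat_time[length(beat_time)], by = 1 / fs)
  x <- stats::spline(beat_time, rr, xout = grid, method = "fmm")$y
  list(t = grid, x = x)
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' All seven HRV metrics for one segment
#'
#' @inheritParams frequency_domain_metrics
#' @return A one-row [tibble::tibble()] with columns `hr`, `sdnn`, `pnn50`,
#'   `rmssd`, `lf`, `hf`, `lfhf`, `n_beats`.
#' @export
hrv_metrics <- function(segment, spec = spectral_params()) {
  td <- time_domain_metrics(segment)
  fd <- frequency_domain_metrics(segment, spec)
  tibble::tibble(
    hr = td$hr, sdnn = td$sdnn, pnn50 = td$pnn50, rmssd = td$rmssd,
    lf = fd$lf, hf = fd$hf, lfhf = fd$lfhf, n_beats = segment$n_beats
  )
}

#' HRV metrics table for one recording
#'
#' Cleans a recording, cuts it into repeated 5-minute segments, and computes
#' the seven ECG parameters per segment. Invalid segments (too few beats,
#' e.g. inside a gap) are kept as rows with `valid = FALSE` and `NA` metrics
#' so that exclusions stay auditable.
#'
#' @param series An [rr_series()] (raw; cleaning is applied here).
#' @param rules [cleaning_rules()].
#' @param spec [spectral_params()].
#' @inheritParams segment_rr
#' @return A tibble with one row per segment: metadata columns
#'   (`participant`, `day`, `period`, `rest`), `lag`, `valid`, `n_beats`,
#'   and the seven metric columns.
#' @export
compute_hrv_table <- function(series, rules = cleaning_rules(),
                              spec = spectral_params(), window_s = 300,
                              max_lags = 8L, min_beats = 100L) {
  cleaned <- clean_rr(series, rules)
  segs <- segment_rr(cleaned, window_s = window_s, max_lags = max_lags,
                     min_beats = min_beats)
  meta <- series$meta
  if (length(segs) == 0L) {
    return(tibble::tibble(
      participant = integer(), day = integer(), period = character(),
      rest = character(), lag = integer(), valid = logical(),
      n_beats = integer(), hr = numeric(), sdnn = numeric(),
      pnn50 = numeric(), rmssd = numeric(), lf = numeric(), hf = numeric(),
      lfhf = numeric()
    ))
  }
  rows <- lapply(segs, function(seg) {
    base <- tibble::tibble(
      participant = meta$participant, day = meta$day, period = meta$period,
      rest = meta$rest, lag = seg$lag, valid = seg$valid,
      n_beats = seg$n_beats
    )
    if (seg$valid) {
      dplyr::bind_cols(base, hrv_metrics(seg, spec)[, METRICS])
    } else {
      dplyr::bind_cols(base, tibble::as_tibble(
        stats::setNames(as.list(rep(NA_real_, length(METRICS))), METRICS)
      ))
    }
  })
  dplyr::bind_rows(rows)
}
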