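# Independent oracles used across the suite. These deliberately use naive
# loop-based formulations (or closed forms) so they stay independent of the
# package's vectorised implementations.

# time-domain metrics by explicit loops over beats
brute_time_domain <- function(rr) {
  n <- length(rr)
  s <- 0
  for (v in rr) s <- s + v
  m <- s / n
  ss <- 0
  for (v in rr) ss <- ss + (v - m)^2
  cnt50 <- 0
  ssd <- 0
  for (i in 2:n) {
    d <- rr[i] - rr[i - 1]
    if (abs(d) > 50) cnt50 <- cnt50 + 1
    ssd <- ssd + d^2
  }
  list(
    hr = 60000 / m,
    sdnn = sqrt(ss / (n - 1)),
    pnn50 = 100 * cnt50 / (n - 1),
    rmssd = sqrt(ssd / (n - 1))
  )
}

# loop summation of per-minute inhaled dose
brute_cumulative_dose <- function(ve, conc) {
  total <- 0
  for (i in seq_along(ve)) {
    if (is.finite(ve[i]) && is.finite(conc[i])) {
      total <- total + ve[i] * 0.001 * conc[i]
    }
  }
  total
}

# direct (single-window) periodogram band power of an evenly sampled signal
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / (fs * n)
  half <- floor(n / 2) + 1L
  P <- P[seq_len(half)]
  interior <- 2:(half - 1L)
  if (n %% 2 == 1L) interior <- 2:half
  P[interior] <- 2 * P[interior]
  freq <- (seq_len(half) - 1) * fs / n
  sum(P[freq >= band[1] & freq < band[2]]) * fs / n
}

# closed-form Savage-Dickey BF10 for the conjugate normal model:
# prior beta ~ N(0, tau^2), y_i | beta ~ N(beta, s^2) iid
conjugate_normal_posterior <- function(y, tau, s) {
  v <- 1 / (1 / tau^2 + length(y) / s^2)
  m <- v * sum(y) / s^2
  list(mean = m, var = v,
       bf10 = stats::dnorm(0, 0, tau) / stats::dnorm(0, m, sqrt(v)))
}

# random plausible RR segment for property tests
random_segment <- function(n = NULL) {
  if (is.null(n)) n <- sample(120:420, 1)
  rr <- stats::rnorm(n, mean = stats::runif(1, 600, 1100),
                     sd = stats::runif(1, 5, 80))
  rr <- pmax(rr, 300)
  make_segment(rr)
}

# wrap a plain RR vector as a valid rr_segment
make_segment <- function(rr, lag = 1L) {
  bt <- cumsum(rr) / 1000
  seg <- list(rr = rr, beat_time = bt, lag = lag,
              window = c(start = 0, end = ceiling(max(bt))),
              n_beats = length(rr), valid = TRUE,
              meta = list(participant = 1, day = 1, period = "AM",
                          rest = "I"))
  class(seg) <- "rr_segment"
  seg
}

# metrics + analysis table for an in-memory study (no disk round trip)
study_analysis_rows <- function(study) {
  metrics <- dplyr::bind_rows(lapply(study$rr, compute_hrv_table))
  deltas <- pair_rest_periods(metrics)
  assemble_analysis_table(deltas, study$bouts, study$bouts)
}

# cached default synthetic study shared by the heavier tests
default_study <- local({
  cache <- NULL
  rows <- NULL
  function(what = c("study", "rows")) {
    what <- match.arg(what)
    if (is.null(cache)) {
      cache <<- gen_study(seed = 20260101)
      rows <<- study_analysis_rows(cache)
    }
    if (what == "study") cache else rows
  }
})
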