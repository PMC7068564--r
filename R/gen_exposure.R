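#' Generate a synthetic per-minute exposure log
#'
#' Per-minute PM2.5 and minute ventilation are lognormal around their
#' means, the 1-minute A-weighted level is normal, and PM10 is a noisy
#' multiple of PM2.5 (which reproduces the near-unit PM2.5/PM10 correlation
#' seen in street-level monitoring). All series are truncated at physical
#' floors. Defaults take the exposure climate of a low-pollution city in
#' summer: PM2.5 around 4.1 ug/m^3 and noise around 71.9 dB(A) along
#' arterial cycling routes, with cycling-level ventilation near 40 L/min.
#'
#' A pure function of its parameters and `seed`.
#'
#' @param minutes Number of minutes in the bout.
#' @param pm25_mean,pm25_sd Mean and SD of per-minute PM2.5, ug/m^3.
#' @param pm10_ratio,pm10_sdlog PM10/PM2.5 ratio and lognormal jitter SD.
#' @param noise_mean,noise_sd Mean and SD of the per-minute level, dB(A).
#' @param ve_mean,ve_sd Mean and SD of minute ventilation, L/min.
#' @param seed Integer seed; if `NULL`, draws from the current RNG stream.
#' @inheritParams exposure_log
#' @return An [exposure_log()].
#' @export
gen_exposure_log <- function(minutes = 180,
                             pm25_mean = 4.1, pm25_sd = 1.2,
                             pm10_ratio = 3.34, pm10_sdlog = 0.05,
                             noise_mean = 71.9, noise_sd = 1.2,
                             ve_mean = 40, ve_sd = 6,
                             seed = NULL,
                             participant = NA, day = NA, period = NA) {
  stopifnot(minutes >= 1, pm25_mean > 0, ve_mean > 0)
  run <- function() {
    pm25 <- pmax(rlnorm_moments(minutes, pm25_mean, pm25_sd), 0.05)
    pm10 <- pm25 * pm10_ratio * exp(stats::rnorm(minutes, 0, pm10_sdlog))
    laeq <- pmax(stats::rnorm(minutes, noise_mean, noise_sd), 30)
    ve <- pmax(rlnorm_moments(minutes, ve_mean, ve_sd), 2)
    exposure_log(seq_len(minutes), pm25, pm10, laeq, ve,
                 participant = participant, day = day, period = period)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# lognormal draws parameterised by arithmetic mean and SD
rlnorm_moments <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
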