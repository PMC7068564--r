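#' Parameters of the synthetic RR-tachogram generator
#'
#' The generated tachogram is a two-tone-plus-noise process:
#' `rr_k = mean_rr + a_lf * sin(2 pi f_lf t_k) + a_hf * sin(2 pi f_hf t_k)
#' + noise`, with `t_k` the cumulative beat time, emulating the
#' low-frequency (baroreflex, 0.04-0.15 Hz) and high-frequency
#' (respiratory, 0.15-0.40 Hz) rhythms that the spectral metrics target.
#' Optional ectopic beats (halved RR) are inserted at a given rate.
#'
#' Defaults approximate a healthy young adult at seated rest: HR around
#' 69 bpm, SDNN around 50 ms, LF/HF around 2, pNN50 around 40 percent.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param a_lf,f_lf LF modulation amplitude (ms) and frequency (Hz, must
#'   lie in the 0.04-0.15 band).
#' @param a_hf,f_hf HF modulation amplitude (ms) and frequency (Hz, in
#'   0.15-0.40).
#' @param noise_sd Per-beat white-noise SD, ms.
#' @param duration_s Recording length, seconds (default 40 min).
#' @param ectopy_rate Per-beat probability of an ectopic (halved) interval.
#' @return A list of class `rr_gen_params`.
#' @export
rr_gen_params <- function(mean_rr = 870, a_lf = 50, f_lf = 0.10,
                          a_hf = 35, f_hf = 0.25, noise_sd = 30,
                          duration_s = 2400, ectopy_rate = 0) {
  stopifnot(a_lf >= 0, a_hf >= 0, noise_sd >= 0, duration_s > 0,
            ectopy_rate >= 0, ectopy_rate < 1,
            f_lf >= 0.04, f_lf < 0.15, f_hf >= 0.15, f_hf < 0.40)
  if (mean_rr - a_lf - a_hf - 5 * noise_sd <= 0) {
    stop("parameters admit non-positive RR intervals; reduce amplitudes/noise")
  }
  structure(
    list(mean_rr = mean_rr, a_lf = a_lf, f_lf = f_lf, a_hf = a_hf,
         f_hf = f_hf, noise_sd = noise_sd, duration_s = duration_s,
         ectopy_rate = ectopy_rate),
    class = "rr_gen_params"
  )
}

# Core beat loop. chunk_params: list with one rr_gen_params-like list per
# consecutive chunk of `chunk_s` seconds; the beat clock runs continuously
# across chunk boundaries. Returns beat_time, rr and the indices of
# inserted ectopics.
gen_rr_track <- function(chunk_params, chunk_s, total_s, ectopy_rate = 0) {
  n_guess <- as.integer(ceiling(total_s / 0.25))
  bt <- numeric(n_guess)
  rr <- numeric(n_guess)
  ect <- logical(n_guess)
  t <- 0
  k <- 0L
  n_chunks <- length(chunk_params)
  repeat {
    ci <- min(floor(t / chunk_s) + 1L, n_chunks)
    p <- chunk_params[[ci]]
    val <- p$mean_rr +
      p$a_lf * sin(2 * pi * p$f_lf * t) +
      p$a_hf * sin(2 * pi * p$f_hf * t) +
      stats::rnorm(1, 0, p$noise_sd)
    val <- max(val, 250)
    is_ect <- ectopy_rate > 0 && stats::runif(1) < ectopy_rate
    if (is_ect) val <- val / 2
    t_new <- t + val / 1000
    if (t_new > total_s) break
    k <- k + 1L
    bt[k] <- t_new
    rr[k] <- val
    ect[k] <- is_ect
    t <- t_new
  }
  list(beat_time = bt[seq_len(k)], rr = rr[seq_len(k)],
       ectopic = which(ect[seq_len(k)]))
}

#' Generate a synthetic RR-interval recording
#'
#' A pure function of `(params, seed)`: the same seed reproduces the series
#' bit-identically.
#'
#' @param params An [rr_gen_params()] object.
#' @param seed Integer seed; if `NULL`, draws from the current RNG stream.
#' @inheritParams rr_series
#' @return An [rr_series()]; the indices of inserted ectopic beats are
#'   available via the `ectopic` attribute.
#' @export
gen_rr_series <- function(params = rr_gen_params(), seed = NULL,
                          participant = NA, day = NA, period = NA,
                          rest = NA) {
  stopifnot(inherits(params, "rr_gen_params"))
  run <- function() {
    gen_rr_track(list(params), chunk_s = params$duration_s,
                 total_s = params$duration_s,
                 ectopy_rate = params$ectopy_rate)
  }
  trk <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- rr_series(trk$beat_time, trk$rr, participant = participant,
                   day = day, period = period, rest = rest)
  attr(out, "ectopic") <- trk$ectopic
  out
}
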