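#' Ground truth for a synthetic study
#'
#' Fully determines the distribution of the generated delta outcomes given
#' the study design: dose coefficients per outcome, per-participant
#' interaction offsets, confounder coefficients, the MA(1) innovation
#' coefficient, and per-outcome residual SDs.
#'
#' Default effects follow the order of magnitude reported for this kind of
#' panel (a 0.5 bpm heart-rate shift per ug of inhaled PM2.5, and a mild
#' daily fatigue drift), with all other effects null; residual SDs are set
#' so that the marginal spread of each delta outcome is realistic for
#' 5-minute rest windows.
#'
#' @param beta_pm25 Named vector over the seven outcomes: effect per ug of
#'   cumulative inhaled PM2.5.
#' @param beta_noise Named vector: effect per percentage point of noise
#'   dose.
#' @param inter_pm25,inter_noise 3 x 7 matrices (participants 2-4 by
#'   outcome): dose-by-participant interaction offsets added to the main
#'   dose slope.
#' @param conf_day,conf_period,conf_distance,conf_duration Named vectors of
#'   confounder effects (per day, for PM vs AM, per km, per hour).
#' @param theta MA(1) innovation coefficient of the injected lag noise.
#' @param sigma Named vector of per-lag innovation SDs, in each outcome's
#'   units.
#' @return A list of class `study_truth`.
#' @export
study_truth <- function(beta_pm25 = c(d_hr = 0.5, d_sdnn = 0, d_pnn50 = 0,
                                      d_rmssd = 0, d_lf = 0, d_hf = 0,
                                      d_lfhf = 0),
                        beta_noise = zero_outcomes(),
                        inter_pm25 = zero_interactions(),
                        inter_noise = zero_interactions(),
                        conf_day = c(d_hr = 0.5, d_sdnn = 0, d_pnn50 = 0,
                                     d_rmssd = 0, d_lf = 0, d_hf = 0,
                                     d_lfhf = 0),
                        conf_period = zero_outcomes(),
                        conf_distance = zero_outcomes(),
                        conf_duration = zero_outcomes(),
                        theta = 0.3,
                        sigma = c(d_hr = 6, d_sdnn = 25, d_pnn50 = 12,
                                  d_rmssd = 25, d_lf = 300, d_hf = 250,
                                  d_lfhf = 1.5)) {
  as_oc <- function(v) {
    out <- zero_outcomes()
    out[names(v)] <- v
    out
  }
  stopifnot(abs(theta) < 1, all(sigma >= 0),
            all(dim(inter_pm25) == c(3, 7)), all(dim(inter_noise) == c(3, 7)))
  colnames(inter_pm25) <- colnames(inter_noise) <- OUTCOMES
  structure(
    list(beta_pm25 = as_oc(beta_pm25), beta_noise = as_oc(beta_noise),
         inter_pm25 = inter_pm25, inter_noise = inter_noise,
         conf_day = as_oc(conf_day), conf_period = as_oc(conf_period),
         conf_distance = as_oc(conf_distance),
         conf_duration = as_oc(conf_duration),
         theta = theta, sigma = as_oc(sigma)),
    class = "study_truth"
  )
}

zero_outcomes <- function() {
  stats::setNames(rep(0, length(OUTCOMES)), OUTCOMES)
}

zero_interactions <- function() {
  matrix(0, nrow = 3, ncol = 7,
         dimnames = list(paste0("P", 2:4), OUTCOMES))
}

# Measure per-lag HR/SDNN/LF/HF of a recording (cleaned first, so the
# internal measurement matches what the analysis pipeline will see).
measure_recording <- function(series, spec, min_beats) {
  cleaned <- suppressWarnings(clean_rr(series))
  segs <- segment_rr(cleaned, min_beats = min_beats)
  out <- matrix(NA_real_, nrow = length(segs), ncol = 4,
                dimnames = list(NULL, c("hr", "sdnn", "lf", "hf")))
  for (i in seq_along(segs)) {
    if (!segs[[i]]$valid) next
    td <- time_domain_metrics(segs[[i]])
    fd <- frequency_domain_metrics(segs[[i]], spec)
    out[i, ] <- c(td$hr, td$sdnn, fd$lf, fd$hf)
  }
  out
}

# Invert metric targets (hr bpm, sdnn ms, lf/hf ms^2) to tachogram
# parameters for one 5-minute chunk. Accounts approximately for the share
# of broadband beat noise falling in each band.
invert_targets <- function(hr_t, sdnn_t, lf_t, hf_t, f_lf, f_hf) {
  hr_t <- min(max(hr_t, 35), 200)
  mean_rr <- 60000 / hr_t
  beat_nyq <- 1000 / mean_rr / 2
  w_lf <- min(0.11 / beat_nyq, 0.45)
  w_hf <- min(0.25 / beat_nyq, 0.45)
  lf_t <- max(lf_t, 4)
  hf_t <- max(hf_t, 4)
  sdnn_t <- max(sdnn_t, 5)
  noise_var <- (sdnn_t^2 - lf_t - hf_t) / max(1 - w_lf - w_hf, 0.2)
  noise_var <- min(max(noise_var, 25), (0.25 * mean_rr)^2)
  list(
    mean_rr = mean_rr,
    a_lf = sqrt(2 * max(lf_t - noise_var * w_lf, 2)),
    a_hf = sqrt(2 * max(hf_t - noise_var * w_hf, 2)),
    f_lf = f_lf, f_hf = f_hf,
    noise_sd = sqrt(noise_var)
  )
}

#' Generate a complete synthetic study
#'
#' Emulates the full design this package analyses: `n_participants`
#' participants cycling `n_days` days with AM and PM bouts, each bout
#' bracketed by a 40-minute pre-rest and post-rest RR recording (rest
#' labels I/II in the morning, III/IV in the afternoon) and accompanied by
#' a per-minute exposure log. Participants 3 and 4 wear a particle mask
#' (a covariate label only).
#'
#' Dose effects are injected at the delta-metric scale — the scale on which
#' the models operate. For each bout the pre-rest recording is generated
#' from jittered baseline parameters and measured; per-lag targets for the
#' post-rest metrics are then set to `pre + design x truth + MA(1) noise`
#' and inverted to tachogram parameters (mean RR for heart rate, sine
#' amplitudes for the band powers, beat-noise SD for SDNN) chunk by chunk.
#' pNN50 and rMSSD are emergent, not directly injected. Doses are computed
#' from the generated exposure logs, not drawn independently. Infeasible
#' targets (e.g. negative band power) are clipped and counted.
#'
#' An independent segment dropout (default 5 percent) blanks whole
#' 5-minute windows of the written recordings, emulating abnormal or
#' missing segments; downstream, those windows fail the minimum-beat check
#' and their lags drop out of the paired analysis table.
#'
#' @param truth A [study_truth()].
#' @param n_participants,n_days Design size (defaults 4 and 5).
#' @param baseline An [rr_gen_params()] for the pre-rest recordings.
#' @param dropout Independent per-segment dropout probability.
#' @param ectopy_rate Per-beat ectopic insertion rate in the written
#'   recordings.
#' @param seed Integer seed; the whole study is a pure function of
#'   (arguments, seed).
#' @param noise_params [noise_dose_params()] used for the generated doses.
#' @param spec [spectral_params()] used by the internal metric measurement.
#' @param min_beats Segment validity threshold used internally.
#' @param out_dir If non-`NULL`, the study is also written to disk:
#'   `manifest.csv`, `rr/*.csv`, `exposure/*.csv`.
#' @return A list of class `velohrv_study`: `manifest` (tibble: one row per
#'   rest recording with file keys and bout covariates), `bouts` (tibble:
#'   one row per bout with covariates and computed doses), `rr` (named list
#'   of [rr_series()]), `exposure` (named list of [exposure_log()]),
#'   `truth`, `seed`, `n_clipped` (infeasible metric targets clipped).
#' @export
gen_study <- function(truth = study_truth(), n_participants = 4L,
                      n_days = 5L, baseline = rr_gen_params(),
                      dropout = 0.05, ectopy_rate = 0, seed = 1L,
                      noise_params = noise_dose_params(),
                      spec = spectral_params(), min_beats = 100L,
                      out_dir = NULL) {
  stopifnot(inherits(truth, "study_truth"), n_participants >= 1,
            n_days >= 1, dropout >= 0, dropout < 1)
  study <- withr::with_seed(as.integer(seed), {
    build_study(truth, n_participants, n_days, baseline, dropout,
                ectopy_rate, noise_params, spec, min_beats)
  })
  study$seed <- as.integer(seed)
  class(study) <- "velohrv_study"
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

build_study <- function(truth, n_participants, n_days, baseline, dropout,
                        ectopy_rate, noise_params, spec, min_beats) {
  n_lags <- 8L
  window_s <- 300
  rr_list <- list()
  exp_list <- list()
  bout_rows <- list()
  manifest_rows <- list()
  n_clipped <- 0L

  for (pp in seq_len(n_participants)) {
    mask <- pp %in% c(3L, 4L)
    for (dd in seq_len(n_days)) {
      for (per in c("AM", "PM")) {
        key <- sprintf("P%d_D%d_%s", pp, dd, per)
        duration_h <- min(max(stats::rnorm(1, 3.0, 0.4), 2.2), 4.3)
        distance_km <- min(max(stats::rnorm(1, 41.7, 5.3), 28), 58)
        minutes <- as.integer(round(duration_h * 60))

        pm25_bout <- min(max(rlnorm_moments(1, 4.1, 2.1), 1.2), 16)
        noise_bout <- stats::rnorm(1, 71.9, 1.2)
        ve_bout <- min(max(stats::rnorm(1, 40, 5), 25), 55)

        log <- gen_exposure_log(
          minutes = minutes, pm25_mean = pm25_bout, pm25_sd = 0.3 * pm25_bout,
          noise_mean = noise_bout, noise_sd = 1.2,
          ve_mean = ve_bout, ve_sd = 6,
          participant = pp, day = dd, period = per
        )
        dose <- summarize_doses(log, noise_params)

        # deterministic part of the delta targets for this bout
        eff <- truth$beta_pm25 * dose$cum_pm25 +
          truth$beta_noise * dose$noise_dose +
          truth$conf_day * dd +
          truth$conf_period * (per == "PM") +
          truth$conf_distance * distance_km +
          truth$conf_duration * duration_h
        if (pp >= 2L && pp <= 4L) {
          eff <- eff + truth$inter_pm25[pp - 1L, ] * dose$cum_pm25 +
            truth$inter_noise[pp - 1L, ] * dose$noise_dose
        }

        # MA(1) lag noise, reset at each bout
        eta <- matrix(stats::rnorm(n_lags * 7), n_lags, 7) *
          rep(truth$sigma, each = n_lags)
        e <- eta + truth$theta * rbind(0, eta[-n_lags, , drop = FALSE])
        delta <- sweep(e, 2, eff, `+`)
        colnames(delta) <- OUTCOMES

        # pre-rest recording: jittered baseline per lag
        pre_chunks <- lapply(seq_len(n_lags), function(l) {
          list(mean_rr = baseline$mean_rr + stats::rnorm(1, 0, 10),
               a_lf = baseline$a_lf * exp(stats::rnorm(1, 0, 0.12)),
               f_lf = baseline$f_lf,
               a_hf = baseline$a_hf * exp(stats::rnorm(1, 0, 0.12)),
               f_hf = baseline$f_hf,
               noise_sd = baseline$noise_sd)
        })
        pre_trk <- gen_rr_track(pre_chunks, window_s, n_lags * window_s,
                                ectopy_rate)
        pre_rest <- if (per == "AM") "I" else "III"
        post_rest <- if (per == "AM") "II" else "IV"
        pre_series <- rr_series(pre_trk$beat_time, pre_trk$rr,
                                participant = pp, day = dd, period = per,
                                rest = pre_rest)

        pre_meas <- measure_recording(pre_series, spec, min_beats)

        # post-rest recording: invert per-lag metric targets
        post_chunks <- vector("list", n_lags)
        for (l in seq_len(n_lags)) {
          pm <- pre_meas[l, ]
          if (any(!is.finite(pm))) {
            pm <- c(hr = 60000 / baseline$mean_rr,
                    sdnn = sqrt(baseline$a_lf^2 / 2 + baseline$a_hf^2 / 2 +
                                  baseline$noise_sd^2),
                    lf = baseline$a_lf^2 / 2, hf = baseline$a_hf^2 / 2)
          }
          hr_t <- pm[["hr"]] + delta[l, "d_hr"]
          sdnn_t <- pm[["sdnn"]] + delta[l, "d_sdnn"]
          lf_t <- pm[["lf"]] + delta[l, "d_lf"]
          hf_t <- pm[["hf"]] + delta[l, "d_hf"]
          if (hr_t < 35 || hr_t > 200 || sdnn_t < 5 || lf_t < 4 || hf_t < 4) {
            n_clipped <- n_clipped + 1L
          }
          post_chunks[[l]] <- invert_targets(hr_t, sdnn_t, lf_t, hf_t,
                                             baseline$f_lf, baseline$f_hf)
        }
        post_trk <- gen_rr_track(post_chunks, window_s, n_lags * window_s,
                                 ectopy_rate)
        post_series <- rr_series(post_trk$beat_time, post_trk$rr,
                                 participant = pp, day = dd, period = per,
                                 rest = post_rest)

        # independent segment dropout
        pre_series <- drop_segments(pre_series, dropout, window_s, n_lags)
        post_series <- drop_segments(post_series, dropout, window_s, n_lags)

        rr_list[[paste0(key, "_", pre_rest)]] <- pre_series
        rr_list[[paste0(key, "_", post_rest)]] <- post_series
        exp_list[[key]] <- log

        bout_rows[[key]] <- tibble::tibble(
          participant = pp, day = dd, period = per,
          distance_km = distance_km, duration_h = duration_h, mask = mask,
          cum_pm25 = dose$cum_pm25, cum_pm10 = dose$cum_pm10,
          noise_dose = dose$noise_dose
        )
        for (rst in c(pre_rest, post_rest)) {
          manifest_rows[[paste0(key, "_", rst)]] <- tibble::tibble(
            participant = pp, day = dd, period = per, rest = rst,
            rr_file = file.path("rr", paste0(key, "_", rst, ".csv")),
            exposure_file = file.path("exposure", paste0(key, ".csv")),
            distance_km = distance_km, duration_h = duration_h, mask = mask
          )
        }
      }
    }
  }

  list(manifest = dplyr::bind_rows(manifest_rows),
       bouts = dplyr::bind_rows(bout_rows),
       rr = rr_list, exposure = exp_list, truth = truth,
       n_clipped = n_clipped)
}

# blank whole 5-minute windows with probability `dropout` each
drop_segments <- function(series, dropout, window_s, n_lags) {
  if (dropout <= 0) return(series)
  dropped <- which(stats::runif(n_lags) < dropout)
  if (length(dropped) == 0L) return(series)
  keep <- rep(TRUE, length(series$rr))
  for (l in dropped) {
    keep <- keep & !(series$beat_time >= (l - 1) * window_s &
                       series$beat_time < l * window_s)
  }
  if (!any(keep)) return(series)  # never blank an entire recording
  out <- rr_series(series$beat_time[keep], series$rr[keep],
                   participant = series$meta$participant,
                   day = series$meta$day, period = series$meta$period,
                   rest = series$meta$rest)
  attr(out, "dropped_lags") <- dropped
  out
}

#' @export
print.velohrv_study <- function(x, ...) {
  cat(sprintf(
    "<velohrv_study> %d participants x %d days x 2 periods (seed %d)\n",
    length(unique(x$bouts$participant)), length(unique(x$bouts$day)),
    x$seed
  ))
  cat(sprintf("  %d recordings, %d exposure logs, %d clipped targets\n",
              length(x$rr), length(x$exposure), x$n_clipped))
  invisible(x)
}

# Write a study to disk as manifest.csv + rr/ + exposure/ CSV files.
write_study <- function(study, out_dir) {
  dir.create(file.path(out_dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "exposure"), recursive = TRUE,
             showWarnings = FALSE)
  for (nm in names(study$rr)) {
    write_rr_csv(study$rr[[nm]], file.path(out_dir, "rr",
                                           paste0(nm, ".csv")))
  }
  for (nm in names(study$exposure)) {
    write_exposure_csv(study$exposure[[nm]],
                       file.path(out_dir, "exposure", paste0(nm, ".csv")))
  }
  utils::write.csv(study$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Read a study manifest written by [gen_study()]
#'
#' @param study_dir Directory containing `manifest.csv`, `rr/`, `exposure/`.
#' @return The manifest tibble with `rr_file`/`exposure_file` resolved to
#'   absolute paths.
#' @export
read_study_manifest <- function(study_dir) {
  man <- tibble::as_tibble(
    utils::read.csv(file.path(study_dir, "manifest.csv"),
                    comment.char = "#", stringsAsFactors = FALSE)
  )
  man$rr_file <- file.path(study_dir, man$rr_file)
  man$exposure_file <- file.path(study_dir, man$exposure_file)
  man$mask <- as.logical(man$mask)
  man
}
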