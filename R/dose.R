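#' Per-minute inhaled particulate dose
#'
#' Mass of pollutant inhaled in one minute: minute ventilation (L/min,
#' converted to m^3/min by the 0.001 factor) times the minute-average
#' concentration (ug/m^3), giving ug.
#'
#' @param ve Minute ventilation, L/min (vectorised).
#' @param conc Concentration, ug/m^3 (vectorised).
#' @return Inhaled mass, ug.
#' @export
inhaled_dose_minute <- function(ve, conc) {
  if (any(is.finite(ve) & ve < 0) || any(is.finite(conc) & conc < 0)) {
    stop(errorCondition(
      "ventilation and concentration must be non-negative",
      class = c("velohrv_domain_error", "error")
    ))
  }
  ve * 0.001 * conc
}

#' Per-minute exposure log for one cycling bout
#'
#' @param minute Integer minute index, contiguous from 1 within a bout;
#'   gaps are tolerated but flagged via the `gaps` attribute.
#' @param pm25,pm10 Minute-average concentrations, ug/m^3.
#' @param laeq A-weighted 1-minute equivalent level, dB(A).
#' @param ve Minute ventilation, L/min.
#' @param participant,day,period Bout metadata.
#' @return A tibble of class `exposure_log`.
#' @export
exposure_log <- function(minute, pm25, pm10, laeq, ve,
                         participant = NA, day = NA, period = NA) {
  stopifnot(length(minute) >= 1)
  n <- length(minute)
  stopifnot(length(pm25) == n, length(pm10) == n, length(laeq) == n,
            length(ve) == n)
  if (any(is.finite(pm25) & pm25 < 0) || any(is.finite(pm10) & pm10 < 0) ||
      any(is.finite(ve) & ve < 0)) {
    stop("concentrations and ventilation must be non-negative")
  }
  out <- tibble::tibble(
    minute = as.integer(minute), pm25 = pm25, pm10 = pm10,
    laeq = laeq, ve = ve,
    participant = participant, day = day, period = period
  )
  gaps <- setdiff(seq(min(out$minute), max(out$minute)), out$minute)
  attr(out, "gaps") <- gaps
  class(out) <- c("exposure_log", class(out))
  out
}

#' Read a per-minute exposure log from CSV
#'
#' Expects columns `minute, pm25_ugm3, pm10_ugm3, laeq_dba, ve_lmin`.
#'
#' @param path Path to the CSV file.
#' @inheritParams exposure_log
#' @return An [exposure_log()].
#' @export
read_exposure_csv <- function(path, participant = NA, day = NA, period = NA) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("minute", "pm25_ugm3", "pm10_ugm3", "laeq_dba", "ve_lmin")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' must contain columns %s", path,
                 paste(need, collapse = ", ")))
  }
  exposure_log(df$minute, df$pm25_ugm3, df$pm10_ugm3, df$laeq_dba,
               df$ve_lmin, participant = participant, day = day,
               period = period)
}

#' Write a per-minute exposure log to CSV
#' @param log An [exposure_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(log, path) {
  df <- data.frame(minute = log$minute, pm25_ugm3 = log$pm25,
                   pm10_ugm3 = log$pm10, laeq_dba = log$laeq,
                   ve_lmin = log$ve)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative inhaled dose over a bout
#'
#' Sums [inhaled_dose_minute()] over all minutes of the bout. Minutes with a
#' missing ventilation or concentration value are skipped (the dose then
#' underestimates) and counted in the `coverage` attribute.
#'
#' @param log An [exposure_log()].
#' @param pollutant `"pm25"` or `"pm10"`.
#' @return Cumulative inhaled mass, ug, with attribute `coverage` listing
#'   `minutes_used` and `minutes_skipped`.
#' @export
cumulative_inhaled_dose <- function(log, pollutant = c("pm25", "pm10")) {
  pollutant <- match.arg(pollutant)
  conc <- log[[pollutant]]
  ok <- is.finite(conc) & is.finite(log$ve)
  dose <- sum(inhaled_dose_minute(log$ve[ok], conc[ok]))
  attr(dose, "coverage") <- c(minutes_used = sum(ok),
                              minutes_skipped = sum(!ok))
  dose
}

#' Noise-dose parameters (criterion level, duration, exchange parameter)
#'
#' Defaults adopt a 70 dB(A) criterion over 24 h with exchange parameter
#' q = 10 (a 3 dB exchange rate): the dose doubles for each ~3 dB increase
#' in level, and multiplies by 10 for each q dB.
#'
#' @param lc Criterion sound level, dB(A).
#' @param tc Criterion duration, hours.
#' @param q Exchange parameter, dB.
#' @return A list of class `noise_dose_params`.
#' @export
noise_dose_params <- function(lc = 70, tc = 24, q = 10) {
  stopifnot(tc > 0, q > 0)
  structure(list(lc = lc, tc = tc, q = q), class = "noise_dose_params")
}

#' Cumulative percentage noise dose
#'
#' The classical percentage dose
#' `D = 100 * sum_i (T_i / T_c) * 10^((L_i - L_c) / q)`,
#' where each interval i contributes its duration `T_i` (hours) at level
#' `L_i` dB(A). A constant level held at the criterion `L_c` for the full
#' criterion duration `T_c` gives exactly 100 percent.
#'
#' @param laeq Vector of interval levels, dB(A) (e.g. the per-minute
#'   L_Aeq,1min series of a bout, or a single average level).
#' @param t_hours Interval durations in hours: a scalar applied to every
#'   interval (default 1/60, one minute) or a vector matching `laeq`.
#' @param params A [noise_dose_params()].
#' @return Dose in percent. An empty `laeq` gives 0 with a warning.
#' @export
noise_dose <- function(laeq, t_hours = 1 / 60, params = noise_dose_params()) {
  stopifnot(inherits(params, "noise_dose_params"))
  laeq <- laeq[is.finite(laeq)]
  if (length(laeq) == 0L) {
    warning("empty level series: noise dose is 0")
    return(0)
  }
  if (length(t_hours) == 1L) t_hours <- rep(t_hours, length(laeq))
  stopifnot(length(t_hours) == length(laeq), all(t_hours >= 0))
  100 * sum(t_hours / params$tc * 10^((laeq - params$lc) / params$q))
}

#' Noise dose as a function of the criterion-level cutoff
#'
#' Evaluates [noise_dose()] for each candidate cutoff, holding duration and
#' exchange parameters fixed — the cutoff-sensitivity curve used to choose a
#' criterion level.
#'
#' @inheritParams noise_dose
#' @param cutoffs Candidate criterion levels, dB(A).
#' @param tc,q Criterion duration (h) and exchange parameter (dB).
#' @return A tibble with columns `cutoff_dba` and `dose_pct`, one row per
#'   cutoff; strictly decreasing in the cutoff for any non-empty series.
#' @export
dose_threshold_curve <- function(laeq, cutoffs = c(53, 55, 65, 70, 75),
                                 t_hours = 1 / 60, tc = 24, q = 10) {
  stopifnot(length(cutoffs) >= 1)
  dose <- vapply(cutoffs, function(lc) {
    suppressWarnings(noise_dose(laeq, t_hours, noise_dose_params(lc, tc, q)))
  }, numeric(1))
  tibble::tibble(cutoff_dba = cutoffs, dose_pct = dose)
}

#' Dose summary for one cycling bout
#'
#' @param log An [exposure_log()].
#' @param params A [noise_dose_params()].
#' @return A one-row tibble: bout metadata, `cum_pm25`, `cum_pm10` (ug),
#'   `noise_dose` (percent), `minutes`, `exposure_h`, and the noise
#'   parameters used.
#' @export
summarize_doses <- function(log, params = noise_dose_params()) {
  ok_noise <- is.finite(log$laeq)
  tibble::tibble(
    participant = log$participant[1], day = log$day[1], period = log$period[1],
    cum_pm25 = as.numeric(cumulative_inhaled_dose(log, "pm25")),
    cum_pm10 = as.numeric(cumulative_inhaled_dose(log, "pm10")),
    noise_dose = noise_dose(log$laeq[ok_noise], 1 / 60, params),
    minutes = nrow(log),
    exposure_h = sum(ok_noise) / 60,
    lc = params$lc, tc = params$tc, q = params$q
  )
}
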