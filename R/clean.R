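#' Cleaning parameters for RR-interval recordings
#'
#' Two rules are applied, in order. A physiological range filter keeps beats
#' whose instantaneous heart rate lies in `[hr_min, hr_max]` bpm, i.e. RR in
#' `[60000/hr_max, 60000/hr_min]` ms; the defaults 30-220 bpm are the
#' recording device's stated detection range. A running-median ectopy filter
#' then removes beats deviating from the local median (window of
#' `ectopy_window` beats) by more than a fraction `ectopy_frac`; it is
#' iterated to a fixed point so that cleaning is idempotent.
#'
#' @param hr_min,hr_max Admissible instantaneous heart rate, bpm.
#' @param ectopy_window Running-median window, beats (odd).
#' @param ectopy_frac Maximal tolerated relative deviation from the running
#'   median (0.2 = 20 percent).
#' @param max_passes Safety cap on ectopy-filter iterations.
#' @return A list of class `cleaning_rules`.
#' @export
cleaning_rules <- function(hr_min = 30, hr_max = 220,
                           ectopy_window = 11, ectopy_frac = 0.2,
                           max_passes = 20L) {
  stopifnot(hr_min > 0, hr_max > hr_min,
            ectopy_window >= 3, ectopy_window %% 2 == 1,
            ectopy_frac > 0)
  structure(
    list(rr_min = 60000 / hr_max, rr_max = 60000 / hr_min,
         ectopy_window = as.integer(ectopy_window),
         ectopy_frac = ectopy_frac, max_passes = as.integer(max_passes)),
    class = "cleaning_rules"
  )
}

#' Clean an RR-interval recording
#'
#' Removes beats outside the physiological RR range and beats flagged by the
#' running-median ectopy filter (see [cleaning_rules()]). Removed beats leave
#' gaps: surviving beats keep their original time stamps, so downstream
#' window assignment is unaffected.
#'
#' @param series An [rr_series()].
#' @param rules A [cleaning_rules()] object.
#' @return The cleaned [rr_series()], with a `rejections` attribute: a
#'   data frame counting removals per rule, plus a `passes` attribute giving
#'   the number of ectopy-filter iterations run.
#'
#'   If every beat is removed, an error condition of class
#'   `velohrv_empty_after_cleaning` is signalled; its `report` field carries
#'   the rejection counts.
#' @export
clean_rr <- function(series, rules = cleaning_rules()) {
  stopifnot(inherits(series, "rr_series"), inherits(rules, "cleaning_rules"))
  bt <- series$beat_time
  rr <- series$rr

  in_range <- rr >= rules$rr_min & rr <= rules$rr_max
  n_range <- sum(!in_range)
  bt <- bt[in_range]
  rr <- rr[in_range]

  n_ectopy <- 0L
  passes <- 0L
  while (length(rr) >= 3L && passes < rules$max_passes) {
    k <- min(rules$ectopy_window, length(rr) - (length(rr) + 1L) %% 2L)
    med <- stats::runmed(rr, k = k, endrule = "median")
    bad <- abs(rr - med) / med > rules$ectopy_frac
    passes <- passes + 1L
    if (!any(bad)) break
    n_ectopy <- n_ectopy + sum(bad)
    bt <- bt[!bad]
    rr <- rr[!bad]
  }

  report <- data.frame(
    rule = c("range", "ectopy"),
    removed = c(n_range, n_ectopy)
  )
  if (length(rr) == 0L) {
    stop(errorCondition(
      "all beats were removed during cleaning",
      class = c("velohrv_empty_after_cleaning", "error"),
      report = report
    ))
  }
  out <- rr_series(bt, rr,
                   participant = series$meta$participant,
                   day = series$meta$day,
                   period = series$meta$period,
                   rest = series$meta$rest)
  attr(out, "rejections") <- report
  attr(out, "passes") <- passes
  out
}
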