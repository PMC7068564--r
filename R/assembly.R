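#' Pair pre/post rest periods into delta outcomes
#'
#' For each (participant, day, period, lag), forms the post-minus-pre
#' difference of the seven ECG parameters: Rest II minus Rest I in the
#' morning, Rest IV minus Rest III in the afternoon. Lags present in only
#' one member of a pair (or invalid in either) are dropped and counted.
#'
#' @param metrics A metrics table as produced by [compute_hrv_table()]
#'   (rows for all rests), with rest labels `"I"`-`"IV"`.
#' @return A tibble with one row per paired lag: `participant`, `day`,
#'   `period`, `lag`, and `d_hr`, `d_sdnn`, `d_pnn50`, `d_rmssd`, `d_lf`,
#'   `d_hf`, `d_lfhf`. Attribute `dropped` counts unmatched lags per
#'   (participant, day, period).
#' @export
pair_rest_periods <- function(metrics) {
  stopifnot(all(c("participant", "day", "period", "rest", "lag", "valid",
                  METRICS) %in% names(metrics)))
  pre_label <- c(AM = "I", PM = "III")
  post_label <- c(AM = "II", PM = "IV")

  usable <- dplyr::filter(metrics, .data$valid)
  pre <- dplyr::filter(usable, .data$rest == pre_label[.data$period])
  post <- dplyr::filter(usable, .data$rest == post_label[.data$period])

  keys <- c("participant", "day", "period", "lag")
  paired <- dplyr::inner_join(
    dplyr::select(pre, dplyr::all_of(c(keys, METRICS))),
    dplyr::select(post, dplyr::all_of(c(keys, METRICS))),
    by = keys, suffix = c("_pre", "_post")
  )
  out <- dplyr::select(paired, dplyr::all_of(keys))
  for (m in METRICS) {
    out[[paste0("d_", sub("^lfhf$", "lfhf", m))]] <-
      paired[[paste0(m, "_post")]] - paired[[paste0(m, "_pre")]]
  }
  names(out)[5:11] <- OUTCOMES
  out <- dplyr::arrange(out, .data$participant, .data$day, .data$period,
                        .data$lag)

  n_candidates <- dplyr::bind_rows(pre, post) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    nrow()
  attr(out, "dropped") <- n_candidates - nrow(out)
  out
}

#' Join delta outcomes with doses and confounders
#'
#' Doses and bout covariates are constant within a (participant, day,
#' period) block and join many-to-one onto the per-lag delta rows.
#'
#' @param deltas Output of [pair_rest_periods()].
#' @param doses A tibble keyed by (participant, day, period) with at least
#'   `cum_pm25`, `cum_pm10`, `noise_dose`.
#' @param bouts A tibble keyed by (participant, day, period) with
#'   `distance_km`, `duration_h`, `mask`.
#' @return The model-ready analysis table: one row per delta observation
#'   with dose and confounder columns appended.
#' @export
assemble_analysis_table <- function(deltas, doses, bouts) {
  keys <- c("participant", "day", "period")
  out <- deltas |>
    dplyr::inner_join(
      dplyr::select(doses, dplyr::all_of(c(keys, "cum_pm25", "cum_pm10",
                                           "noise_dose"))),
      by = keys
    ) |>
    dplyr::inner_join(
      dplyr::select(bouts, dplyr::all_of(c(keys, "distance_km", "duration_h",
                                           "mask"))),
      by = keys
    ) |>
    dplyr::arrange(.data$participant, .data$day, .data$period, .data$lag)
  out
}
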