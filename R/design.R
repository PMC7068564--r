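#' Model specification for one delta outcome
#'
#' @param outcome One of the seven delta-outcome columns (`"d_hr"`,
#'   `"d_sdnn"`, `"d_pnn50"`, `"d_rmssd"`, `"d_lf"`, `"d_hf"`, `"d_lfhf"`).
#' @param doses Dose predictors, a subset of `c("cum_pm25", "noise_dose")`
#'   (PM10 is assembled and reported but excluded from default model
#'   formulas because of its near-unit correlation with PM2.5; pass
#'   `"cum_pm10"` explicitly to re-enable it).
#' @param interactions If `TRUE`, include dose-by-participant interaction
#'   columns (participant 1 is the reference level).
#' @param confounders Confounder columns passed through as fixed effects.
#'   The number of repeated 5-minute windows (the lag) is not a column: it
#'   enters the model as the MA(1) residual autocorrelation over successive
#'   lags within a block.
#' @param ma_order Residual moving-average order (only 0 and 1 supported).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome,
                       doses = "cum_pm25",
                       interactions = TRUE,
                       confounders = c("day", "period", "distance_km",
                                       "duration_h"),
                       ma_order = 1L) {
  outcome <- match.arg(outcome, OUTCOMES)
  stopifnot(length(doses) >= 0,
            all(doses %in% c("cum_pm25", "noise_dose", "cum_pm10")),
            ma_order %in% c(0L, 1L))
  structure(
    list(outcome = outcome, doses = doses,
         interactions = isTRUE(interactions),
         confounders = confounders, ma_order = as.integer(ma_order)),
    class = "model_spec"
  )
}

#' Build the response and design matrix for one model
#'
#' Rows are sorted canonically by (participant, day, period, lag) so that
#' the MA(1) term applies to successive lags within one (participant, day,
#' period) block. Period and participant are dummy-coded with AM and
#' participant 1 as reference; each dose gets one interaction column per
#' non-reference participant. Continuous covariates are passed through in
#' their original units (centering and scaling happen inside the fitter and
#' are undone in reporting).
#'
#' @param rows The analysis table from [assemble_analysis_table()].
#' @param spec A [model_spec()].
#' @return A list with `y` (response), `X` (design matrix with named
#'   columns), `blocks` (integer block index per row), `focal` (names of the
#'   dose and interaction columns), `spec`, and `n_dropped` (rows lost to
#'   missing values).
#' @export
build_design <- function(rows, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- unique(c("participant", "day", "period", "lag", spec$outcome,
                   spec$doses, setdiff(spec$confounders, "period")))
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols) > 0) {
    stop("analysis table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- dplyr::arrange(rows, .data$participant, .data$day, .data$period,
                         .data$lag)
  ok <- stats::complete.cases(rows[need])
  n_dropped <- sum(!ok)
  rows <- rows[ok, , drop = FALSE]
  stopifnot(nrow(rows) > 0)

  y <- rows[[spec$outcome]]
  cols <- list(`(Intercept)` = rep(1, nrow(rows)))
  for (d in spec$doses) cols[[d]] <- as.numeric(rows[[d]])

  if ("day" %in% spec$confounders) cols[["day"]] <- as.numeric(rows$day)
  if ("period" %in% spec$confounders) {
    cols[["periodPM"]] <- as.numeric(rows$period == "PM")
  }
  for (v in setdiff(spec$confounders, c("day", "period"))) {
    cols[[v]] <- as.numeric(rows[[v]])
  }

  participants <- sort(unique(rows$participant))
  ref <- participants[1]
  for (pp in setdiff(participants, ref)) {
    cols[[paste0("P", pp)]] <- as.numeric(rows$participant == pp)
  }

  focal <- spec$doses
  if (spec$interactions && length(participants) > 1) {
    for (d in spec$doses) {
      for (pp in setdiff(participants, ref)) {
        nm <- paste0(d, ":P", pp)
        cols[[nm]] <- as.numeric(rows[[d]]) * as.numeric(rows$participant == pp)
        focal <- c(focal, nm)
      }
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (nrow(X) <= ncol(X)) {
    stop("fewer rows than design columns: the model is not identifiable")
  }
  blocks <- as.integer(factor(
    paste(rows$participant, rows$day, rows$period, sep = "\r"),
    levels = unique(paste(rows$participant, rows$day, rows$period,
                          sep = "\r"))
  ))
  list(y = y, X = X, blocks = blocks, focal = focal, spec = spec,
       n_dropped = n_dropped)
}
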