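#' Fit one model suite across the seven delta outcomes
#'
#' Three suites are supported: `"pm25"` (PM2.5 dose and its participant
#' interactions), `"noise"` (noise dose and interactions), and `"joint"`
#' (both doses and both interaction sets).
#'
#' @param rows The analysis table from [assemble_analysis_table()].
#' @param suite `"pm25"`, `"noise"` or `"joint"`.
#' @param config A [sampler_config()]; each fit derives its chain seeds
#'   from `config$seed` offset by the outcome index, so the whole suite is
#'   reproducible from a single seed.
#' @param outcomes Outcomes to fit (default all seven).
#' @return A list of class `velohrv_suite`: `report` (tidy tibble with
#'   columns suite, outcome, term, estimate, ci_low, ci_high, bf10, rhat,
#'   ess, restricted to the focal dose and interaction terms) and `fits`
#'   (named list of full [fit_bayesian_lm()] objects).
#' @export
run_model_suite <- function(rows, suite = c("pm25", "noise", "joint"),
                            config = sampler_config(),
                            outcomes = OUTCOMES) {
  suite <- match.arg(suite)
  doses <- switch(suite,
    pm25 = "cum_pm25",
    noise = "noise_dose",
    joint = c("cum_pm25", "noise_dose")
  )
  fits <- list()
  reports <- list()
  for (i in seq_along(outcomes)) {
    oc <- outcomes[i]
    spec <- model_spec(oc, doses = doses)
    des <- build_design(rows, spec)
    cfg <- config
    cfg$seed <- config$seed + 101L * i
    fit <- fit_bayesian_lm(des$y, des$X, des$blocks, cfg)
    fits[[oc]] <- fit
    rep_i <- dplyr::filter(fit$summary, .data$term %in% des$focal)
    rep_i <- dplyr::mutate(rep_i, suite = suite, outcome = oc,
                           .before = 1)
    reports[[oc]] <- rep_i
  }
  structure(list(report = dplyr::bind_rows(reports), fits = fits,
                 suite = suite),
            class = "velohrv_suite")
}

#' @export
print.velohrv_suite <- function(x, digits = 3, ...) {
  cat(sprintf("<velohrv_suite> '%s': %d outcomes\n", x$suite,
              length(x$fits)))
  df <- as.data.frame(lapply(x$report, function(col) {
    if (is.numeric(col)) signif(col, digits) else col
  }))
  print(df, row.names = FALSE)
  invisible(x)
}
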