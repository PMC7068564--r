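#' Savage-Dickey density-ratio Bayes factor
#'
#' For a point null at zero nested in a model with a proper prior on the
#' focal coefficient, the Bayes factor in favour of a nonzero effect is the
#' ratio of prior to posterior density at zero:
#' `BF10 = p_prior(0) / p_posterior(0)`. The posterior density at zero is
#' estimated by a Gaussian kernel on the draws with Silverman's bandwidth
#' ([stats::bw.nrd0()]). `BF10 > 1` favours the presence of the effect.
#'
#' @param prior_density_0 Prior density evaluated at zero (must be finite
#'   and positive; the prior must be proper).
#' @param draws Posterior draws of the coefficient.
#' @param floor Numerical floor for the posterior density at zero; below it
#'   the Bayes factor is capped and flagged via the `capped` attribute.
#' @return `BF10`, with attributes `posterior_density_0` and `capped`.
#' @export
savage_dickey_bf <- function(prior_density_0, draws, floor = 1e-10) {
  stopifnot(is.finite(prior_density_0), prior_density_0 > 0,
            length(draws) >= 10)
  bw <- stats::bw.nrd0(draws)
  if (!is.finite(bw) || bw <= 0) bw <- max(abs(draws), 1e-8) * 1e-3
  post0 <- mean(stats::dnorm(0, mean = draws, sd = bw))
  capped <- post0 < floor
  bf <- prior_density_0 / max(post0, floor)
  attr(bf, "posterior_density_0") <- post0
  attr(bf, "capped") <- capped
  bf
}
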