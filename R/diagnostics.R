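# Convergence diagnostics on a list of per-chain draw vectors.

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the standard between/within variance
#' ratio computed over the resulting 2m half-chains.
#'
#' @param chains A list of numeric vectors (one per chain, equal length).
#' @return The split R-hat (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x)
    h <- n %/% 2
    list(x[seq_len(h)], x[(n - h + 1):n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Geyer-style initial positive sequence estimate: pairwise sums of
#' autocorrelations (averaged over chains) are accumulated until the first
#' negative pair.
#'
#' @inheritParams split_rhat
#' @return Estimated effective number of draws.
#' @export
ess_draws <- function(chains) {
  n <- length(chains[[1]])
  m <- length(chains)
  max_lag <- min(n - 2L, 500L)
  acfs <- vapply(chains, function(x) {
    if (stats::var(x) < .Machine$double.eps) return(rep(0, max_lag + 1))
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  }, numeric(max_lag + 1L))
  rho <- rowMeans(acfs)
  s <- 0
  k <- 1L
  while (k + 1L <= max_lag) {
    pair <- rho[k + 1L] + rho[k + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
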