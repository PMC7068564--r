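#' Time-domain HRV metrics for one 5-minute segment
#'
#' Conventions, fixed package-wide:
#' * `hr` (bpm) is `60000 / mean(rr)` — the mean heart rate of the segment,
#'   not the mean of instantaneous rates;
#' * `sdnn` (ms) is the sample standard deviation of RR (n - 1 denominator);
#' * `pnn50` (percent) counts successive differences strictly greater than
#'   50 ms in absolute value, out of the n - 1 successive pairs;
#' * `rmssd` (ms) is the root mean square of successive differences.
#'
#' @param segment An `rr_segment` from [segment_rr()]; must be valid.
#' @return A named list with `hr`, `sdnn`, `pnn50`, `rmssd`.
#'
#'   An invalid segment (fewer beats than the validity threshold) signals an
#'   error condition of class `velohrv_insufficient_beats`.
#' @export
time_domain_metrics <- function(segment) {
  stopifnot(inherits(segment, "rr_segment"))
  if (!segment$valid) stop_insufficient_beats(segment)
  rr <- segment$rr
  d <- diff(rr)
  list(
    hr = 60000 / mean(rr),
    sdnn = stats::sd(rr),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    rmssd = sqrt(mean(d^2))
  )
}
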