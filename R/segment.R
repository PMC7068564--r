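#' Cut a cleaned recording into repeated 5-minute segments
#'
#' Windows are half-open `[(k-1)*window_s, k*window_s)` anchored at the
#' recording start (t = 0); beats are assigned by their time stamp. An
#' incomplete trailing window is discarded: the last window counts as
#' complete when the final beat falls within two median beat intervals of
#' the window end, so a gap-free 40-minute recording yields exactly eight
#' windows even though its last beat lands slightly before 2400 s. At most
#' `max_lags` windows are returned.
#'
#' @param series A cleaned [rr_series()].
#' @param window_s Window length in seconds (default 300 = 5 min).
#' @param max_lags Maximum number of windows (default 8).
#' @param min_beats Minimum beat count for a segment to be usable; segments
#'   below it are returned but flagged `valid = FALSE`.
#' @return A list of `rr_segment` objects (possibly empty), each with fields
#'   `rr`, `beat_time`, `lag`, `window` (start/end, s), `n_beats`, `valid`,
#'   `meta`.
#' @export
segment_rr <- function(series, window_s = 300, max_lags = 8L,
                       min_beats = 100L) {
  stopifnot(inherits(series, "rr_series"), window_s > 0, max_lags >= 1)
  t_last <- max(series$beat_time)
  tol <- 2 * stats::median(series$rr) / 1000
  n_complete <- floor((t_last + tol) / window_s)
  n_windows <- min(n_complete, max_lags)
  if (n_windows < 1L) return(list())

  lapply(seq_len(n_windows), function(k) {
    lo <- (k - 1) * window_s
    hi <- k * window_s
    idx <- series$beat_time >= lo & series$beat_time < hi
    seg <- list(
      rr = series$rr[idx],
      beat_time = series$beat_time[idx],
      lag = k,
      window = c(start = lo, end = hi),
      n_beats = sum(idx),
      valid = sum(idx) >= min_beats,
      meta = series$meta
    )
    class(seg) <- "rr_segment"
    seg
  })
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf("<rr_segment> lag %d [%g, %g) s: %d beats%s\n",
              x$lag, x$window[["start"]], x$window[["end"]], x$n_beats,
              if (x$valid) "" else " (invalid: too few beats)"))
  invisible(x)
}

stop_insufficient_beats <- function(segment) {
  stop(errorCondition(
    sprintf("segment lag %d has %d beats, below the validity threshold",
            segment$lag, segment$n_beats),
    class = c("velohrv_insufficient_beats", "error")
  ))
}
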