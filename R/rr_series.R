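#' RR-interval series for one rest recording
#'
#' An `rr_series` holds the beat-to-beat (RR) intervals of a single rest
#' recording together with the time stamp of each beat and the study
#' coordinates of the recording (participant, day, period, rest label).
#'
#' @param beat_time Numeric vector, seconds from recording start, strictly
#'   increasing. Convention: `beat_time[k]` is the time at which beat `k`
#'   ends, so `beat_time[k+1] - beat_time[k]` equals `rr[k+1] / 1000` in a
#'   gap-free recording.
#' @param rr Numeric vector of RR intervals in milliseconds, one per beat;
#'   all positive.
#' @param participant,day,period,rest Recording metadata: participant id,
#'   study day (1-5), period (`"AM"`/`"PM"`), rest label (`"I"`-`"IV"`).
#' @param check_timing If `TRUE`, warn when beat-time differences disagree
#'   with the following RR interval by more than 1 ms (expected only after
#'   beats have been removed, which leaves gaps).
#'
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(beat_time, rr, participant = NA, day = NA,
                      period = NA, rest = NA, check_timing = FALSE) {
  beat_time <- as.numeric(beat_time)
  rr <- as.numeric(rr)
  if (length(beat_time) != length(rr)) {
    stop("`beat_time` and `rr` must have the same length")
  }
  if (length(rr) == 0L) stop("an rr_series must contain at least one beat")
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("all RR intervals must be finite and positive")
  }
  if (any(diff(beat_time) <= 0)) {
    stop("`beat_time` must be strictly increasing")
  }
  if (check_timing && length(rr) > 1L) {
    err <- abs(diff(beat_time) * 1000 - rr[-1L])
    if (any(err > 1)) {
      warning(sprintf(
        "%d beat-time differences deviate from the following RR by > 1 ms",
        sum(err > 1)
      ))
    }
  }
  structure(
    list(
      beat_time = beat_time,
      rr = rr,
      meta = list(participant = participant, day = day,
                  period = period, rest = rest)
    ),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<rr_series> %d beats over %.1f s (participant %s, day %s, %s, rest %s)\n",
    length(x$rr), max(x$beat_time) - min(x$beat_time),
    m$participant, m$day, m$period, m$rest
  ))
  cat(sprintf("  mean RR %.1f ms (HR %.1f bpm)\n",
              mean(x$rr), 60000 / mean(x$rr)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

#' Read an RR-interval recording from CSV
#'
#' Expects a headered CSV with columns `beat_time_s` and `rr_ms`; lines
#' starting with `#` are treated as comments. Metadata is supplied by the
#' caller (normally from the study manifest), not parsed from the filename.
#'
#' @param path Path to the CSV file.
#' @inheritParams rr_series
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path, participant = NA, day = NA,
                        period = NA, rest = NA) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("beat_time_s", "rr_ms")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' must contain columns %s", path,
                 paste(need, collapse = ", ")))
  }
  rr_series(df$beat_time_s, df$rr_ms, participant = participant,
            day = day, period = period, rest = rest)
}

#' Write an RR-interval recording to CSV
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  df <- data.frame(beat_time_s = series$beat_time, rr_ms = series$rr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
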