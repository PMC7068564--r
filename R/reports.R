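#' Descriptive summary table
#'
#' Mean, SD, min, P25, P50, P75, max, and IQR for the selected columns.
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the common scientific-software default);
#' IQR = P75 - P25.
#'
#' @param df A data frame.
#' @param cols Character vector of numeric columns to summarise; defaults to
#'   all numeric columns.
#' @return A tibble with one row per variable and columns `variable`,
#'   `mean`, `sd`, `min`, `p25`, `p50`, `p75`, `max`, `iqr`, `n`.
#' @export
descriptive_report <- function(df, cols = NULL) {
  stopifnot(nrow(df) >= 1)
  if (is.null(cols)) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  rows <- lapply(cols, function(v) {
    x <- df[[v]]
    x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      variable = v, mean = mean(x), sd = stats::sd(x), min = min(x),
      p25 = q[1], p50 = q[2], p75 = q[3], max = max(x), iqr = q[3] - q[1],
      n = length(x)
    )
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Pearson correlations with significance stars
#'
#' Two-sided t-test significance is marked `*`, `**`, `***` at the 0.05,
#' 0.01 and 0.001 levels. Pairs involving a zero-variance column get `NA`
#' correlations rather than an error.
#'
#' @param df A data frame.
#' @param cols Columns to correlate; defaults to all numeric columns.
#' @return A list of class `correlation_report`: `r` (correlation matrix),
#'   `p` (p-value matrix), `stars` (character matrix), `n` (complete rows).
#' @export
correlation_report <- function(df, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  x <- df[cols]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("at least 3 complete rows are required")
  k <- length(cols)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- x[[i]]; xj <- x[[j]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- stats::cor.test(xi, xj, method = "pearson")
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  stars <- matrix("", k, k, dimnames = list(cols, cols))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(list(r = r, p = p, stars = stars, n = nrow(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (n = %d); stars: * 0.05 ** 0.01 *** 0.001\n",
              x$n))
  fmt <- matrix(paste0(format(round(x$r, digits)), x$stars),
                nrow(x$r), dimnames = dimnames(x$r))
  print(fmt, quote = FALSE)
  invisible(x)
}
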