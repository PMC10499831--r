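#' Aggregate winter (November-April) rainfall
#'
#' Sums dated rainfall totals over each November-April window, labelling the
#' winter by its spring calendar year (the winter of 1993-94 is "1994"), so
#' winter rain aligns with the demographic season it precedes. A winter with
#' any of its six months unrepresented in the input is emitted as missing
#' and flagged, so downstream correlations drop the pair rather than use a
#' partial sum.
#'
#' @param precipitation Data frame with columns `date` (Date or
#'   "YYYY-MM-DD" strings; monthly or daily totals both work) and `mm`.
#' @return Data frame `year`, `rain_mm` (`NA` when incomplete), `complete`.
#' @examples
#' p <- data.frame(date = c("1993-11-01", "1993-12-01", "1994-01-01",
#'                          "1994-02-01", "1994-03-01", "1994-04-01"),
#'                 mm = c(10, 0, 25, 0, 5, 0))
#' winter_rain(p)  # 40 mm for winter-year 1994
#' @export
winter_rain <- function(precipitation) {
  stopifnot(is.data.frame(precipitation),
            all(c("date", "mm") %in% names(precipitation)))
  d <- as.Date(precipitation$date)
  if (anyNA(d)) stop("unparseable dates in precipitation records", call. = FALSE)
  if (any(precipitation$mm < 0, na.rm = TRUE))
    stop("negative rainfall values", call. = FALSE)
  mo <- as.integer(format(d, "%m"))
  yr <- as.integer(format(d, "%Y"))
  in_window <- mo %in% c(11L, 12L, 1L:4L)
  wy <- ifelse(mo >= 11L, yr + 1L, yr)  # label by the spring side
  wy[!in_window] <- NA_integer_
  winters <- sort(unique(wy[!is.na(wy)]))
  out <- do.call(rbind, lapply(winters, function(w) {
    sel <- !is.na(wy) & wy == w
    months_present <- unique(mo[sel])
    complete <- all(c(11L, 12L, 1L:4L) %in% months_present) &&
      !anyNA(precipitation$mm[sel])
    data.frame(year = w,
               rain_mm = if (complete) sum(precipitation$mm[sel]) else NA_real_,
               complete = complete)
  }))
  rownames(out) <- NULL
  out
}

#' Lagged Pearson correlation between two annual series
#'
#' Pairs series `a` in year \eqn{t} with series `b` in year \eqn{t + lag},
#' computes the Pearson correlation over complete pairs, and a 95% confidence
#' interval by the Fisher z transform with the \eqn{n - 3} denominator. A
#' perfect correlation (|r| = 1, degenerate z) is reported with the interval
#' collapsed to the boundary and flagged.
#'
#' @param a,b Data frames with columns `year` and `value` (or named numeric
#'   vectors with years as names).
#' @param lag Integer lag in years applied to `b`.
#' @param labels Length-2 character vector naming the pair.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return A `lagged_correlation` list: `pair`, `lag`, `n`, `r`, `ci`
#'   (lower, upper), `boundary`.
#' @examples
#' a <- data.frame(year = 1991:1995, value = c(1, 2, 3, 4, 5))
#' b <- data.frame(year = 1991:1995, value = c(2, 1, 4, 3, 6))
#' lagged_correlation(a, b, lag = 0)
#' @export
lagged_correlation <- function(a, b, lag = 0L, labels = c("a", "b"),
                               conf_level = 0.95) {
  a <- .as_series(a); b <- .as_series(b)
  lag <- as.integer(lag)
  m <- match(a$year + lag, b$year)
  ok <- !is.na(m) & is.finite(a$value) & is.finite(b$value[m])
  va <- a$value[ok]; vb <- b$value[m[ok]]
  n <- length(va)
  if (n < 3L)
    stop("fewer than 3 overlapping pairs at lag ", lag, call. = FALSE)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero variance in an aligned series: correlation undefined", call. = FALSE)
  r <- stats::cor(va, vb)
  boundary <- abs(r) >= 1 - 1e-12
  if (boundary) {
    ci <- c(r, r)
  } else {
    zr <- atanh(r)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    half <- zq / sqrt(n - 3)
    ci <- tanh(c(zr - half, zr + half))
  }
  structure(list(pair = labels, lag = lag, n = n, r = r,
                 ci = ci, boundary = boundary, conf_level = conf_level),
            class = "lagged_correlation")
}

.as_series <- function(s) {
  if (is.data.frame(s)) {
    stopifnot(all(c("year", "value") %in% names(s)))
    if (anyDuplicated(s$year)) stop("duplicate years in series", call. = FALSE)
    return(s[, c("year", "value")])
  }
  if (is.numeric(s) && !is.null(names(s)))
    return(data.frame(year = as.integer(names(s)), value = as.numeric(s)))
  stop("series must be a data frame (year, value) or a named numeric vector",
       call. = FALSE)
}

#' @export
print.lagged_correlation <- function(x, ...) {
  cat(sprintf("%s(t) ~ %s(t%+d): r = %.3f [%.3f, %.3f], n = %d%s\n",
              x$pair[1], x$pair[2], x$lag, x$r, x$ci[1], x$ci[2], x$n,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Trophic-chain correlations from a population series
#'
#' Computes the three lagged pairs of the chain on a population series
#' (`reindeer_n`, `fox_pct`, `goose_n` columns): reindeer abundance in year
#' \eqn{t} against fox reproduction in \eqn{t+2}; fox reproduction against
#' goose abundance in the same year; and reindeer in \eqn{t} against goose
#' abundance in \eqn{t+2}.
#'
#' @param series Population series data frame.
#' @param window Optional year range (length-2) restricting the series.
#' @return Named list of three `lagged_correlation` objects:
#'   `reindeer_fox_lag2`, `fox_goose_lag0`, `reindeer_goose_lag2`.
#' @export
trophic_correlations <- function(series, window = NULL) {
  stopifnot(is.data.frame(series),
            all(c("year", "goose_n", "reindeer_n", "fox_pct") %in% names(series)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    series <- series[series$year >= window[1] & series$year <= window[2], ]
  }
  s <- function(col) data.frame(year = series$year, value = series[[col]])
  list(
    reindeer_fox_lag2 = lagged_correlation(s("reindeer_n"), s("fox_pct"),
                                           lag = 2L, labels = c("reindeer", "fox")),
    fox_goose_lag0 = lagged_correlation(s("fox_pct"), s("goose_n"),
                                        lag = 0L, labels = c("fox", "goose")),
    reindeer_goose_lag2 = lagged_correlation(s("reindeer_n"), s("goose_n"),
                                             lag = 2L, labels = c("reindeer", "goose")))
}
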