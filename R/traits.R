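#' Body-condition index from mass and structural size
#'
#' Regresses body mass on tarsus length by ordinary least squares, pooled over
#' all complete observations, and defines each individual's condition as the
#' residual: mass adjusted for structural size, in grams. Rows missing mass or
#' tarsus receive `NA` condition and do not enter the regression.
#'
#' @param observations Data frame with columns `mass_g` and `tarsus_mm`
#'   (other columns are passed through).
#' @param by_year If `TRUE`, fit a separate regression per year (requires a
#'   `year` column); the default is a single pooled line.
#' @return `observations` with a `condition` column added; the fitted
#'   regression is attached as attribute `"condition_fit"` (coefficients and
#'   n used).
#' @examples
#' d <- data.frame(tarsus_mm = c(70, 80, 90), mass_g = c(1900, 2000, 2400))
#' compute_condition_index(d)$condition  # 50, -100, 50
#' @export
compute_condition_index <- function(observations, by_year = FALSE) {
  stopifnot(is.data.frame(observations))
  if (!all(c("mass_g", "tarsus_mm") %in% names(observations)))
    stop("'observations' needs columns 'mass_g' and 'tarsus_mm'", call. = FALSE)
  ok <- is.finite(observations$mass_g) & is.finite(observations$tarsus_mm)
  if (any(observations$mass_g[ok] <= 0) || any(observations$tarsus_mm[ok] <= 0))
    stop("mass and tarsus must be positive", call. = FALSE)
  fit_one <- function(dat, rows) {
    if (sum(rows) < 3L)
      stop("need at least 3 complete mass/tarsus observations", call. = FALSE)
    if (var(dat$tarsus_mm[rows]) == 0)
      stop("tarsus length is constant: condition regression is degenerate",
           call. = FALSE)
    lm(mass_g ~ tarsus_mm, data = dat[rows, ])
  }
  observations$condition <- NA_real_
  if (by_year) {
    if (!("year" %in% names(observations)))
      stop("by_year = TRUE requires a 'year' column", call. = FALSE)
    fits <- list()
    for (y in sort(unique(observations$year))) {
      rows <- ok & observations$year == y
      f <- fit_one(observations, rows)
      observations$condition[rows] <- resid(f)
      fits[[as.character(y)]] <- c(coef(f), n = sum(rows))
    }
    attr(observations, "condition_fit") <- fits
  } else {
    f <- fit_one(observations, ok)
    observations$condition[ok] <- resid(f)
    attr(observations, "condition_fit") <-
      c(coef(f), n = sum(ok))
  }
  observations
}

#' Normalise a trait to mean zero and unit standard deviation
#'
#' Affine transform \eqn{(v - \bar v) / s_v} using the sample standard
#' deviation; idempotent and correlation-preserving. `NA`s are ignored in the
#' centring/scaling and propagated to the output.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Normalised vector of the same length.
#' @examples
#' normalize_trait(c(2, 4, 6))  # -1 0 1
#' @export
normalize_trait <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("trait is constant (or has < 2 finite values): cannot normalise",
         call. = FALSE)
  (values - mean(v)) / sd(v)
}

#' Temporal trend test for a trait
#'
#' Least-squares regression of the trait on calendar year with a two-sided
#' test of zero slope. The default unit of analysis is annual means weighted
#' by annual sample size; set `unit = "observations"` for an
#' observation-level regression. The unit used is recorded in the output.
#'
#' @param data Data frame with columns `year` and `value`.
#' @param unit `"annual_means"` (weighted by n, default) or `"observations"`.
#' @return A list of class `trend_test`: `slope`, `se`, `p_value`, `unit`,
#'   `n_years`.
#' @export
annual_trend_test <- function(data, unit = c("annual_means", "observations")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data), all(c("year", "value") %in% names(data)))
  data <- data[is.finite(data$value) & is.finite(data$year), ]
  n_years <- length(unique(data$year))
  if (n_years < 3L)
    stop("need at least 3 distinct years for a trend test", call. = FALSE)
  if (unit == "annual_means") {
    agg <- aggregate(value ~ year, data = data, FUN = mean)
    agg$n <- as.vector(table(factor(data$year, levels = agg$year)))
    f <- lm(value ~ year, data = agg, weights = n)
  } else {
    f <- lm(value ~ year, data = data)
  }
  sm <- suppressWarnings(summary(f))
  cf <- sm$coefficients
  slope <- unname(coef(f)["year"])
  se <- if (nrow(cf) >= 2L) cf["year", 2] else NA_real_
  p <- if (nrow(cf) >= 2L) cf["year", 4] else NA_real_
  # an (essentially) exact fit leaves no residual variance and the t test is
  # meaningless: a flat line is no evidence of trend (p = 1), a non-zero
  # exact slope is certain (p ~ 0)
  vscale <- max(sd(data$value), abs(mean(data$value)), 1)
  if (!is.finite(p) || sm$sigma < 1e-10 * vscale) {
    degenerate_zero <- abs(slope) < 1e-8 * vscale
    p <- if (degenerate_zero) 1 else 0
    if (degenerate_zero) slope <- 0
  }
  out <- list(slope = slope, se = se, p_value = p, unit = unit,
              n_years = n_years)
  structure(out, class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Trend (%s, %d years): slope = %.4g (se %.3g), p = %.3g\n",
              x$unit, x$n_years, x$slope, x$se, x$p_value))
  invisible(x)
}

#' Individual annual fitness from survival and recruitment
#'
#' Female annual fitness is her contribution of individuals to the next
#' breeding season, \eqn{W = I + B/2}: survival indicator \eqn{I \in \{0,1\}}
#' plus half the recruit count \eqn{B} (recruits of both sexes; the half
#' assumes an even sex ratio). The doubled fitness \eqn{2W = 2I + B} is an
#' integer and is the response of the Poisson selection models.
#'
#' @param I Survival indicator(s), 0 or 1.
#' @param B Recruit count(s), non-negative integer.
#' @return Data frame with columns `I`, `B`, `W`, `twoW`.
#' @examples
#' compute_fitness(1, 3)  # W = 2.5, twoW = 5
#' @export
compute_fitness <- function(I, B) {
  if (length(I) != length(B)) stop("'I' and 'B' lengths differ", call. = FALSE)
  if (any(!I %in% c(0, 1))) stop("'I' must be 0 or 1", call. = FALSE)
  if (any(!is.finite(B)) || any(B < 0) || any(abs(B - round(B)) > 1e-8))
    stop("'B' must be a non-negative integer", call. = FALSE)
  I <- as.integer(I); B <- as.integer(round(B))
  data.frame(I = I, B = B, W = I + B / 2, twoW = 2L * I + B)
}
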