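## Time-series statistics for ddPCR abundance series: unadjusted
## auto-/partial auto-/cross-correlations by sampling-date lag, a
## floating-mean Lomb-Scargle periodogram for the uneven calendar, a
## GCV-selected cubic smoothing spline trend, and the coefficient of
## variation of log10 quantifications.

#' Per-date mean of log10 replicate values
#'
#' Collapses a replicated abundance series to one value per sampling
#' date, the convention used before correlation analysis (log10
#' quantifications averaged across the replicate oysters). Non-positive
#' values are floored at \code{floor_value} before the log.
#'
#' @param series Data frame with columns date, value.
#' @param floor_value Positive floor applied before log10.
#' @return Data frame: date, log10_mean.
#' @export
collapse_series <- function(series, floor_value = 1) {
  v <- pmax(series$value, floor_value)
  agg <- tapply(log10(v), series$date, mean)
  data.frame(date = as.numeric(names(agg)), log10_mean = unname(agg))
}

#' Unadjusted autocorrelation and partial autocorrelation
#'
#' The biased (n-denominator) sample autocorrelation
#' \code{r_k = sum (x_t - xbar)(x_{t+k} - xbar) / sum (x_t - xbar)^2}
#' with \code{r_0 = 1}, and partial autocorrelations from the
#' Durbin-Levinson recursion (via \code{stats::acf}/\code{stats::pacf}).
#'
#' @param x Numeric series (one value per sampling date).
#' @param max_lag Maximum lag in sampling dates.
#' @return Data frame: lag (0..max_lag), acf, pacf (NA at lag 0).
#' @export
acf_pacf <- function(x, max_lag = 10) {
  if (length(x) <= max_lag) stop("validation error: series shorter than max_lag")
  if (stats::var(x) == 0) stop("validation error: constant series")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)
  data.frame(
    lag = 0:max_lag,
    acf = as.numeric(a$acf),
    pacf = c(NA, as.numeric(p$acf))
  )
}

#' Unadjusted cross-correlation by lag with argmax
#'
#' Standard sample cross-correlation between two aligned series for lags
#' \code{-max_lag..max_lag} (via \code{stats::ccf}). At lag k the value
#' correlates \code{a_{t+k}} with \code{b_t}, so a positive argmax lag
#' means a lags behind b; \code{ccf_series(a, b)} at lag k equals
#' \code{ccf_series(b, a)} at -k.
#'
#' @param a,b Numeric series of equal length, aligned by sampling date.
#' @param dates_a,dates_b Optional date vectors checked for alignment.
#' @param max_lag Maximum lag in sampling dates.
#' @return List: \code{table} (lag, ccf), \code{argmax_lag},
#'   \code{argmax_value}.
#' @export
ccf_series <- function(a, b, max_lag = 10, dates_a = NULL, dates_b = NULL) {
  if (!is.null(dates_a) || !is.null(dates_b)) {
    if (is.null(dates_a) || is.null(dates_b) || !identical(dates_a, dates_b)) {
      stop("validation error: series dates are not aligned")
    }
  }
  if (length(a) != length(b)) stop("validation error: unequal series lengths")
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tab <- data.frame(lag = as.numeric(cc$lag), ccf = as.numeric(cc$acf))
  i <- which.max(tab$ccf)
  list(table = tab, argmax_lag = tab$lag[i], argmax_value = tab$ccf[i])
}

#' Floating-mean Lomb-Scargle periodogram for uneven sampling
#'
#' Generalized (floating-mean) Lomb-Scargle periodogram evaluated on a
#' frequency grid from 1/T to n/(2T) (T = observation span, n = number
#' of observations) with an oversampling factor controlling grid
#' density. Power uses the standard normalization by the total variance,
#' so it lies in [0, 1]. A false-alarm threshold for the peak is
#' available from \code{\link{lomb_scargle_fap_level}}.
#'
#' @param dates Ordinal day numbers (>= 4, not necessarily even).
#' @param values Observations at those dates (non-constant).
#' @param oversampling Frequency grid oversampling factor.
#' @return List: \code{frequency}, \code{power}, \code{peak_frequency},
#'   \code{peak_power}, \code{n}.
#' @export
lomb_scargle <- function(dates, values, oversampling = 5) {
  n <- length(values)
  if (n < 4) stop("validation error: need >= 4 observations")
  if (length(dates) != n) stop("validation error: dates/values length mismatch")
  if (stats::var(values) == 0) stop("validation error: constant input")
  t <- as.numeric(dates)
  span <- max(t) - min(t)
  freq <- seq(1 / span, n / (2 * span), by = 1 / (oversampling * span))
  y <- values - mean(values)
  yy <- sum(y^2)
  power <- vapply(freq, function(f) {
    w <- 2 * pi * f
    cw <- cos(w * t); sw <- sin(w * t)
    # floating mean: project onto {1, cos, sin} with the constant removed
    c0 <- cw - mean(cw); s0 <- sw - mean(sw)
    cc <- sum(c0^2); ss <- sum(s0^2); cs <- sum(c0 * s0)
    yc <- sum(y * c0); ys <- sum(y * s0)
    d <- cc * ss - cs^2
    if (d <= 0) return(0)
    (ss * yc^2 + cc * ys^2 - 2 * cs * yc * ys) / (d * yy)
  }, 0)
  i <- which.max(power)
  list(frequency = freq, power = power,
       peak_frequency = freq[i], peak_power = power[i], n = n)
}

#' False-alarm power level for a Lomb-Scargle peak
#'
#' Power threshold exceeded by the highest peak of pure noise with
#' probability \code{fap}, under the classical independent-frequencies
#' approximation: each normalized power follows a
#' Beta-derived law with \code{prob(P > z) = (1 - z)^{(n-3)/2}} and the
#' maximum over M effective independent frequencies is corrected as
#' \code{1 - (1 - prob)^M}.
#'
#' @param n Number of observations.
#' @param n_freq Number of evaluated frequencies; the effective count is
#'   reduced by the oversampling factor.
#' @param fap Target false-alarm probability.
#' @param oversampling Oversampling factor used for the grid.
#' @return Power threshold in [0, 1].
#' @export
lomb_scargle_fap_level <- function(n, n_freq, fap = 0.01, oversampling = 5) {
  m <- max(1, round(n_freq / oversampling))
  prob_single <- 1 - (1 - fap)^(1 / m)
  1 - prob_single^(2 / (n - 3))
}

#' GCV-selected cubic smoothing spline trend
#'
#' Cubic smoothing spline with the smoothing parameter chosen by
#' generalized cross-validation (\code{stats::smooth.spline} with
#' \code{cv = FALSE}), evaluated at the observation dates.
#'
#' @param dates Strictly increasing observation dates (>= 5, no
#'   duplicates).
#' @param values Observations.
#' @return List: \code{fitted} (data frame date, value), \code{spar},
#'   \code{lambda}.
#' @export
spline_trend <- function(dates, values) {
  if (length(dates) < 5) stop("validation error: need >= 5 observations")
  if (anyDuplicated(dates)) stop("validation error: duplicate dates")
  fit <- stats::smooth.spline(dates, values, cv = FALSE)
  pred <- stats::predict(fit, as.numeric(dates))
  list(fitted = data.frame(date = as.numeric(dates), value = pred$y),
       spar = fit$spar, lambda = fit$lambda)
}

#' Coefficient of variation of a log10 quantification series
#'
#' Sample standard deviation divided by sample mean, computed by default
#' on the log10 scale of the per-date quantifications.
#'
#' @param x Numeric series (log10 quantifications, or raw values with
#'   \code{log10_input = FALSE} to take logs first).
#' @param log10_input Set FALSE to log10-transform \code{x} first.
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(x, log10_input = TRUE) {
  if (!log10_input) x <- log10(x)
  if (length(x) < 2) stop("validation error: need >= 2 values")
  m <- mean(x)
  if (m == 0) stop("validation error: zero mean")
  stats::sd(x) / m
}
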