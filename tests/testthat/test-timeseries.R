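test_that("autocorrelations use the biased unadjusted estimator", {
  set.seed(41)
  x <- rnorm(40)
  out <- acf_pacf(x, max_lag = 10)
  expect_equal(out$acf[1], 1)
  ref <- acf(x, lag.max = 10, plot = FALSE)
  expect_equal(out$acf, as.numeric(ref$acf))
  # manual biased r_1
  xb <- x - mean(x)
  r1 <- sum(xb[-length(x)] * xb[-1]) / sum(xb^2)
  expect_equal(out$acf[2], r1)
  expect_true(all(abs(out$acf) <= 1))
  expect_true(all(abs(out$pacf[-1]) <= 1))
  # alternating series: r_1 near -1
  alt <- rep(c(1, -1), 30)
  expect_lt(acf_pacf(alt, 2)$acf[2], -0.9)
  expect_error(acf_pacf(rep(1, 20), 5), "constant")
  expect_error(acf_pacf(rnorm(5), 10), "shorter")
})

test_that("white-noise autocorrelations stay inside the sampling bound", {
  set.seed(42)
  frac_ok <- mean(vapply(1:100, function(i) {
    x <- rnorm(200)
    r <- acf_pacf(x, 10)$acf[-1]
    all(abs(r) < 2.5 / sqrt(200))
  }, TRUE))
  expect_gt(frac_ok, 0.85)
})

test_that("cross-correlation finds planted lags and is antisymmetric", {
  set.seed(43)
  b <- rnorm(40)
  cc0 <- ccf_series(b, b, max_lag = 5)
  expect_equal(cc0$argmax_lag, 0)
  expect_equal(cc0$argmax_value, 1)
  # a lags b by 2 sampling dates
  a <- c(rnorm(2), b[1:38])
  cc <- ccf_series(a, b, max_lag = 5)
  expect_equal(cc$argmax_lag, 2)
  # CCF(a,b) at lag k equals CCF(b,a) at -k
  cc_ba <- ccf_series(b, a, max_lag = 5)
  expect_equal(cc$table$ccf, rev(cc_ba$table$ccf))
  expect_error(ccf_series(a, b, dates_a = 1:40, dates_b = 2:41), "aligned")
  expect_error(ccf_series(rnorm(5), rnorm(6)), "unequal")
})

test_that("independent noise series rarely show strong cross-correlation", {
  set.seed(44)
  strong <- mean(vapply(1:100, function(i) {
    ccf_series(rnorm(35), rnorm(35), max_lag = 10)$argmax_value >= 0.5
  }, TRUE))
  expect_lt(strong, 0.10)
})

test_that("Lomb-Scargle recovers a planted period on uneven dates", {
  set.seed(45)
  dates <- cumsum(sample(1:4, 35, TRUE))
  vals <- sin(2 * pi * dates / 20)
  ls <- lomb_scargle(dates, vals)
  grid_step <- ls$frequency[2] - ls$frequency[1]
  expect_lt(abs(ls$peak_frequency - 1 / 20), grid_step + 1e-12)
  expect_gt(ls$peak_power, 0.9)
  expect_true(all(ls$power >= 0 & ls$power <= 1 + 1e-9))
  expect_error(lomb_scargle(1:10, rep(1, 10)), "constant")
  expect_error(lomb_scargle(1:3, rnorm(3)), ">= 4")
})

test_that("period recovery holds across random uneven sampling patterns", {
  set.seed(46)
  ok <- vapply(1:20, function(i) {
    dates <- cumsum(sample(1:4, 35, TRUE))
    vals <- sin(2 * pi * dates / 20) + rnorm(35, 0, 0.2)
    ls <- lomb_scargle(dates, vals)
    abs(ls$peak_frequency - 0.05) <= 2 * (ls$frequency[2] - ls$frequency[1])
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("evenly sampled periodogram peak agrees with an FFT oracle", {
  set.seed(47)
  n <- 64
  dates <- 1:n
  vals <- sin(2 * pi * dates / 8) + rnorm(n, 0, 0.1)
  ls <- lomb_scargle(dates, vals, oversampling = 8)
  spec <- Mod(fft(vals - mean(vals)))[2:(n / 2)]
  fft_freq <- (1:(n / 2 - 1)) / n
  fft_peak <- fft_freq[which.max(spec)]
  expect_lt(abs(ls$peak_frequency - fft_peak),
            2 * (ls$frequency[2] - ls$frequency[1]))
})

test_that("white-noise periodogram peaks stay below the 1% false-alarm level", {
  set.seed(48)
  exceed <- mean(vapply(1:100, function(i) {
    dates <- cumsum(sample(1:4, 35, TRUE))
    ls <- lomb_scargle(dates, rnorm(35))
    ls$peak_power > lomb_scargle_fap_level(ls$n, length(ls$frequency), 0.01)
  }, TRUE))
  expect_lt(exceed, 0.06)
})

test_that("GCV spline reproduces lines and denoises sinusoids", {
  dates <- c(1, 3, 4, 7, 9, 12, 15, 20)
  line <- 2 + 0.5 * dates
  fit <- spline_trend(dates, line)
  expect_equal(fit$fitted$value, line, tolerance = 1e-6)
  set.seed(49)
  d2 <- sort(sample(1:100, 60))
  truth <- sin(2 * pi * d2 / 40)
  noisy <- truth + rnorm(60, 0, 0.3)
  fit2 <- spline_trend(d2, noisy)
  rmse <- sqrt(mean((fit2$fitted$value - truth)^2))
  expect_lt(rmse, 0.3)
  expect_error(spline_trend(c(1, 1, 2, 3, 4), rnorm(5)), "duplicate")
  expect_error(spline_trend(1:4, rnorm(4)), ">= 5")
})

test_that("coefficient of variation matches sd over mean of log10 values", {
  expect_equal(coefficient_of_variation(rep(2.5, 5)), 0)
  x <- c(1, 1, 1, 1, 5)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  # doubling deviations doubles the CV
  base <- c(2, 2.5, 3, 3.5, 4)
  doubled <- 3 + 2 * (base - 3)
  expect_equal(coefficient_of_variation(doubled),
               2 * coefficient_of_variation(base) *
                 mean(base) / mean(doubled))
  expect_equal(mean(base), mean(doubled))  # same mean, so exactly 2x
  expect_equal(coefficient_of_variation(doubled),
               2 * coefficient_of_variation(base))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  # raw-scale input can be logged first
  expect_equal(coefficient_of_variation(10^base, log10_input = FALSE),
               coefficient_of_variation(base))
})

test_that("replicate series collapse to per-date log10 means", {
  s <- data.frame(date = c(1, 1, 2, 2), value = c(10, 1000, 100, 100))
  cs <- collapse_series(s)
  expect_equal(cs$log10_mean, c(2, 2))
  expect_identical(cs$date, c(1, 2))
})
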