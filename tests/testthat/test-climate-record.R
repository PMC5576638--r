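make_series <- function(dates, tmax, tmin, snow = NA_real_)
  daily_weather(as.Date(dates, origin = "1970-01-01"), tmax, tmin, snow)

test_that("impute_daily fills interior gaps linearly and nothing else", {
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 7)
  s <- daily_weather(d, tmax = c(NA, 10, NA, NA, NA, 14, 16) + 5,
                     tmin = c(NA, 10, NA, NA, NA, 14, 16) - 5)
  out <- impute_daily(s)
  expect_equal(out$tmax[3:5], c(11, 12, 13) + 5)
  expect_equal(out$tmin[3:5], c(11, 12, 13) - 5)
  expect_true(is.na(out$tmax[1]))          # leading gap stays missing
  expect_true(all(out$tmax_imputed[3:5]))
  expect_false(any(out$tmax_imputed[c(2, 6, 7)]))
  # recorded values unchanged; idempotent
  again <- impute_daily(out)
  expect_identical(again, out)
  full <- daily_weather(d, tmax = 1:7, tmin = 0:6)
  expect_equal(impute_daily(full)$tmax, 1:7)
})

test_that("annual summaries apply the missing-day inclusion thresholds", {
  d <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  s <- daily_weather(d, rep(10, 365), rep(10, 365), rep(0, 365))
  a <- summarize_years(impute_daily(s))
  expect_equal(a$mat, 10)
  expect_equal(a$mst, 10)
  expect_true(a$included_annual && a$included_summer)

  # exactly 15 missing annual days (January): excluded for annual analyses
  tmax <- rep(10, 365); tmax[1:15] <- NA
  a15 <- summarize_years(impute_daily(daily_weather(d, tmax, tmax - 1)))
  expect_equal(a15$missing_annual, 15)
  expect_false(a15$included_annual)
  a14 <- summarize_years(impute_daily(
    daily_weather(d, replace(rep(10, 365), 1:14, NA), rep(9, 365))))
  expect_true(a14$included_annual)

  # 9 missing summer days: still included for summer analyses
  tmax2 <- rep(10, 365)
  jun1 <- as.integer(as.Date("2001-06-01") - as.Date("2001-01-01")) + 1
  tmax2[jun1:(jun1 + 8)] <- NA
  a9 <- summarize_years(impute_daily(daily_weather(d, tmax2, tmax2 - 2)))
  expect_equal(a9$missing_summer, 9)
  expect_true(a9$included_summer)
})

test_that("missing days are counted before imputation", {
  d <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  tmax <- rep(10, 365); tmax[100:140] <- NA
  a <- summarize_years(impute_daily(daily_weather(d, tmax, tmax - 1)))
  expect_equal(a$missing_annual, 41)   # imputation does not hide the gap
  expect_false(a$included_annual)
})

test_that("fit_trend matches the OLS closed form and spec examples", {
  years <- 1910:2015
  vals <- 5 + 0.019 * (years - 1910)
  tr <- fit_trend(vals, years)
  expect_equal(tr$slope, 0.019, tolerance = 1e-12)
  expect_equal(tr$total_change, 0.019 * 105, tolerance = 1e-12)
  expect_lt(tr$p_two_sided, 1e-100)
  # constant series
  trc <- fit_trend(rep(3, 20), 1981:2000)
  expect_equal(trc$slope, 0)
  expect_equal(trc$total_change, 0)
  # closed-form check on noisy data
  set.seed(5)
  v <- rnorm(30); y <- 1986:2015
  tr2 <- fit_trend(v, y)
  b <- cov(v, y) / var(y)
  resid <- v - mean(v) - b * (y - mean(y))
  se <- sqrt(sum(resid^2) / 28 / sum((y - mean(y))^2))
  expect_equal(tr2$slope, b, tolerance = 1e-12)
  expect_equal(tr2$slope_se, se, tolerance = 1e-12)
  expect_equal(tr2$p_two_sided, 2 * pt(-abs(b / se), 28), tolerance = 1e-12)
  expect_error(fit_trend(c(1, 2, 3), rep(2000, 3)),
               class = "taluscape_validation_error")
})

test_that("synthetic warming series recovers the generating total change", {
  sc <- synthetic_scenario(seed = 41, warming_rate = 1.9, noise_sd = 0.5,
                           missing_day_rate = 0.15)
  an <- summarize_years(impute_daily(make_daily_weather(sc)))
  tr <- fit_trend(an$mat, an$year)
  truth <- 1.9 / 100 * 105
  expect_gt(truth, tr$ci95_total_change[1] - 0.15)
  expect_lt(truth, tr$ci95_total_change[2] + 0.15)
  expect_lt(tr$p_two_sided, 1e-10)
})

test_that("compare_epochs: identical epochs, z-test example, MW oracle", {
  vals <- rep(c(4, 5, 6, 7), 10)
  yrs <- 1936:1975
  w <- compare_epochs(vals, yrs, split_year = 1955, test = "welch_t")
  expect_equal(w$p_two_sided, 1, tolerance = 1e-9)
  expect_equal(w$n_a, 20); expect_equal(w$n_b, 20)

  # 0/45 vs 20/59 negligible-snow years: two-tailed z-test p < 0.0005
  snow <- c(rep(10, 45), rep(c(0, 10), c(20, 39)))
  yrs2 <- c(1911:1955, 1956:2014)
  z <- compare_epochs(snow, yrs2, 1955, "two_proportion_z")
  expect_equal(z$prop_a, 0)
  expect_equal(z$prop_b, 20 / 59, tolerance = 1e-12)
  expect_lt(z$p_two_sided, 0.0005)

  # Mann-Whitney against exhaustive enumeration at small n
  a <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  b <- c(4.3, 6.1, 5.9, 7.2, 3.8, 6.6)
  got <- compare_epochs(c(a, b), c(1951:1955, 1956:1961), 1955,
                        "mann_whitney")
  expect_equal(got$p_two_sided, oracle_mann_whitney(a, b), tolerance = 1e-9)

  expect_error(compare_epochs(1:10, 2001:2010, 1955, "welch_t"),
               class = "taluscape_validation_error")
  expect_error(compare_epochs(vals, yrs, test = "bogus"))
})

test_that("spearman_trend detects a monotone snow decline", {
  set.seed(8)
  yrs <- 1911:2015
  snow <- 80 - 0.5 * (yrs - 1911) + rnorm(105, 0, 5)
  sp <- compare_epochs(snow, yrs, 1955, "spearman_trend")
  expect_lt(sp$p_two_sided, 1e-10)
  expect_lt(sp$statistic, 0)
})

test_that("compare_slopes follows the Welch closed form", {
  set.seed(12)
  y1 <- 1910:2015; v1 <- 5 + 0.019 * (y1 - 1910) + rnorm(106, 0, 0.5)
  y2 <- 1910:2015; v2 <- 5 + 0.010 * (y2 - 1910) + rnorm(106, 0, 0.5)
  t1 <- fit_trend(v1, y1); t2 <- fit_trend(v2, y2)
  cs <- compare_slopes(t1, t2)
  tt <- (t1$slope - t2$slope) / sqrt(t1$slope_se^2 + t2$slope_se^2)
  df <- (t1$slope_se^2 + t2$slope_se^2)^2 /
    (t1$slope_se^4 / 104 + t2$slope_se^4 / 104)
  expect_equal(cs$statistic, tt, tolerance = 1e-12)
  expect_equal(cs$p_two_sided, 2 * pt(-abs(tt), df), tolerance = 1e-12)
  # identical fits: p = 1
  expect_equal(compare_slopes(t1, t1)$p_two_sided, 1)
  # a huge SE drowns the contrast
  t3 <- t2; t3$slope_se <- 100
  expect_gt(compare_slopes(t1, t3)$p_two_sided, 0.99)
})

test_that("delta_offset is the historical-minus-base mean difference", {
  yrs <- 1910:2015
  # stationary series: zero offset
  ann0 <- summarize_years(impute_daily(make_daily_weather(
    synthetic_scenario(seed = 2, warming_rate = 0, noise_sd = 0,
                       missing_day_rate = 0))))
  # leap-year phasing of the seasonal cosine perturbs summer means at the
  # 1e-4 C level even with zero noise
  expect_equal(delta_offset(ann0, "mst"), 0, tolerance = 1e-3)
  # linear 0.019 C/yr: offset = -(2005.5 - 1932.5) * 0.019
  ann <- data.frame(year = yrs, mat = 5 + 0.019 * (yrs - 1910),
                    mst = 15 + 0.019 * (yrs - 1910),
                    april_snow = 0, missing_annual = 0, missing_summer = 0,
                    included_annual = TRUE, included_summer = TRUE)
  expect_equal(delta_offset(ann, "mst"), -73 * 0.019, tolerance = 1e-12)
  expect_error(delta_offset(ann, "mst", base_period = c(2050, 2060)),
               class = "taluscape_validation_error")
})

test_that("GHCN long format reads with unit conversion", {
  f <- withr::local_tempfile(fileext = ".csv")
  long <- rbind(
    data.frame(station = "TAHOE", date = "2000-01-01", element = "TMAX",
               value = 55),
    data.frame(station = "TAHOE", date = "2000-01-01", element = "TMIN",
               value = -12),
    data.frame(station = "TAHOE", date = "2000-01-01", element = "SNWD",
               value = 340),
    data.frame(station = "TAHOE", date = "2000-01-02", element = "TMAX",
               value = 60))
  write.csv(long, f, row.names = FALSE)
  s <- read_ghcn_daily(f, station = "TAHOE")
  expect_equal(s$tmax, c(5.5, 6.0))
  expect_equal(s$tmin, c(-1.2, NA))
  expect_equal(s$snow_depth, c(34, NA))
})
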