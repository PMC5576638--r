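#' Ordinary least-squares trend of an annual variable
#'
#' Fits `value ~ year` by OLS over included years and reports the slope, its
#' standard error, the two-sided p-value, and the total change over the
#' record span (`slope * (last_year - first_year)`).
#'
#' @param values annual values.
#' @param years calendar years, same length.
#' @param span optional two-element record span for `total_change`; defaults
#'   to `range(years)` of the fitted points.
#' @return A `trend_result` list: `slope`, `slope_se`, `p_two_sided`,
#'   `n_years`, `total_change`, `span`, `ci95_total_change`, and `fit`.
#' @export
fit_trend <- function(values, years, span = range(years)) {
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]; years <- years[ok]
  if (length(values) < 3)
    stop_validation("need at least 3 included years to fit a trend")
  if (length(unique(years)) < 2)
    stop_validation("degenerate trend fit: all observations share one year")
  fit <- lm(values ~ years)
  sm <- summary(fit)$coefficients
  slope <- sm["years", "Estimate"]
  se <- sm["years", "Std. Error"]
  p <- sm["years", "Pr(>|t|)"]
  span_w <- diff(range(span))
  tc <- slope * span_w
  tcrit <- qt(0.975, df = fit$df.residual)
  structure(list(slope = slope, slope_se = se, p_two_sided = p,
                 n_years = length(values), total_change = tc,
                 span = range(span),
                 ci95_total_change = c(tc - tcrit * se * span_w,
                                       tc + tcrit * se * span_w),
                 fit = fit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Linear trend: slope %.4g /yr (SE %.3g), p = %.3g, N = %d\n",
    x$slope, x$slope_se, x$p_two_sided, x$n_years))
  cat(sprintf("  total change over %d-%d: %+.3g (95%% CI %.3g to %.3g)\n",
              x$span[1], x$span[2], x$total_change,
              x$ci95_total_change[1], x$ci95_total_change[2]))
  invisible(x)
}

#' Contrast an annual variable between two epochs
#'
#' Epoch A is years at or before `split_year` ("including and preceding"),
#' epoch B is years after it. Tests: Welch's t (`welch_t`), Mann-Whitney
#' (`mann_whitney`), Spearman rank correlation of the variable against year
#' over the whole record (`spearman_trend`, a monotone-trend test rather than
#' an epoch contrast), and a two-proportion z-test (`two_proportion_z`) on a
#' binary predicate of the variable (e.g. negligible April snow, < 2 cm).
#'
#' @param values annual values; NA years are dropped.
#' @param years calendar years.
#' @param split_year epoch boundary (default 1955).
#' @param test one of `"welch_t"`, `"mann_whitney"`, `"spearman_trend"`,
#'   `"two_proportion_z"`.
#' @param predicate for `two_proportion_z`: function mapping values to
#'   logical, default `function(v) v < 2` (negligible snowpack, cm).
#' @return An `epoch_comparison` list: `test`, `p_two_sided`, `statistic`,
#'   `n_a`, `n_b`, and per-epoch summaries.
#' @export
compare_epochs <- function(values, years, split_year = 1955,
                           test = c("welch_t", "mann_whitney",
                                    "spearman_trend", "two_proportion_z"),
                           predicate = function(v) v < 2) {
  test <- match.arg(test)
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]; years <- years[ok]
  a <- values[years <= split_year]
  b <- values[years > split_year]
  if (length(a) == 0 || length(b) == 0)
    stop_validation("both epochs must contain at least one included year")
  res <- switch(test,
    welch_t = {
      ht <- t.test(b, a, var.equal = FALSE)
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    mann_whitney = {
      ht <- suppressWarnings(wilcox.test(b, a, exact = (length(a) +
        length(b)) <= 50 && !anyDuplicated(c(a, b))))
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    spearman_trend = {
      ht <- suppressWarnings(cor.test(values, years, method = "spearman"))
      list(statistic = unname(ht$estimate), p = ht$p.value)
    },
    two_proportion_z = {
      xa <- predicate(a); xb <- predicate(b)
      p1 <- mean(xa); p2 <- mean(xb)
      pp <- mean(c(xa, xb))
      se <- sqrt(pp * (1 - pp) * (1 / length(xa) + 1 / length(xb)))
      z <- if (se == 0) 0 else (p2 - p1) / se
      list(statistic = z, p = 2 * pnorm(-abs(z)),
           prop_a = p1, prop_b = p2)
    })
  structure(c(list(test = test, split_year = split_year,
                   n_a = length(a), n_b = length(b),
                   mean_a = mean(a), mean_b = mean(b),
                   p_two_sided = res$p), res[setdiff(names(res), "p")]),
            class = "epoch_comparison")
}

#' Compare two fitted trend slopes
#'
#' Welch-style t-test on two independent slope estimates using their
#' standard errors, with Welch-Satterthwaite degrees of freedom from the two
#' regressions' residual dfs (normal reference if dfs are unavailable).
#'
#' @param trend_a,trend_b `trend_result` objects from [fit_trend()].
#' @return List with `statistic`, `df`, `p_two_sided`, `slope_diff`.
#' @export
compare_slopes <- function(trend_a, trend_b) {
  se1 <- trend_a$slope_se; se2 <- trend_b$slope_se
  if ((is.na(se1) || se1 == 0) && (is.na(se2) || se2 == 0))
    stop_validation("both slope standard errors are zero; test undefined")
  d <- trend_a$slope - trend_b$slope
  se <- sqrt(se1^2 + se2^2)
  t <- d / se
  df1 <- trend_a$fit$df.residual %||% Inf
  df2 <- trend_b$fit$df.residual %||% Inf
  df <- (se1^2 + se2^2)^2 / (se1^4 / df1 + se2^4 / df2)
  if (!is.finite(df)) df <- Inf
  p <- if (is.finite(df)) 2 * pt(-abs(t), df) else 2 * pnorm(-abs(t))
  list(statistic = t, df = df, p_two_sided = p, slope_diff = d)
}

#' Delta-method temperature offset between two periods
#'
#' The delta method reconstructs a past climate grid by shifting a current
#' grid with the station-observed mean difference between a historical and a
#' base period: `offset = mean(hist years) - mean(base years)` of the chosen
#' annual variable over included years. Adding the offset to a current-period
#' surface yields the historical surface.
#'
#' @param annual an `annual_climate` table from [summarize_years()].
#' @param variable `"mst"` or `"mat"`.
#' @param base_period,hist_period two-element year ranges (inclusive).
#' @return Offset in degrees C (negative when the past was cooler).
#' @export
delta_offset <- function(annual, variable = c("mst", "mat"),
                         base_period = c(2001, 2010),
                         hist_period = c(1910, 1955)) {
  variable <- match.arg(variable)
  inc <- if (variable == "mst") annual$included_summer else
    annual$included_annual
  v <- annual[[variable]]
  in_base <- inc & annual$year >= base_period[1] & annual$year <= base_period[2]
  in_hist <- inc & annual$year >= hist_period[1] & annual$year <= hist_period[2]
  if (!any(in_base) || !any(in_hist))
    stop_validation("each period needs at least one included year")
  mean(v[in_hist]) - mean(v[in_base])
}
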