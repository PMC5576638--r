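#' Daily weather series container
#'
#' @param date Date vector, unique.
#' @param tmax,tmin daily extremes in degrees C; NA where unrecorded.
#' @param snow_depth snow depth in cm; NA where unrecorded.
#' @return A `daily_weather` data frame sorted by date.
#' @export
daily_weather <- function(date, tmax, tmin, snow_depth = NA_real_) {
  date <- as.Date(date)
  if (anyDuplicated(date)) stop_validation("dates must be unique")
  bad <- !is.na(tmax) & !is.na(tmin) & tmin > tmax
  if (any(bad))
    stop_validation("tmin exceeds tmax on ", sum(bad), " day(s)")
  df <- data.frame(date = date, tmax = as.numeric(tmax),
                   tmin = as.numeric(tmin),
                   snow_depth = rep_len(as.numeric(snow_depth), length(date)))
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("daily_weather", "data.frame")
  df
}

#' Read a GHCN-daily-style long CSV
#'
#' Expects columns `station`, `date`, `element`, `value` with elements
#' TMAX/TMIN in tenths of degrees C and SNWD (snow depth) in mm, the GHCN
#' convention; converts to degrees C and cm. A wide CSV with `date`, `tmax`,
#' `tmin`, `snow_depth` columns already in C/cm is also accepted.
#'
#' @param path CSV path.
#' @param station optional station id filter for long-format files.
#' @return A [daily_weather()].
#' @export
read_ghcn_daily <- function(path, station = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("element", "value") %in% names(df))) {
    if (!is.null(station) && "station" %in% names(df))
      df <- df[df$station == station, , drop = FALSE]
    df$date <- as.Date(as.character(df$date), tryFormats =
                         c("%Y-%m-%d", "%Y%m%d"))
    wide <- data.frame(date = sort(unique(df$date)))
    pick <- function(el, scale) {
      v <- df[df$element == el, c("date", "value")]
      out <- v$value[match(wide$date, v$date)] * scale
      out
    }
    wide$tmax <- pick("TMAX", 0.1)
    wide$tmin <- pick("TMIN", 0.1)
    wide$snow_depth <- pick("SNWD", 0.1)  # mm -> cm
    daily_weather(wide$date, wide$tmax, wide$tmin, wide$snow_depth)
  } else if (all(c("date", "tmax", "tmin") %in% names(df))) {
    daily_weather(as.Date(df$date), df$tmax, df$tmin,
                  df$snow_depth %||% NA_real_)
  } else {
    stop_validation("unrecognised daily-weather file layout: ", path)
  }
}

#' Write a daily weather series as a wide CSV (degrees C, cm)
#' @param series a [daily_weather()].
#' @param path output path.
#' @export
write_daily_weather <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Linearly impute missing daily values
#'
#' Gaps strictly between recorded days are filled by linear interpolation in
#' time; leading and trailing gaps are left missing; recorded values are
#' never modified (the operation is idempotent). Pre-imputation missingness
#' is recorded in logical `*_imputed` columns so annual QC can count missing
#' days before imputation.
#'
#' @param series a [daily_weather()].
#' @param variables columns to impute.
#' @return The series with gaps filled and `*_imputed` flag columns.
#' @export
impute_daily <- function(series,
                         variables = c("tmax", "tmin", "snow_depth")) {
  t <- as.numeric(series$date)
  for (v in intersect(variables, names(series))) {
    flag <- paste0(v, "_imputed")
    if (is.null(series[[flag]])) series[[flag]] <- FALSE
    obs <- !is.na(series[[v]]) & !series[[flag]]
    if (sum(obs) < 2) {
      attr(series, paste0(v, "_unimputable")) <- TRUE
      next
    }
    filled <- approx(t[obs], series[[v]][obs], xout = t, rule = 1)$y
    newly <- is.na(series[[v]]) & !is.na(filled)
    series[[v]][newly] <- filled[newly]
    series[[flag]] <- series[[flag]] | newly
  }
  series
}

#' Annual climate summaries with missing-day QC
#'
#' Computes, per calendar year: mean annual temperature (MAT, the mean of
#' daily `(tmax + tmin) / 2`), mean summer temperature (MST, the same over
#' June 1 - August 31), and an April snow-depth statistic. Missing days are
#' counted BEFORE imputation (days absent from the record or lacking either
#' temperature extreme); a year is included for annual analyses when it has
#' fewer than 15 missing days and for summer analyses when the summer window
#' has fewer than 10.
#'
#' @param series a [daily_weather()], normally after [impute_daily()].
#' @param april_snow_stat `"mean"` of daily April readings (default) or
#'   `"first"` (the April 1 reading).
#' @param exclude_years optional explicit year-exclusion list applied on top
#'   of the automatic missing-day rule (both inclusion flags forced FALSE).
#' @return An `annual_climate` data frame: `year`, `mat`, `mst`,
#'   `april_snow`, `missing_annual`, `missing_summer`, `included_annual`,
#'   `included_summer`.
#' @export
summarize_years <- function(series, april_snow_stat = c("mean", "first"),
                            exclude_years = integer()) {
  april_snow_stat <- match.arg(april_snow_stat)
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  tmean <- (series$tmax + series$tmin) / 2
  imput <- (series$tmax_imputed %||% rep(FALSE, nrow(series))) |
    (series$tmin_imputed %||% rep(FALSE, nrow(series)))
  recorded <- !is.na(tmean) & !imput
  years <- sort(unique(yr))
  summer_len <- function(y) 30L + 31L + 31L
  out <- lapply(years, function(y) {
    in_y <- yr == y
    in_s <- in_y & mo %in% 6:8
    miss_a <- days_in_year(y) - sum(recorded & in_y)
    miss_s <- summer_len(y) - sum(recorded & in_s)
    apr <- series$snow_depth[in_y & mo == 4]
    apr_dates <- series$date[in_y & mo == 4]
    april_snow <- if (length(apr) == 0 || all(is.na(apr))) NA_real_
      else if (april_snow_stat == "mean") mean(apr, na.rm = TRUE)
      else apr[order(apr_dates)][1]
    data.frame(year = y,
               mat = mean(tmean[in_y], na.rm = TRUE),
               mst = if (any(in_s)) mean(tmean[in_s], na.rm = TRUE)
                     else NA_real_,
               april_snow = april_snow,
               missing_annual = miss_a, missing_summer = miss_s)
  })
  out <- do.call(rbind, out)
  out$included_annual <- out$missing_annual < 15 &
    !out$year %in% exclude_years & is.finite(out$mat)
  out$included_summer <- out$missing_summer < 10 &
    !out$year %in% exclude_years & is.finite(out$mst)
  class(out) <- c("annual_climate", "data.frame")
  out
}
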