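#' Construct a calibration curve
#'
#' A calibration curve tabulates the expected Fraction Modern (Fm) of
#' atmospheric carbon against calendar year, with a 1-sigma uncertainty on the
#' curve value. Pre-bomb segments (conventional IntCal-style tables) and a
#' post-bomb segment covering the atmospheric bomb spike are distinguished by
#' `segment`.
#'
#' @param calendar_year numeric, calendar years AD, strictly increasing after
#'   construction (rows are sorted).
#' @param curve_fm expected Fm at each year.
#' @param curve_sigma 1-sigma uncertainty of `curve_fm`; must be positive.
#' @param segment character, `"pre-bomb"` or `"post-bomb"` per row.
#' @return A `calibration_curve`, a data frame with columns
#'   `calendar_year`, `curve_fm`, `curve_sigma`, `segment`.
#' @export
calibration_curve <- function(calendar_year, curve_fm, curve_sigma,
                              segment = "pre-bomb") {
  df <- data.frame(calendar_year = as.numeric(calendar_year),
                   curve_fm = as.numeric(curve_fm),
                   curve_sigma = as.numeric(curve_sigma),
                   segment = rep_len(as.character(segment),
                                     length(calendar_year)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$calendar_year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("calibration_curve", "data.frame")
  validate_curve(df)
  df
}

validate_curve <- function(curve) {
  if (anyDuplicated(curve$calendar_year))
    stop_validation("calibration curve has duplicate calendar years")
  if (is.unsorted(curve$calendar_year, strictly = TRUE))
    stop_validation("calendar years must be strictly increasing")
  if (any(!is.finite(curve$curve_sigma)) || any(curve$curve_sigma <= 0))
    stop_validation("curve_sigma must be positive everywhere")
  if (!all(curve$segment %in% c("pre-bomb", "post-bomb")))
    stop_validation("segment labels must be 'pre-bomb' or 'post-bomb'")
  invisible(curve)
}

#' Read a calibration-curve CSV
#'
#' Accepts IntCal-style tables carrying conventional radiocarbon ages
#' (`unit_convention = "c14_age"`, converted to Fm via
#' `Fm = exp(-age / 8033)`, the Libby mean-life convention; the sigma column
#' is propagated through the same transform) and post-bomb F14C tables
#' (`unit_convention = "fm"`). Expected columns: `calendar_year`, `value`,
#' `sigma`, and optionally `segment`.
#'
#' @param path CSV file path.
#' @param unit_convention `"fm"` or `"c14_age"`.
#' @param segment default segment label when the file has no `segment` column.
#' @return A [calibration_curve()].
#' @export
read_curve <- function(path, unit_convention = c("fm", "c14_age"),
                       segment = "pre-bomb") {
  unit_convention <- match.arg(unit_convention)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("calendar_year", "value", "sigma")
  if (!all(need %in% names(df)))
    stop_validation("curve file must have columns: ",
                    paste(need, collapse = ", "))
  if (unit_convention == "c14_age") {
    fm <- exp(-df$value / 8033)
    # first-order error propagation: sigma_fm = Fm * sigma_age / 8033
    sig <- fm * df$sigma / 8033
  } else {
    fm <- df$value
    sig <- df$sigma
  }
  calibration_curve(df$calendar_year, fm, sig,
                    segment = df$segment %||% segment)
}

#' Write a calibration curve to CSV
#'
#' @param curve a [calibration_curve()].
#' @param path output path. Values are written in Fm units (`unit = "fm"`).
#' @export
write_curve <- function(curve, path) {
  out <- data.frame(calendar_year = curve$calendar_year,
                    value = curve$curve_fm, sigma = curve$curve_sigma,
                    segment = curve$segment, unit = "fm")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Append a post-bomb segment to a pre-bomb calibration curve
#'
#' Joins two curve segments into one table. Where the tabulated years
#' overlap, the post-bomb segment takes precedence: pre-bomb rows at or after
#' the post-bomb segment's first year are dropped.
#'
#' @param pre_bomb,post_bomb [calibration_curve()] objects.
#' @return A single [calibration_curve()] spanning both segments.
#' @export
append_curves <- function(pre_bomb, post_bomb) {
  validate_curve(pre_bomb); validate_curve(post_bomb)
  cut <- min(post_bomb$calendar_year)
  keep <- pre_bomb[pre_bomb$calendar_year < cut, , drop = FALSE]
  out <- rbind(as.data.frame(keep), as.data.frame(post_bomb))
  calibration_curve(out$calendar_year, out$curve_fm, out$curve_sigma,
                    out$segment)
}

# Linear interpolation of curve mean and sigma onto an arbitrary year grid.
interp_curve <- function(curve, years) {
  list(fm = approx(curve$calendar_year, curve$curve_fm, xout = years,
                   rule = 1)$y,
       sigma = approx(curve$calendar_year, curve$curve_sigma, xout = years,
                      rule = 1)$y)
}
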