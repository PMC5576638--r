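#' Synthetic-world scenario
#'
#' Bundles the parameters of the synthetic inputs the pipeline consumes.
#' Defaults describe a Tahoe-like stated world: a 1910-2015 station record
#' warming at 1.9 degrees C per century with sd 0.5 degrees C annual noise
#' and 15% missing days; a calibration curve with a 0.98 Fm pre-bomb plateau
#' and a +0.8 bomb spike beginning 1955; a 270-m mountainous MST grid with a
#' 6.5e-3 degrees C/m lapse rate; and occupancy generated from a logistic
#' model on refugial MST at a true dispersal radius of 4 km.
#'
#' @param seed integer; every stochastic generator derives from it.
#' @param years calendar-year range of the weather record.
#' @param warming_rate warming in degrees C per century.
#' @param noise_sd sd of daily temperature noise (degrees C).
#' @param missing_day_rate fraction of days missing per year, in `[0, 1)`.
#' @param curve_spec list: `years`, `plateau_fm`, `spike_year`, `amplitude`,
#'   `rise_years`, `decay_years`, `sigma_pre`, `sigma_post`.
#' @param grid_spec list: `nx`, `ny`, `cellsize` (m), `base_temp` (degrees C
#'   at zero elevation), `lapse_rate` (degrees C per m), `relief_m`,
#'   `n_bumps` (sparse cold pools give radii their distinct signals),
#'   `noise_sd`, `xll`, `yll`.
#' @param occupancy_spec list: `beta0`, `beta1` (logistic intercept and slope
#'   on refugial MST), `n_sites`, `true_radius_km`.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1,
                               years = c(1910, 2015),
                               warming_rate = 1.9,
                               noise_sd = 0.5,
                               missing_day_rate = 0.15,
                               curve_spec = list(),
                               grid_spec = list(),
                               occupancy_spec = list()) {
  if (missing_day_rate < 0) stop_validation("missing_day_rate must be >= 0")
  curve_spec <- modifyList(list(years = c(1650, 2015), plateau_fm = 0.98,
                                spike_year = 1955, amplitude = 0.8,
                                rise_years = 9, decay_years = 16,
                                sigma_pre = 0.002, sigma_post = 0.004),
                           curve_spec)
  grid_spec <- modifyList(list(nx = 110, ny = 110, cellsize = 270,
                               base_temp = 17, lapse_rate = 6.5e-3,
                               relief_m = 900, n_bumps = 45,
                               noise_sd = 0.1, xll = 0, yll = 0),
                          grid_spec)
  occupancy_spec <- modifyList(list(beta0 = 20, beta1 = -1.4,
                                    n_sites = 200, true_radius_km = 4),
                              occupancy_spec)
  structure(list(seed = as.integer(seed), years = years,
                 warming_rate = warming_rate, noise_sd = noise_sd,
                 missing_day_rate = missing_day_rate,
                 curve_spec = curve_spec, grid_spec = grid_spec,
                 occupancy_spec = occupancy_spec),
            class = "synthetic_scenario")
}

#' Synthetic bomb-spike calibration curve
#'
#' Pre-spike years carry a flat plateau (tabulated at 1-yr steps); from the
#' spike year the curve rises as a smooth sigmoid-in-sine ramp over
#' `rise_years` to `plateau + amplitude`, then decays exponentially with
#' e-folding `decay_years` (tabulated at 0.5-yr steps) — an asymmetric pulse
#' whose post-peak branch re-crosses every post-spike Fm level once, so
#' post-bomb measurements calibrate to two-branch (bimodal) solutions, as on
#' the real atmospheric curve.
#'
#' @param curve_spec as in [synthetic_scenario()] (`scenario$curve_spec`).
#' @return A [calibration_curve()] with pre- and post-bomb segments.
#' @export
make_calibration_curve <- function(curve_spec) {
  cs <- synthetic_scenario(curve_spec = curve_spec)$curve_spec
  y0 <- cs$years[1]; y1 <- cs$years[2]
  if (cs$spike_year <= y0 || cs$spike_year >= y1)
    stop_validation("spike year must lie inside the curve's year range")
  pre_years <- seq(y0, cs$spike_year - 1, by = 1)
  post_years <- seq(cs$spike_year, y1, by = 0.5)
  peak <- cs$spike_year + cs$rise_years
  post_fm <- ifelse(post_years <= peak,
    cs$plateau_fm + cs$amplitude *
      sin(pi / 2 * (post_years - cs$spike_year) / cs$rise_years)^2,
    cs$plateau_fm + cs$amplitude * exp(-(post_years - peak) / cs$decay_years))
  pre <- calibration_curve(pre_years, rep(cs$plateau_fm, length(pre_years)),
                           rep(cs$sigma_pre, length(pre_years)), "pre-bomb")
  post <- calibration_curve(post_years, post_fm,
                            rep(cs$sigma_post, length(post_years)),
                            "post-bomb")
  append_curves(pre, post)
}

#' Synthetic daily station record
#'
#' Daily mean temperature = annual base + linear warming trend (by calendar
#' year, so noiseless annual means recover the slope exactly) + a seasonal
#' cosine that sums to exactly zero over each year + Gaussian noise; tmax and
#' tmin sit half a diurnal range either side. Snow depth follows a seasonal
#' pulse peaking around the start of March with a declining year factor, so
#' late-record Aprils can drop to negligible (< 2 cm) depth. A seeded
#' fraction of days is marked missing.
#'
#' @param scenario a [synthetic_scenario()].
#' @param diurnal_range tmax - tmin (degrees C).
#' @param seasonal_amp seasonal half-amplitude of daily means (degrees C).
#' @param base_mat mean annual temperature in the first year (degrees C).
#' @param snow_base peak snow depth in the first year (cm).
#' @param snow_decline fractional decline in the snow year-factor per
#'   century (1 = linear decline to zero over 100 yr).
#' @return A [daily_weather()].
#' @export
make_daily_weather <- function(scenario, diurnal_range = 12,
                               seasonal_amp = 9, base_mat = 6,
                               snow_base = 90, snow_decline = 0.85) {
  if (scenario$missing_day_rate < 0)
    stop_validation("missing_day_rate must be >= 0")
  y0 <- scenario$years[1]; y1 <- scenario$years[2]
  if (y1 < y0) stop_validation("empty year range")
  dates <- seq(as.Date(paste0(y0, "-01-01")),
               as.Date(paste0(y1, "-12-31")), by = "day")
  year <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  nd <- days_in_year(year)
  season <- -seasonal_amp * cos(2 * pi * (doy - 14.5) / nd)
  trend <- scenario$warming_rate / 100 * (year - y0)
  with_seed(scenario$seed, {
    tmean <- base_mat + trend + season +
      rnorm(length(dates), sd = scenario$noise_sd)
    snow_season <- pmax(0, cos(2 * pi * (doy - 60) / nd))^2
    year_factor <- pmax(0, 1 - snow_decline / 100 * (year - y0))
    snow <- pmax(0, snow_base * snow_season * year_factor +
                   rnorm(length(dates), sd = 3) * (snow_season > 0))
    miss <- runif(length(dates)) < scenario$missing_day_rate
  })
  tmax <- tmean + diurnal_range / 2
  tmin <- tmean - diurnal_range / 2
  tmax[miss] <- NA; tmin[miss] <- NA; snow[miss] <- NA
  daily_weather(dates, tmax, tmin, snow)
}

#' Synthetic mean-summer-temperature grid
#'
#' Elevation is a sum of sparse Gaussian peaks ("cold pools") over a flat
#' base; MST = `base_temp - lapse_rate * elevation + smooth noise`, on a
#' projected metre grid. Sparse narrow peaks make the refugial minimum
#' within r km genuinely change with r, which is what gives dispersal-radius
#' model selection its signal.
#'
#' @param grid_spec as in [synthetic_scenario()] (`scenario$grid_spec`).
#' @param seed RNG seed (defaults to 1; pass the scenario seed).
#' @param elevation optional explicit elevation matrix overriding the
#'   synthetic terrain.
#' @return List with `mst` and `elevation`, both [climate_grid()]s.
#' @export
make_temperature_grid <- function(grid_spec, seed = 1, elevation = NULL) {
  gs <- synthetic_scenario(grid_spec = grid_spec)$grid_spec
  if (gs$nx <= 0 || gs$ny <= 0 || gs$cellsize <= 0)
    stop_validation("grid extent and cell size must be positive")
  nx <- gs$nx; ny <- gs$ny
  cx <- (seq_len(nx) - 0.5) * gs$cellsize
  cy <- (seq_len(ny) - 0.5) * gs$cellsize
  if (is.null(elevation)) {
    elev <- matrix(0, ny, nx)
    if (gs$n_bumps > 0 && gs$relief_m > 0) {
      with_seed(seed, {
        bx <- runif(gs$n_bumps, 0, nx * gs$cellsize)
        by <- runif(gs$n_bumps, 0, ny * gs$cellsize)
        bh <- runif(gs$n_bumps, 0.3, 1) * gs$relief_m
        bw <- runif(gs$n_bumps, 1.5, 4) * gs$cellsize
      })
      for (b in seq_len(gs$n_bumps)) {
        dx2 <- outer(rep(1, ny), (cx - bx[b])^2)
        dy2 <- outer((rev(cy) - by[b])^2, rep(1, nx))
        elev <- pmax(elev, bh[b] * exp(-(dx2 + dy2) / (2 * bw[b]^2)))
      }
    }
  } else {
    elev <- as.matrix(elevation)
    if (!all(dim(elev) == c(ny, nx)))
      stop_validation("elevation matrix must be ny x nx")
  }
  with_seed(seed + 1L, {
    noise <- if (gs$noise_sd > 0)
      matrix(rnorm(ny * nx, sd = gs$noise_sd), ny, nx) else 0
  })
  mst <- gs$base_temp - gs$lapse_rate * elev + noise
  list(mst = climate_grid(mst, gs$xll, gs$yll, gs$cellsize),
       elevation = climate_grid(elev, gs$xll, gs$yll, gs$cellsize))
}

#' Synthetic survey sites with model-generated occupancy
#'
#' Sites are scattered uniformly over the grid (one cell in from the edge);
#' the refugial MST at the true dispersal radius is computed from the grid,
#' and occupancy is drawn Bernoulli with
#' `p = plogis(beta0 + beta1 * mst_min)`. Each site receives a square talus
#' polygon of known (lognormal) area placed fully inside its 1-km disk, so
#' `talus_area_1km` is exact by construction.
#'
#' @param occupancy_spec as in [synthetic_scenario()]
#'   (`scenario$occupancy_spec`).
#' @param grid MST [climate_grid()] (e.g. `make_temperature_grid(...)$mst`).
#' @param seed RNG seed.
#' @param radii radii (km) at which `mst_min_<r>k` columns are computed.
#' @param talus generate talus polygons (disable for very large n).
#' @return Data frame of sites with `site_id`, `x`, `y`, `occupancy`,
#'   `p_true`, `mst_min_<r>k`, and (if `talus`) `talus_area_1km`,
#'   `log_talus_area`; polygons in `attr(, "talus")`.
#' @export
make_sites_with_occupancy <- function(occupancy_spec, grid, seed = 1,
                                      radii = 1:5, talus = TRUE) {
  os <- synthetic_scenario(occupancy_spec = occupancy_spec)$occupancy_spec
  n <- os$n_sites
  w <- ncol(grid$values) * grid$cellsize
  h <- nrow(grid$values) * grid$cellsize
  with_seed(seed, {
    x <- grid$xll + runif(n, grid$cellsize, w - grid$cellsize)
    y <- grid$yll + runif(n, grid$cellsize, h - grid$cellsize)
    side <- sqrt(exp(rnorm(n, mean = 9.2, sd = 0.8)))
    offr <- runif(n, 0, pmax(0, 1000 - side / sqrt(2) - 1))
    offa <- runif(n, 0, 2 * pi)
    u_occ <- runif(n)
  })
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n)), x = x, y = y,
                      stringsAsFactors = FALSE)
  sites <- add_site_predictors(sites, grid, talus = NULL, radii =
                                 sort(unique(c(radii, os$true_radius_km))))
  mst_true <- sites[[paste0("mst_min_", os$true_radius_km, "k")]]
  p <- plogis(os$beta0 + os$beta1 * mst_true)
  sites$p_true <- p
  sites$occupancy <- ifelse(u_occ < p, "extant", "extirpated")
  if (talus) {
    cxs <- x + offr * cos(offa); cys <- y + offr * sin(offa)
    polys <- lapply(seq_len(n), function(i) {
      s <- side[i]
      cbind(c(-1, 1, 1, -1) * s / 2 + cxs[i],
            c(-1, -1, 1, 1) * s / 2 + cys[i])
    })
    sites$talus_area_1km <- side^2
    sites$log_talus_area <- log_talus_area(side^2)
    attr(sites, "talus") <- polys
  }
  sites
}

#' Synthetic pellet Fm measurements from known deposit years
#'
#' Looks up the curve Fm at each (average) deposit year and adds Gaussian
#' analytical error, giving measurements whose true calendar ages are known
#' — the ground truth for calibration-coverage checks.
#'
#' @param curve a [calibration_curve()].
#' @param deposit_years true average deposit years.
#' @param fm_sigma analytical 1-sigma (recycled).
#' @param seed RNG seed.
#' @return A [radiocarbon_measurement()] data frame with a `true_year`
#'   column.
#' @export
make_pellet_measurements <- function(curve, deposit_years, fm_sigma = 0.004,
                                     seed = 1) {
  ci <- interp_curve(curve, deposit_years)
  fm_sigma <- rep_len(fm_sigma, length(deposit_years))
  with_seed(seed, {
    fm <- rnorm(length(deposit_years), ci$fm, fm_sigma)
  })
  m <- radiocarbon_measurement(sprintf("P%02d", seq_along(deposit_years)),
                               fm = pmax(fm, 1e-6), fm_sigma = fm_sigma)
  m$true_year <- deposit_years
  m
}

#' Write every synthetic pipeline input to a directory
#'
#' Emits the file formats the real pipeline reads: calibration-curve CSV,
#' measurement CSV, daily-weather CSV, MST ASCII grid, talus GeoJSON, site
#' CSV, and a pipeline config JSON wired to them.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of paths (the config as `$config`).
#' @export
write_scenario_inputs <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  curve <- make_calibration_curve(scenario$curve_spec)
  write_curve(curve, p("curve.csv"))
  meas <- make_pellet_measurements(curve,
    deposit_years = seq(1930, 1990, by = 10), seed = scenario$seed)
  write.csv(as.data.frame(meas), p("measurements.csv"), row.names = FALSE)
  write_daily_weather(make_daily_weather(scenario), p("daily.csv"))
  tg <- make_temperature_grid(scenario$grid_spec, seed = scenario$seed)
  write_ascii_grid(tg$mst, p("mst.asc"))
  sites <- make_sites_with_occupancy(scenario$occupancy_spec, tg$mst,
                                     seed = scenario$seed)
  write_talus_geojson(attr(sites, "talus"), p("talus.geojson"))
  write.csv(sites[, c("site_id", "x", "y", "occupancy")], p("sites.csv"),
            row.names = FALSE)
  cfg <- list(seed = scenario$seed,
              curve = p("curve.csv"), measurements = p("measurements.csv"),
              daily = p("daily.csv"), grid = p("mst.asc"),
              sites = p("sites.csv"), talus = p("talus.geojson"),
              split_year = 1955, radii = 1:5, dispersal_km =
                scenario$occupancy_spec$true_radius_km,
              scenarios = list(historical = -1.45, current = 0,
                               `2030` = 1.33, `2050` = 2.74))
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(lapply(cfg[c("curve", "measurements", "daily", "grid",
                           "sites", "talus")], identity),
              list(config = p("config.json"))))
}
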