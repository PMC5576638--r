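#' Pipeline configuration
#'
#' Loads and validates the flat per-stage configuration. All referenced
#' input files must exist at validation time; the seed is recorded in every
#' report. CLI flags override config values.
#'
#' @param path JSON config path, or a list of the same shape.
#' @param overrides named list of overrides (e.g. from CLI flags).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path, overrides = list()) {
  if (is.character(path) && !file.exists(path))
    stop_validation("config file does not exist: ", path)
  cfg <- if (is.character(path)) jsonlite::read_json(path,
    simplifyVector = TRUE) else path
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  defaults <- list(split_year = 1955, radii = 1:5, mass = 0.95,
                   dispersal_km = 4, threshold = NULL, seed = 1,
                   scenarios = list(current = 0),
                   prior_model = NULL)
  cfg <- modifyList(defaults, cfg)
  for (key in c("curve", "measurements", "daily", "grid", "sites",
                "talus")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop_validation("configured ", key, " file does not exist: ",
                      cfg[[key]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes calibrate -> trends -> occupancy -> project on the configured
#' inputs and returns one structured report: calibrated 95% ranges, the
#' trend table and epoch contrasts, the AICc model-comparison table with the
#' best model's 0.5-probability threshold, the exact binomial comparison to
#' a prior model (when prior coefficients are configured), and per-scenario
#' area summaries. Stages whose inputs are not configured are skipped and
#' recorded as such. Any stage failure aborts with a stage-labelled error.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus a human-readable `report.txt`.
#' @return The report, a `pipeline_report` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  report <- list(seed = config$seed,
                 config_hash = config_hash(config), stages = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$curve) && !is.null(config$measurements)) {
    report$calibration <- stage("calibrate", {
      curve <- read_curve(config$curve)
      meas <- read_measurements(config$measurements)
      dens <- calibrate_all(meas, curve, mass = config$mass)
      lapply(dens, function(d)
        list(ranges95 = d$ranges95, out_of_range = d$out_of_range))
    })
    report$stages <- c(report$stages, "calibrate")
  }

  if (!is.null(config$daily)) {
    report$trends <- stage("trends", {
      daily <- impute_daily(read_ghcn_daily(config$daily))
      annual <- summarize_years(daily,
        exclude_years = config$exclude_years %||% integer())
      # QC-included years where possible; on heavily gappy (but imputed)
      # records where <3 years pass the missing-day rule, fall back to all
      # years with finite means and record the fallback.
      inc_a <- if (sum(annual$included_annual) >= 3) annual$included_annual
               else is.finite(annual$mat)
      inc_s <- if (sum(annual$included_summer) >= 3) annual$included_summer
               else is.finite(annual$mst)
      mat_t <- fit_trend(annual$mat[inc_a], annual$year[inc_a])
      mst_t <- fit_trend(annual$mst[inc_s], annual$year[inc_s])
      relaxed <- annual
      relaxed$included_annual <- inc_a
      relaxed$included_summer <- inc_s
      list(annual = annual, qc_fallback = !identical(inc_a,
             annual$included_annual),
           mat = mat_t[c("slope", "slope_se", "p_two_sided", "n_years",
                         "total_change")],
           mst = mst_t[c("slope", "slope_se", "p_two_sided", "n_years",
                         "total_change")],
           mat_epochs = compare_epochs(annual$mat[inc_a],
             annual$year[inc_a],
             config$split_year, "welch_t")[c("p_two_sided", "n_a", "n_b")],
           snow_negligible = compare_epochs(
             annual$april_snow, annual$year, config$split_year,
             "two_proportion_z")[c("p_two_sided", "prop_a", "prop_b")],
           delta_offset_mst = tryCatch(delta_offset(annual, "mst"),
             error = function(e) {
               # strict QC left a period empty; fall back to all finite years
               relaxed$included_summer <- is.finite(annual$mst)
               delta_offset(relaxed, "mst")
             }))
    })
    report$stages <- c(report$stages, "trends")
  }

  grid <- NULL
  if (!is.null(config$grid)) grid <- read_ascii_grid(config$grid)

  if (!is.null(config$sites) && !is.null(grid)) {
    report$occupancy <- stage("occupancy", {
      sites <- read_sites(config$sites)
      talus <- if (!is.null(config$talus))
        read_talus_geojson(config$talus) else NULL
      sites <- spatial_thin(sites, config$thin_dist_m %||% 250,
                            seed = config$seed)
      sites <- add_site_predictors(sites, grid, talus,
                                   radii = config$radii)
      cmp <- rank_models(sites, radii = config$radii,
                         with_talus = !is.null(talus))
      best <- attr(cmp, "models")[[cmp$model[1]]]
      thr <- if (best$k == 2) occupancy_threshold(best) else NA_real_
      prior <- NULL
      if (!is.null(config$prior_model)) {
        pm <- config$prior_model
        eta <- pm$intercept + pm$beta_log_talus * sites$log_talus_area +
          pm$beta_mst_1km * sites$mst_min_1k
        pp <- plogis(eta)
        prior <- list(
          binomial = binomial_extirpation_test(sites$occupancy, pp),
          rates = classification_rates(sites$occupancy, pp))
      }
      list(n_sites = nrow(sites), comparison = as.data.frame(cmp),
           best_model = cmp$model[1],
           best_coefficients = as.list(best$coefficients),
           separation = best$separation, threshold = thr, prior = prior)
    })
    report$stages <- c(report$stages, "occupancy")
  }

  if (!is.null(grid)) {
    report$projection <- stage("project", {
      thr <- config$threshold %||% report$occupancy$threshold %||% 14.2
      if (!is.finite(thr)) thr <- 14.2
      as.data.frame(area_summary(grid, unlist(config$scenarios),
                                 threshold = thr,
                                 dispersal_km = config$dispersal_km))
    })
    report$stages <- c(report$stages, "project")
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, force = TRUE)
  # small stable polynomial hash; enough to tie outputs to their config
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (!is.null(attr(x, "class")) && is.data.frame(x)) {
    x <- as.data.frame(x)
  }
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("taluscape pipeline report (seed ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  cat("stages run:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$calibration)) {
    cat("\n-- calibrated 95% ranges --\n")
    for (nm in names(x$calibration)) {
      r <- x$calibration[[nm]]$ranges95
      cat(" ", nm, ": ", paste(sprintf("%.1f-%.1f", r$start_year,
                                       r$end_year), collapse = ", "),
          "\n", sep = "")
    }
  }
  if (!is.null(x$trends)) {
    cat("\n-- station trends --\n")
    cat(sprintf("  MAT: %+.2f C over record (p = %.2g, N = %d)\n",
                x$trends$mat$total_change, x$trends$mat$p_two_sided,
                x$trends$mat$n_years))
    cat(sprintf("  MST: %+.2f C over record (p = %.2g, N = %d)\n",
                x$trends$mst$total_change, x$trends$mst$p_two_sided,
                x$trends$mst$n_years))
    cat(sprintf("  delta offset (hist - base, MST): %+.2f C\n",
                x$trends$delta_offset_mst))
  }
  if (!is.null(x$occupancy)) {
    cat("\n-- occupancy model selection --\n")
    print(head(x$occupancy$comparison, 3))
    cat(sprintf("  best: %s  (threshold %.2f C%s)\n",
                x$occupancy$best_model, x$occupancy$threshold,
                if (x$occupancy$separation) ", complete separation" else ""))
  }
  if (!is.null(x$projection)) {
    cat("\n-- habitat area projection --\n")
    print(x$projection)
  }
  invisible(x)
}
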