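#' Projected climate raster
#'
#' A minimal single-band raster in a projected (metric) coordinate system:
#' a numeric matrix whose rows run north to south (row 1 is the northernmost
#' row, the ESRI ASCII-grid convention), plus the lower-left corner and the
#' square cell size in metres. Missing cells are NA.
#'
#' @param values numeric matrix, row 1 = top (north).
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length in metres, > 0.
#' @param crs free-text label of the projected CRS (metres assumed).
#' @return A `climate_grid` object.
#' @export
climate_grid <- function(values, xll = 0, yll = 0, cellsize,
                         crs = "local-metric") {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop_validation("cellsize must be a single positive number (metres)")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop_validation("grid extent must be positive")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "climate_grid: %d x %d cells @ %g m (%s)\n  range %.2f to %.2f, %d NA\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$crs,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
    sum(!is.finite(x$values))))
  invisible(x)
}

# x coordinate of each column's cell center / y of each row's center
grid_x <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
grid_y <- function(g) g$yll + (rev(seq_len(nrow(g$values))) - 0.5) * g$cellsize

#' Read / write ESRI ASCII grids
#'
#' The plain-text raster interchange format (`NCOLS/NROWS/XLLCORNER/
#' YLLCORNER/CELLSIZE/NODATA_value` header followed by rows north to south),
#' used here as the portable stand-in for GeoTIFF.
#'
#' @param path file path.
#' @param crs CRS label to attach on read.
#' @return `read_ascii_grid`: a [climate_grid()].
#' @export
read_ascii_grid <- function(path, crs = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- hdr$nodata_value %||% -9999
  m[m == nd] <- NA
  climate_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
               cellsize = hdr$cellsize, crs = crs)
}

#' @rdname read_ascii_grid
#' @param grid a [climate_grid()].
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$values
  m[!is.finite(m)] <- -9999
  hdr <- c(paste("NCOLS", ncol(m)), paste("NROWS", nrow(m)),
           paste("XLLCORNER", grid$xll), paste("YLLCORNER", grid$yll),
           paste("CELLSIZE", grid$cellsize), "NODATA_value -9999")
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply a uniform scenario temperature offset
#'
#' Scenario deltas are uniform scalars added cellwise (ensemble-mean offsets
#' relative to the current-period surface); NA cells stay NA.
#'
#' @param grid a [climate_grid()] of mean summer temperature (degrees C).
#' @param delta offset in degrees C (0 = current; negative = historical).
#' @return The shifted [climate_grid()].
#' @export
apply_scenario <- function(grid, delta) {
  if (!is.finite(delta)) stop_validation("scenario delta must be finite")
  grid$values <- grid$values + delta
  grid
}

#' Refugial mask: cells strictly cooler than a threshold
#'
#' @param grid a [climate_grid()].
#' @param threshold degrees C; cells with MST strictly below it are refugial
#'   (a cell exactly at the threshold is not).
#' @return A logical matrix with the grid's geometry (NA cells FALSE).
#' @export
refugial_mask <- function(grid, threshold = 14.2) {
  if (!is.finite(threshold)) stop_validation("threshold must be finite")
  m <- grid$values < threshold
  m[!is.finite(grid$values)] <- FALSE
  m
}

#' Suitable mask: cells within a dispersal radius of any refugial cell
#'
#' A cell is climatically suitable when its center lies within
#' `dispersal_km` (Euclidean, center-to-center, projected plane) of the
#' center of some refugial cell; refugial cells are always suitable.
#' Implemented by dilating the refugial mask with the disk of cell offsets —
#' an exact distance criterion, not an approximation.
#'
#' @param refugia logical matrix from [refugial_mask()].
#' @param cellsize cell edge in metres.
#' @param dispersal_km dispersal radius in km (default 4).
#' @return Logical matrix, same geometry.
#' @export
suitable_mask <- function(refugia, cellsize, dispersal_km = 4) {
  r_cells <- dispersal_km * 1000 / cellsize
  k <- floor(r_cells)
  nr <- nrow(refugia); nc <- ncol(refugia)
  out <- matrix(FALSE, nr, nc)
  if (!any(refugia)) return(out)
  for (di in -k:k) {
    wj <- floor(sqrt(r_cells^2 - di^2) + 1e-9)
    ilo <- max(1, 1 - di); ihi <- min(nr, nr - di)
    if (ilo > ihi) next
    for (dj in -wj:wj) {
      jlo <- max(1, 1 - dj); jhi <- min(nc, nc - dj)
      if (jlo > jhi) next
      src_i <- ilo:ihi; src_j <- jlo:jhi
      out[src_i + di, src_j + dj] <-
        out[src_i + di, src_j + dj] | refugia[src_i, src_j]
    }
  }
  out
}

#' Areas of refugial and suitable habitat per scenario
#'
#' @param grid current-period MST [climate_grid()].
#' @param scenarios named numeric vector of deltas (degrees C), e.g.
#'   `c(historical = -1.45, current = 0, "2030" = 1.33, "2050" = 2.74)`.
#' @param threshold refugial MST threshold (degrees C).
#' @param dispersal_km dispersal radius (km).
#' @param baseline scenario name used for percent declines
#'   (default `"current"`, or the zero-delta scenario if unnamed).
#' @return An `area_summary` data frame: `scenario`, `delta`, `refugial_km2`,
#'   `suitable_km2`, `refugial_pct_decline`, `suitable_pct_decline`.
#' @export
area_summary <- function(grid, scenarios, threshold = 14.2,
                         dispersal_km = 4, baseline = "current") {
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    stop_validation("scenarios must be a named vector of deltas")
  cell_km2 <- (grid$cellsize / 1000)^2
  rows <- lapply(names(scenarios), function(nm) {
    g <- apply_scenario(grid, scenarios[[nm]])
    ref <- refugial_mask(g, threshold)
    suit <- suitable_mask(ref, g$cellsize, dispersal_km)
    data.frame(scenario = nm, delta = scenarios[[nm]],
               refugial_km2 = sum(ref) * cell_km2,
               suitable_km2 = sum(suit) * cell_km2)
  })
  out <- do.call(rbind, rows)
  if (!baseline %in% out$scenario) baseline <- out$scenario[out$delta == 0][1]
  b <- out[out$scenario == baseline, ]
  decline <- function(x, x0) if (isTRUE(x0 > 0)) 100 * (1 - x / x0) else
    NA_real_
  out$refugial_pct_decline <- decline(out$refugial_km2, b$refugial_km2)
  out$suitable_pct_decline <- decline(out$suitable_km2, b$suitable_km2)
  class(out) <- c("area_summary", "data.frame")
  out
}
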