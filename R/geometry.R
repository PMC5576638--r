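#' @name talus-geometry
#' @title Talus polygon geometry
#' @description
#' Talus patches are simple polygons in projected metre coordinates, stored
#' as a list of two-column (x, y) matrices. Areas use the shoelace formula;
#' intersection with a dispersal disk clips each polygon against a regular
#' 256-gon approximation of the circle (Sutherland-Hodgman against a convex
#' clip region), accurate to well under 0.1% of the disk area.
NULL

# shoelace area of one ring (any orientation), metres^2
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of `ring` against convex polygon `clip`
# (counter-clockwise). Returns a matrix (possibly 0-row).
clip_convex <- function(ring, clip) {
  out <- ring
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1]) >= 0
    n <- nrow(out)
    res <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(n)) {
      p <- out[j, ]; q <- out[if (j == n) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) res <- rbind(res, p)
      if (xor(pin, qin)) {
        # intersection of segment pq with the clip edge line
        denom <- ex * (p[2] - q[2]) - ey * (p[1] - q[1])
        t <- (ex * (p[2] - a[2]) - ey * (p[1] - a[1])) / denom
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

disk_polygon <- function(cx, cy, r, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Talus area within a radius of a site
#'
#' Total area of the geometric intersection of the talus polygons with the
#' disk of radius `radius_km` around the site centroid. Polygons are assumed
#' non-overlapping (hand-delineated patches); overlaps would double count.
#'
#' @param polygons list of two-column x/y matrices (projected metres), or a
#'   single matrix.
#' @param site list or vector with `x` and `y` (metres).
#' @param radius_km disk radius in km (default 1).
#' @return Area in m^2.
#' @export
talus_area_within <- function(polygons, site, radius_km = 1) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  cx <- site[["x"]]; cy <- site[["y"]]
  disk <- disk_polygon(cx, cy, radius_km * 1000)
  total <- 0
  for (p in polygons) {
    p <- as.matrix(p)
    if (nrow(p) < 3 || anyNA(p)) {
      stop_validation("invalid talus polygon (fewer than 3 vertices or NA)")
    }
    # cheap reject: bounding boxes
    r <- radius_km * 1000
    if (max(p[, 1]) < cx - r || min(p[, 1]) > cx + r ||
        max(p[, 2]) < cy - r || min(p[, 2]) > cy + r) next
    total <- total + polygon_area(clip_convex(p, disk))
  }
  total
}

#' Log talus-area covariate
#'
#' Talus area is log-transformed to reduce skew; a 1 m^2 floor keeps sites
#' with zero mapped talus finite.
#'
#' @param area_m2 area(s) in m^2.
#' @param floor_m2 additive floor before the log (default 1).
#' @return `log(area + floor)`.
#' @export
log_talus_area <- function(area_m2, floor_m2 = 1) log(area_m2 + floor_m2)

#' Read / write talus polygons as GeoJSON
#'
#' Coordinates are taken as already-projected metres (the `crs` member is
#' recorded verbatim); only Polygon and MultiPolygon outer rings are read.
#'
#' @param path GeoJSON file path.
#' @return `read_talus_geojson`: list of two-column coordinate matrices.
#' @export
read_talus_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    if (identical(geom$type, "Polygon")) {
      polys[[length(polys) + 1]] <- ring_to_mat(geom$coordinates[[1]])
    } else if (identical(geom$type, "MultiPolygon")) {
      for (pp in geom$coordinates)
        polys[[length(polys) + 1]] <- ring_to_mat(pp[[1]])
    }
  }
  polys
}

#' @rdname read_talus_geojson
#' @param polygons list of two-column coordinate matrices.
#' @param crs CRS label stored in the file's `crs.properties.name`.
#' @export
write_talus_geojson <- function(polygons, path, crs = "local-metric") {
  close_ring <- function(p) {
    if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
    lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
  }
  feats <- lapply(polygons, function(p) list(
    type = "Feature", properties = list(),
    geometry = list(type = "Polygon",
                    coordinates = list(close_ring(as.matrix(p))))))
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs)),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
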