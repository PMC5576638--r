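# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (no calibrate()/hpd_intervals()/suitable_mask()
# internals): dense-grid trapezoid integration, exhaustive enumeration, and
# Monte-Carlo point sampling.

# Brute-force calibration: unnormalised Normal likelihood on a dense year
# grid, trapezoid-normalised; the HPD region comes from bisecting a density
# cutoff c until mass{f >= c} = mass. Returns the run intervals.
oracle_calibrate_hpd <- function(fm, fm_sigma, curve, mass = 0.95,
                                 step = 0.05) {
  yr <- seq(min(curve$calendar_year), max(curve$calendar_year), by = step)
  mu <- approx(curve$calendar_year, curve$curve_fm, xout = yr)$y
  sg <- approx(curve$calendar_year, curve$curve_sigma, xout = yr)$y
  f <- dnorm(fm, mu, sqrt(fm_sigma^2 + sg^2))
  w <- rep(step, length(yr)); w[c(1, length(yr))] <- step / 2  # trapezoid
  f <- f / sum(f * w)
  mass_above <- function(c0) sum(f[f >= c0] * w[f >= c0])
  lo <- 0; hi <- max(f)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mass_above(mid) >= mass) lo <- mid else hi <- mid
  }
  sel <- f >= lo
  idx <- which(sel)
  breaks <- c(0, which(diff(idx) > 1), length(idx))
  do.call(rbind, lapply(seq_len(length(breaks) - 1), function(i) {
    ii <- idx[(breaks[i] + 1):breaks[i + 1]]
    data.frame(start_year = yr[min(ii)], end_year = yr[max(ii)],
               mass = sum(f[ii] * w[ii]))
  }))
}

# Mass near a mode: trapezoid integral of the normalised likelihood over
# [a, b] at 0.01-yr resolution.
oracle_mode_mass <- function(fm, fm_sigma, curve, a, b, step = 0.01) {
  yr <- seq(min(curve$calendar_year), max(curve$calendar_year), by = step)
  mu <- approx(curve$calendar_year, curve$curve_fm, xout = yr)$y
  sg <- approx(curve$calendar_year, curve$curve_sigma, xout = yr)$y
  f <- dnorm(fm, mu, sqrt(fm_sigma^2 + sg^2))
  w <- rep(step, length(yr)); w[c(1, length(yr))] <- step / 2
  f <- f / sum(f * w)
  sum((f * w)[yr >= a & yr <= b])
}

# Exact Mann-Whitney two-sided p by enumerating all group assignments.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(b, a)
  combs <- combn(n, na)
  mid <- length(a) * length(b) / 2
  count <- 0
  for (j in seq_len(ncol(combs))) {
    aa <- pooled[combs[, j]]; bb <- pooled[-combs[, j]]
    if (abs(u_stat(bb, aa) - mid) >= abs(obs - mid) - 1e-9) count <- count + 1
  }
  count / ncol(combs)
}

# All-pairs distance dilation: cell true iff within r of a TRUE cell.
oracle_suitable <- function(refugia, cellsize, dispersal_km) {
  nr <- nrow(refugia); nc <- ncol(refugia)
  out <- matrix(FALSE, nr, nc)
  ref <- which(refugia, arr.ind = TRUE)
  if (nrow(ref) == 0) return(out)
  r2 <- (dispersal_km * 1000 / cellsize)^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (ref[, 1] - i)^2 + (ref[, 2] - j)^2
    if (any(d2 <= r2 + 1e-9)) out[i, j] <- TRUE
  }
  out
}

# Exhaustive scan: min grid value over cell centers within radius of a site.
oracle_refugial_min <- function(grid, site, radius_km) {
  gx <- grid$xll + (seq_len(ncol(grid$values)) - 0.5) * grid$cellsize
  gy <- grid$yll + (rev(seq_len(nrow(grid$values))) - 0.5) * grid$cellsize
  best <- Inf
  for (i in seq_len(nrow(grid$values))) for (j in seq_len(ncol(grid$values))) {
    if ((gx[j] - site$x)^2 + (gy[i] - site$y)^2 <= (radius_km * 1000)^2 &&
        is.finite(grid$values[i, j]))
      best <- min(best, grid$values[i, j])
  }
  best
}

# Monte-Carlo polygon-in-disk area: uniform points in the disk, point-in-
# polygon by ray casting.
oracle_mc_area <- function(polygon, cx, cy, r, n = 1e6, seed = 42) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi); rad <- r * sqrt(runif(n))
  px <- cx + rad * cos(th); py <- cy + rad * sin(th)
  x <- polygon[, 1]; y <- polygon[, 2]
  nv <- length(x)
  inside <- rep(FALSE, n)
  j <- nv
  for (i in seq_len(nv)) {
    cross <- (y[i] > py) != (y[j] > py)
    xint <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  mean(inside) * pi * r^2
}

# Negative log-likelihood of logistic regression, written independently for
# the generic-optimizer cross-check.
oracle_logistic_nll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

default_curve <- function() make_calibration_curve(list())
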