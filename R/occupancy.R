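#' Refugial mean summer temperature within a radius
#'
#' The minimum MST over all grid cells whose center lies within `radius_km`
#' (Euclidean, projected metres) of the site centroid — the coolest climate
#' refuge reachable at that dispersal distance. Nonincreasing in the radius
#' by construction.
#'
#' @param grid a [climate_grid()] of MST.
#' @param site list/vector with `x`, `y` in the grid's projected metres.
#' @param radius_km search radius in km, > 0.
#' @return Minimum MST in degrees C.
#' @export
refugial_mst <- function(grid, site, radius_km) {
  if (radius_km <= 0) stop_validation("radius must be positive")
  x <- site[["x"]]; y <- site[["y"]]
  gx <- grid_x(grid); gy <- grid_y(grid)
  if (x < grid$xll || x > grid$xll + ncol(grid$values) * grid$cellsize ||
      y < grid$yll || y > grid$yll + nrow(grid$values) * grid$cellsize)
    stop_validation("site lies outside the grid extent")
  r <- radius_km * 1000
  jj <- which(abs(gx - x) <= r)
  ii <- which(abs(gy - y) <= r)
  if (length(ii) == 0 || length(jj) == 0)
    stop_validation("no cell center within radius of site")
  sub <- grid$values[ii, jj, drop = FALSE]
  d2 <- outer((gy[ii] - y)^2, (gx[jj] - x)^2, "+")
  vals <- sub[d2 <= r^2 & is.finite(sub)]
  if (length(vals) == 0)
    stop_validation("no data cell center within radius of site")
  min(vals)
}

#' Spatially thin sites to a minimum separation
#'
#' Occurrence locations closer than `min_dist_m` are reduced so that no two
#' retained sites are within that distance, by iterated uniform-random
#' selection: a site is drawn at random, retained, and all sites within
#' `min_dist_m` of it are discarded, until none remain undecided. The result
#' is a maximal independent set of the proximity graph, deterministic given
#' the seed.
#'
#' @param sites data frame with `x`, `y` in metres.
#' @param min_dist_m minimum separation (default 250).
#' @param seed integer RNG seed.
#' @return The retained subset of `sites` (original row order).
#' @export
spatial_thin <- function(sites, min_dist_m = 250, seed = 1) {
  n <- nrow(sites)
  if (n <= 1) return(sites)
  keep <- logical(n)
  undecided <- rep(TRUE, n)
  with_seed(seed, {
    while (any(undecided)) {
      cand <- which(undecided)
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      keep[pick] <- TRUE
      d2 <- (sites$x - sites$x[pick])^2 + (sites$y - sites$y[pick])^2
      undecided[d2 <= min_dist_m^2] <- FALSE
    }
  })
  sites[keep, , drop = FALSE]
}

#' Fit a logistic occupancy model
#'
#' Maximum-likelihood logistic regression of occupancy (1 = extant,
#' 0 = extirpated) on the named predictors, with the small-sample AICc
#' `-2 logL + 2k + 2k(k+1)/(n-k-1)`. Complete separation — the situation
#' where classes divide perfectly along a predictor — is detected and
#' flagged; with `on_separation = "penalize"` a light ridge penalty
#' (L2, `lambda`) is used to keep coefficients finite, never silently.
#'
#' @param sites data frame with an `occupancy` column (logical, 0/1, or
#'   `"extant"`/`"extirpated"`) and the predictor columns.
#' @param predictors character vector of predictor column names.
#' @param on_separation `"flag"` (default) or `"penalize"`.
#' @param lambda ridge penalty used when `on_separation = "penalize"`.
#' @return An `occupancy_model` list: `predictors`, `coefficients`,
#'   `log_likelihood`, `k`, `n`, `aicc`, `separation`, `fitted`.
#' @export
fit_logistic <- function(sites, predictors,
                         on_separation = c("flag", "penalize"),
                         lambda = 1e-3) {
  on_separation <- match.arg(on_separation)
  y <- occupancy_as_binary(sites$occupancy)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sites[, predictors, drop = FALSE]))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased (e.g. constant) predictors drop to 0
  if (any(abs(beta[-1]) > 15)) sep <- TRUE
  if (sep && on_separation == "penalize") {
    beta <- ridge_logistic(X, y, lambda)
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  k <- length(beta)
  n <- length(y)
  aicc <- -2 * ll + 2 * k +
    if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(predictors = predictors, coefficients = beta,
                 log_likelihood = ll, k = k, n = n, aicc = aicc,
                 separation = sep, fitted = p,
                 vcov = tryCatch(chol2inv(chol(crossprod(X, X * (p * (1 - p))))),
                                 error = function(e) NULL)),
            class = "occupancy_model")
}

occupancy_as_binary <- function(occ) {
  if (is.character(occ) || is.factor(occ)) {
    occ <- as.character(occ)
    if (!all(occ %in% c("extant", "extirpated")))
      stop_validation("occupancy must be 'extant'/'extirpated' or 0/1")
    as.numeric(occ == "extant")
  } else as.numeric(occ)
}

# Newton iterations for L2-penalised logistic regression (no penalty on the
# intercept); keeps estimates finite under separation.
ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  setNames(beta, colnames(X))
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("Logistic occupancy model:", paste(x$predictors, collapse = " + "),
      "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  logL = %.3f, k = %d, n = %d, AICc = %.2f%s\n",
              x$log_likelihood, x$k, x$n, x$aicc,
              if (x$separation) "  [complete separation]" else ""))
  invisible(x)
}

#' Rank candidate occupancy models by AICc
#'
#' The candidate set pairs each refugial-MST radius with and without the
#' log-talus-area covariate: `mst_min_<r>k` alone and
#' `mst_min_<r>k + log_talus_area` for each radius, ten models for radii
#' 1-5 km. Ties are broken by fewer parameters, then model name.
#'
#' @param sites data frame with `occupancy`, `mst_min_<r>k` columns and
#'   `log_talus_area`.
#' @param radii radii (km) with matching `mst_min_<r>k` columns.
#' @param with_talus include the +talus variants (default TRUE).
#' @param ... passed to [fit_logistic()].
#' @return A `model_comparison` data frame sorted by AICc: `model`, `k`,
#'   `log_likelihood`, `aicc`, `delta_aicc`, `separation`; fitted models in
#'   `attr(, "models")`.
#' @export
rank_models <- function(sites, radii = 1:5, with_talus = TRUE, ...) {
  specs <- list()
  for (r in radii) {
    v <- paste0("mst_min_", r, "k")
    if (!v %in% names(sites))
      stop_validation("missing predictor column: ", v)
    specs[[v]] <- v
    if (with_talus) specs[[paste0(v, " + log_talus_area")]] <-
        c(v, "log_talus_area")
  }
  fits <- list(); rows <- list()
  for (nm in names(specs)) {
    fit <- tryCatch(fit_logistic(sites, specs[[nm]], ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("model '", nm, "' failed to fit and was excluded: ",
              conditionMessage(fit))
      next
    }
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, k = fit$k,
                             log_likelihood = fit$log_likelihood,
                             aicc = fit$aicc, separation = fit$separation)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc, out$k, out$model), , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  attr(out, "models") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Covariate value at the 0.5 occupancy probability
#'
#' For a single-covariate logistic model, p = 0.5 at `-beta0 / beta1`.
#'
#' @param model an `occupancy_model` with one slope.
#' @return Threshold on the covariate scale (degrees C for refugial MST).
#' @export
occupancy_threshold <- function(model) {
  if (length(model$coefficients) != 2)
    stop_validation("threshold is defined for single-covariate models")
  b1 <- model$coefficients[2]
  if (b1 == 0) stop_validation("undefined threshold: slope is zero")
  unname(-model$coefficients[1] / b1)
}

#' Exact binomial test of observed extirpations against model predictions
#'
#' Compares the observed extirpation count with an exact binomial null. The
#' default null success probability is the mean of the per-site predicted
#' extirpation probabilities (`1 - p_occupancy`); alternatives are a fixed
#' 0.5 (`"point5"`) and the heterogeneous-probability exact
#' Poisson-binomial null (`"poisson_binomial"`). Two-sided p sums the
#' probabilities of all outcomes no more likely than the observed one
#' (minimum-likelihood convention).
#'
#' @param occupancy site occupancy vector (as in [fit_logistic()]).
#' @param prior_p per-site predicted occupancy probabilities from the prior
#'   (external) model.
#' @param null `"pooled"` (default), `"point5"`, or `"poisson_binomial"`.
#' @return List with `observed`, `n`, `expected`, `p_two_sided`, `null`.
#' @export
binomial_extirpation_test <- function(occupancy, prior_p,
                                      null = c("pooled", "point5",
                                               "poisson_binomial")) {
  null <- match.arg(null)
  y <- occupancy_as_binary(occupancy)
  n <- length(y)
  if (n == 0) stop_validation("empty site set")
  if (length(prior_p) != n)
    stop_validation("every site needs a prior predicted probability")
  x <- sum(1 - y)  # observed extirpations
  q <- 1 - prior_p # predicted extirpation probabilities
  if (null == "poisson_binomial") {
    pmf <- poisson_binomial_pmf(q)
    p <- min(1, sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)]))
    expected <- sum(q)
  } else {
    p0 <- if (null == "pooled") mean(q) else 0.5
    pmf <- dbinom(0:n, n, p0)
    p <- min(1, sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)]))
    expected <- n * p0
  }
  list(observed = x, n = n, expected = expected, p_two_sided = p,
       null = null)
}

# exact pmf of a sum of independent Bernoulli(q_i), by convolution
poisson_binomial_pmf <- function(q) {
  pmf <- 1
  for (qi in q) pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
  pmf
}

#' Classification rates of a prior model at a probability threshold
#'
#' @inheritParams binomial_extirpation_test
#' @param threshold probability threshold (default 0.5): extant sites with
#'   `prior_p >= threshold` and extirpated sites with `prior_p < threshold`
#'   are counted correct.
#' @return List with `extant_correct`, `extant_n`, `extant_rate`,
#'   `extirpated_correct`, `extirpated_n`, `extirpated_rate` (rates NA and
#'   flagged when a class is absent).
#' @export
classification_rates <- function(occupancy, prior_p, threshold = 0.5) {
  y <- occupancy_as_binary(occupancy)
  ext <- y == 1
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(extant_correct = sum(prior_p[ext] >= threshold),
       extant_n = sum(ext),
       extant_rate = rate(sum(prior_p[ext] >= threshold), sum(ext)),
       extirpated_correct = sum(prior_p[!ext] < threshold),
       extirpated_n = sum(!ext),
       extirpated_rate = rate(sum(prior_p[!ext] < threshold), sum(!ext)))
}

#' Read a site table CSV
#'
#' Columns: `site_id`, `x`, `y` (projected metres), `occupancy`
#' (`extant`/`extirpated` or 0/1), optional `prior_p` and precomputed
#' predictor columns.
#'
#' @param path CSV path.
#' @return Data frame of sites.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "occupancy")
  if (!all(need %in% names(df)))
    stop_validation("site file must have columns: ",
                    paste(need, collapse = ", "))
  df
}

#' Attach refugial-MST and talus predictors to a site table
#'
#' @param sites data frame with `x`, `y`.
#' @param grid MST [climate_grid()].
#' @param talus list of talus polygons (may be `NULL` to skip).
#' @param radii refugial radii in km.
#' @param talus_radius_km talus-area radius (default 1).
#' @return `sites` with `mst_min_<r>k`, `talus_area_1km`, `log_talus_area`.
#' @export
add_site_predictors <- function(sites, grid, talus = NULL, radii = 1:5,
                                talus_radius_km = 1) {
  for (r in radii)
    sites[[paste0("mst_min_", r, "k")]] <-
      vapply(seq_len(nrow(sites)), function(i)
        refugial_mst(grid, sites[i, ], r), numeric(1))
  if (!is.null(talus)) {
    area <- vapply(seq_len(nrow(sites)), function(i)
      talus_area_within(talus, sites[i, ], talus_radius_km), numeric(1))
    sites$talus_area_1km <- area
    sites$log_talus_area <- log_talus_area(area)
  }
  sites
}
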