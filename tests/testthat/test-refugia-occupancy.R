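test_that("refugial_mst: constant grid, disk geometry, brute-force oracle", {
  const <- climate_grid(matrix(12, 30, 30), cellsize = 270)
  site <- list(x = 30 * 270 / 2, y = 30 * 270 / 2)
  expect_equal(refugial_mst(const, site, 2), 12)

  # single cool cell 3.9 km east of the site: seen at r = 4, not at r = 3
  m <- matrix(20, 41, 61)
  g <- climate_grid(m, cellsize = 100)
  site2 <- list(x = 10 * 100 - 50, y = 20 * 100 + 50)
  cool_col <- which(abs((seq_len(61) - 0.5) * 100 - (site2$x + 3900)) < 1)
  m[21, cool_col] <- 5   # same row => distance exactly 3900 m
  g$values <- m
  expect_equal(refugial_mst(g, site2, 4), 5)
  expect_equal(refugial_mst(g, site2, 3), 20)

  # random grid vs exhaustive scan
  set.seed(3)
  rg <- climate_grid(matrix(runif(2500, 8, 20), 50, 50), cellsize = 100)
  s3 <- list(x = 2600, y = 2400)
  expect_equal(refugial_mst(rg, s3, 2), oracle_refugial_min(rg, s3, 2))
  expect_error(refugial_mst(rg, list(x = -100, y = 0), 1),
               class = "taluscape_validation_error")
})

test_that("refugial_mst is nonincreasing in radius (property)", {
  set.seed(44)
  g <- make_temperature_grid(list(nx = 60, ny = 60), seed = 44)$mst
  for (i in 1:15) {
    s <- list(x = runif(1, 1500, 60 * 270 - 1500),
              y = runif(1, 1500, 60 * 270 - 1500))
    v <- vapply(1:5, function(r) refugial_mst(g, s, r), numeric(1))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("talus_area_within handles containment and partial overlap", {
  sq <- function(cx, cy, s) cbind(c(-1, 1, 1, -1) * s / 2 + cx,
                                  c(-1, -1, 1, 1) * s / 2 + cy)
  site <- list(x = 0, y = 0)
  expect_equal(talus_area_within(sq(0, 0, 200), site, 1), 200^2,
               tolerance = 1e-9)
  expect_equal(talus_area_within(sq(5000, 0, 200), site, 1), 0)
  # square straddling the disk edge vs Monte-Carlo point sampling (1e6 pts)
  half <- sq(1000, 0, 400)
  mc <- oracle_mc_area(half, 0, 0, 1000, n = 1e6)
  got <- talus_area_within(half, site, 1)
  expect_equal(got, mc, tolerance = 0.01 * mc / got + 0.01)
  # several polygons sum
  expect_equal(talus_area_within(list(sq(0, 0, 100), sq(300, 300, 50)),
                                 site, 1), 100^2 + 50^2, tolerance = 1e-6)
  expect_error(talus_area_within(sq(0, 0, 100)[1:2, ], site, 1),
               class = "taluscape_validation_error")
})

test_that("spatial_thin returns a seeded maximal independent set", {
  far <- data.frame(x = c(0, 1000, 2000), y = c(0, 0, 0))
  expect_equal(nrow(spatial_thin(far, 250, seed = 1)), 3)
  near <- data.frame(x = c(0, 100), y = c(0, 0))
  expect_equal(nrow(spatial_thin(near, 250, seed = 1)), 1)
  # chain A-B 200 m, B-C 200 m, A-C 400 m: only {A, C} or {B} are valid
  chain <- data.frame(id = c("A", "B", "C"), x = c(0, 200, 400), y = 0)
  seen <- character()
  for (s in 1:50) {
    kept <- spatial_thin(chain, 250, seed = s)$id
    seen <- c(seen, paste(sort(kept), collapse = ""))
    d <- as.matrix(dist(spatial_thin(chain, 250, seed = s)[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] > 250))
  }
  expect_setequal(unique(seen), c("AC", "B"))
  # deterministic given seed
  expect_identical(spatial_thin(chain, 250, seed = 9),
                   spatial_thin(chain, 250, seed = 9))
})

test_that("fit_logistic recovers known coefficients within Wald CIs", {
  set.seed(21)
  n <- 1000
  x <- rnorm(n, 14, 2)
  p <- plogis(20 - 1.4 * x)
  df <- data.frame(occupancy = rbinom(n, 1, p), mst = x)
  fit <- fit_logistic(df, "mst")
  se <- sqrt(diag(fit$vcov))
  # single-replicate check at 3 sigma (a 1.96-sigma check would fail ~5%
  # of arbitrary seeds by design); repeated-coverage properties live in
  # the end-to-end and acceptance suites
  expect_lt(abs(fit$coefficients[1] - 20), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] + 1.4), 3 * se[2])
  expect_false(fit$separation)
})

test_that("constant predictor with balanced classes gives null fit", {
  df <- data.frame(occupancy = rep(c(0, 1), 25), z = 1)
  fit <- fit_logistic(df, "z")
  expect_equal(unname(fit$coefficients[2]), 0)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-9)
})

test_that("complete separation is flagged, penalized fit stays finite", {
  df <- data.frame(occupancy = c(rep(1, 10), rep(0, 10)),
                   mst = c(rnorm(10, 12), rnorm(10, 17)))
  fit <- fit_logistic(df, "mst")
  expect_true(fit$separation)
  pen <- fit_logistic(df, "mst", on_separation = "penalize")
  expect_true(all(is.finite(pen$coefficients)))
  expect_true(all(abs(pen$coefficients) < 1e3))
})

test_that("log-likelihood matches a generic-optimizer maximum (20 seeds)", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 120
    x1 <- rnorm(n, 14, 1.5); x2 <- rnorm(n, 9, 1)
    y <- rbinom(n, 1, plogis(6 - 0.5 * x1 + 0.1 * x2))
    df <- data.frame(occupancy = y, a = x1, b = x2)
    fit <- fit_logistic(df, c("a", "b"))
    X <- cbind(1, x1, x2)
    op <- optim(c(0, 0, 0), oracle_logistic_nll, X = X, y = y,
                method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(fit$log_likelihood, -op$value, tolerance = 1e-6)
  }
})

test_that("AICc follows its formula and tends to AIC as n grows", {
  set.seed(60)
  df <- data.frame(occupancy = rbinom(40, 1, 0.5), v = rnorm(40))
  fit <- fit_logistic(df, "v")
  aic <- -2 * fit$log_likelihood + 2 * fit$k
  expect_equal(fit$aicc, aic + 2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1))
  dfb <- data.frame(occupancy = rbinom(5000, 1, 0.5), v = rnorm(5000))
  fitb <- fit_logistic(dfb, "v")
  expect_lt(fitb$aicc - (-2 * fitb$log_likelihood + 2 * fitb$k), 0.01)
})

test_that("rank_models builds ten models, breaks ties, ignores order", {
  g <- make_temperature_grid(list(nx = 70, ny = 70), seed = 77)$mst
  st <- make_sites_with_occupancy(list(n_sites = 120), g, seed = 77)
  cmp <- rank_models(st)
  expect_equal(nrow(cmp), 10)
  expect_equal(cmp$delta_aicc[1], 0)
  expect_true(!is.unsorted(cmp$aicc))
  # invariant to site ordering
  set.seed(1)
  cmp2 <- rank_models(st[sample(nrow(st)), ])
  expect_equal(as.data.frame(cmp)[, c("model", "aicc")],
               as.data.frame(cmp2)[, c("model", "aicc")],
               tolerance = 1e-9)
  # duplicate predictor sets tie and break by k: add a copy of mst_min_1k
  st$mst_min_9k <- st$mst_min_1k
  cmp3 <- rank_models(st, radii = c(1, 9), with_talus = FALSE)
  expect_equal(cmp3$aicc[1], cmp3$aicc[2], tolerance = 1e-9)
  expect_equal(cmp3$model[1], "mst_min_1k")  # lexicographic at equal k
})

test_that("occupancy_threshold is -b0/b1 and recovers the true threshold", {
  m <- structure(list(coefficients = c(`(Intercept)` = 28.4, mst = -2.0)),
                 class = "occupancy_model")
  expect_equal(occupancy_threshold(m), 14.2)
  m0 <- structure(list(coefficients = c(`(Intercept)` = 0, mst = -1)),
                  class = "occupancy_model")
  expect_equal(occupancy_threshold(m0), 0)
  mz <- structure(list(coefficients = c(`(Intercept)` = 1, mst = 0)),
                  class = "occupancy_model")
  expect_error(occupancy_threshold(mz),
               class = "taluscape_validation_error")
  # simulation recovery: generating threshold 20/1.4 ~ 14.29 C
  thr <- vapply(1:10, function(s) {
    g <- make_temperature_grid(list(nx = 80, ny = 80), seed = 400 + s)$mst
    st <- make_sites_with_occupancy(list(n_sites = 400), g,
                                    seed = 400 + s, talus = FALSE)
    occupancy_threshold(fit_logistic(st, "mst_min_4k"))
  }, numeric(1))
  expect_lt(abs(mean(thr) - 20 / 1.4), 3 * sd(thr) / sqrt(10) + 0.2)
})

test_that("exact binomial extirpation test matches closed forms", {
  # 14 of 14 extirpated under pooled extirpation probability 0.5
  occ <- rep("extirpated", 14)
  res <- binomial_extirpation_test(occ, prior_p = rep(0.5, 14))
  expect_equal(res$p_two_sided, 2 * 0.5^14, tolerance = 1e-12)
  expect_lt(res$p_two_sided, 0.001)
  # observed equals expected: p ~ 1
  occ2 <- rep(c("extirpated", "extant"), 7)
  res2 <- binomial_extirpation_test(occ2, prior_p = rep(0.5, 14))
  expect_equal(res2$p_two_sided, 1, tolerance = 1e-9)
  # n = 1 enumeration: prior_p = 0.7 occupancy means extirpation
  # probability 0.3; the rarer observed outcome (extirpation) has p equal
  # to its own probability, the common one has p = 1
  r_common <- binomial_extirpation_test("extant", prior_p = 0.7)
  expect_equal(r_common$p_two_sided, 1, tolerance = 1e-12)
  r_rare <- binomial_extirpation_test("extirpated", prior_p = 0.7)
  expect_equal(r_rare$p_two_sided, 0.3, tolerance = 1e-12)
  # Poisson-binomial with equal probabilities reduces to the binomial
  rpb <- binomial_extirpation_test(occ, rep(0.5, 14),
                                   null = "poisson_binomial")
  expect_equal(rpb$p_two_sided, res$p_two_sided, tolerance = 1e-12)
  # heterogeneous Poisson-binomial pmf sums to 1 and has the right mean
  q <- c(0.1, 0.5, 0.9, 0.3)
  pmf <- taluscape:::poisson_binomial_pmf(q)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_equal(sum(pmf * 0:4), sum(q), tolerance = 1e-12)
  expect_error(binomial_extirpation_test(character(0), numeric(0)),
               class = "taluscape_validation_error")
})

test_that("classification_rates reproduces the per-class fractions", {
  occ <- c(rep("extant", 21), rep("extirpated", 16))
  p <- c(rep(0.9, 18), rep(0.2, 3),   # 18/21 extant predicted occupied
         rep(0.2, 8), rep(0.9, 8))    # 8/16 extirpated predicted extirpated
  r <- classification_rates(occ, p)
  expect_equal(r$extant_rate, 18 / 21)
  expect_equal(r$extirpated_rate, 8 / 16)
  all_ext <- classification_rates(rep("extant", 5), rep(1, 5))
  expect_equal(all_ext$extant_rate, 1)
  expect_true(is.na(all_ext$extirpated_rate))
})
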