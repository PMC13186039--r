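test_that("empirical semivariance matches the Matheron definition", {
  # two points with values 0 and 2 at one lag: gamma = (0-2)^2 / 2 = 2
  emp <- empirical_variogram(cbind(c(0, 1), c(0, 0)), c(0, 2),
                             n_lags = 1, cutoff = 1.5)
  expect_equal(emp$gamma, 2)
  expect_equal(emp$n_pairs, 1)
  # constant field: all semivariances zero, fit degenerates with warning
  set.seed(1)
  xy <- cbind(runif(12), runif(12))
  expect_warning(vg <- fit_variogram(xy, rep(3, 12)), "constant")
  expect_equal(vg$nugget, 0)
  expect_equal(vg$partial_sill, 0)
})

test_that("fitted sill approximates the variance of a stationary field", {
  set.seed(2)
  n <- 120
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  v <- rnorm(n)  # pure nugget / stationary white noise
  vg <- fit_variogram(xy, v, n_lags = 10)
  sill <- vg$nugget + vg$partial_sill
  expect_lt(abs(sill - var(v)) / var(v), 0.2)
  # fitted variogram families are nondecreasing in lag
  for (fam in c("spherical", "exponential", "gaussian")) {
    vgf <- fit_variogram(xy, v, model = fam)
    h <- seq(0.01, 60, length.out = 100)
    g <- variogram_gamma(vgf, h)
    expect_true(all(diff(g) >= -1e-9))
  }
})

test_that("ordinary kriging is exact, unbiased and weight-normalized", {
  set.seed(3)
  xy <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  v <- sin(xy[, 1]) + 0.3 * xy[, 2]
  vg <- structure(list(model = "spherical", nugget = 0, partial_sill = 1,
                       range = 5), class = "variogram_model")
  # exact at data locations with zero nugget
  at_data <- ordinary_kriging(xy, v, vg, targets = xy[1:6, ])
  expect_equal(at_data$prediction, v[1:6], tolerance = 1e-10)
  # constant data reproduce the constant everywhere
  tg <- cbind(runif(8, 0, 10), runif(8, 0, 10))
  const <- ordinary_kriging(xy, rep(7, 15), vg, targets = tg)
  expect_equal(const$prediction, rep(7, 8), tolerance = 1e-10)
  # weights sum to one at every target
  w <- ordinary_kriging(xy, v, vg, targets = tg, return_weights = TRUE)
  expect_equal(rowSums(w$weights), rep(1, 8), tolerance = 1e-10)
  expect_error(ordinary_kriging(xy[1:2, ], v[1:2], vg, targets = tg), "3")
})

test_that("kriging matches an independent covariance-form dense solve", {
  set.seed(4)
  n <- 18
  xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  v <- cos(xy[, 1] / 2) + 0.2 * xy[, 2] + rnorm(n, 0, 0.1)
  vg <- structure(list(model = "exponential", nugget = 0.05,
                       partial_sill = 0.8, range = 4),
                  class = "variogram_model")
  tg <- cbind(runif(5, 1, 9), runif(5, 1, 9))
  got <- ordinary_kriging(xy, v, vg, targets = tg)

  # oracle: covariance formulation C(h) = sill - gamma(h)
  sill <- vg$nugget + vg$partial_sill
  dmat <- as.matrix(dist(xy))
  C <- sill - variogram_gamma(vg, dmat)
  diag(C) <- sill
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  oracle <- vapply(seq_len(nrow(tg)), function(t) {
    d0 <- sqrt((xy[, 1] - tg[t, 1])^2 + (xy[, 2] - tg[t, 2])^2)
    b <- c(sill - variogram_gamma(vg, d0), 1)
    sol <- solve(A, b)
    sum(sol[1:n] * v)
  }, numeric(1))
  expect_equal(got$prediction, oracle, tolerance = 1e-8)
})

test_that("duplicate data locations are averaged with a warning", {
  xy <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  v <- c(1, 3, 5, 6, 7)
  vg <- structure(list(model = "spherical", nugget = 0, partial_sill = 1,
                       range = 2), class = "variogram_model")
  expect_warning(got <- ordinary_kriging(xy, v, vg, targets = cbind(0, 0)),
                 "duplicate")
  expect_equal(got$prediction, 2)  # mean of the duplicated values
})

test_that("regional geometric means follow the log-mean definition", {
  expect_equal(regional_geometric_mean(c(1, 100), c("A", "A"))$geometric_mean,
               10)
  expect_equal(regional_geometric_mean(c(2, 4, 8), rep("A", 3))$geometric_mean,
               4)
  out <- regional_geometric_mean(c(5, 5, 5, 2, 8), c("A", "A", "A", "B", "B"))
  expect_equal(out$geometric_mean[out$region == "A"], 5)
  expect_equal(out$cv[out$region == "A"], 0)
  expect_equal(out$n, c(3, 2))
  expect_error(regional_geometric_mean(c(1, -2, 3), rep("A", 3)), "2")
})

test_that("gridded bioaccessibility maps respect bounds and nodata", {
  soil <- generate_soil_dataset(150, seed = 5)
  frame <- prepare_model_frame(soil)
  rf <- rf_grid_fit(frame, seed = 6)
  grid <- generate_property_grid(10, 10, seed = 7)
  ids <- sort(unique(as.vector(grid$values$region_id)))
  regional_cd <- data.frame(region_id = ids,
                            cd_total = c(0.5, 1, 2, 4)[seq_along(ids)])
  mapped <- map_national_bioaccessibility(rf, grid, regional_cd)
  bp <- as.vector(mapped$grid$values$ba_percent)
  expect_true(all(bp > 0 & bp <= 100))
  expect_equal(nrow(mapped$regional), length(ids))
  expect_true(all(mapped$regional$geometric_mean > 0))

  # nodata propagates per cell
  grid$values$ph[1, 1] <- NA
  mapped2 <- map_national_bioaccessibility(rf, grid, regional_cd)
  expect_true(is.na(mapped2$grid$values$ba_percent[1, 1]))
  expect_false(anyNA(mapped2$grid$values$ba_percent[-1, ]))

  # uniform properties + one regional Cd value -> uniform map
  gconst <- generate_property_grid(8, 8, constant = TRUE)
  gconst$values$region_id[] <- 1
  mapped3 <- map_national_bioaccessibility(
    rf, gconst, data.frame(region_id = 1, cd_total = 1))
  expect_equal(length(unique(as.vector(mapped3$grid$values$ba_percent))), 1)

  expect_error(map_national_bioaccessibility(
    rf, grid, data.frame(region_id = 1, cd_total = 1)), "region id")
})
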