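# Spatial interpolation: empirical variograms, weighted-least-squares
# variogram fitting, ordinary kriging, and regional aggregation by
# geometric mean. Coordinates are planar Cartesian; rasters are abstract
# regular grids with cell-center convention.

#' Semivariance of a fitted variogram model at lag h
#'
#' Families use the practical-range convention: `range` is the distance at
#' which the exponential/gaussian models reach ~95% of the sill.
#'
#' @param vgm A `variogram_model`.
#' @param h Nonnegative lags.
#' @return Semivariance values; `gamma(0) = 0` (nugget is a discontinuity
#'   at the origin).
#' @export
variogram_gamma <- function(vgm, h) {
  n <- vgm$nugget; p <- vgm$partial_sill; a <- vgm$range
  g <- switch(vgm$model,
    spherical = ifelse(h < a, p * (1.5 * h / a - 0.5 * (h / a)^3), p),
    exponential = p * (1 - exp(-3 * h / a)),
    gaussian = p * (1 - exp(-3 * (h / a)^2)),
    stop("unknown variogram family", call. = FALSE))
  ifelse(h == 0, 0, n + g)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' @param coords Two-column coordinate matrix.
#' @param values Numeric vector of the same length.
#' @param n_lags Number of lag bins.
#' @param cutoff Maximum lag considered; defaults to half the maximum
#'   pairwise distance.
#' @return `data.frame` with `lag` (bin center of mass), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_lags = 12, cutoff = NULL) {
  coords <- as.matrix(coords)
  d <- as.vector(stats::dist(coords))
  pairs <- utils::combn(length(values), 2)
  sq <- (values[pairs[1, ]] - values[pairs[2, ]])^2 / 2
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d <= cutoff & d > 0
  d <- d[keep]; sq <- sq[keep]
  bins <- cut(d, breaks = seq(0, cutoff, length.out = n_lags + 1),
              include.lowest = TRUE)
  out <- data.frame(
    lag = as.vector(tapply(d, bins, mean)),
    gamma = as.vector(tapply(sq, bins, mean)),
    n_pairs = as.vector(tapply(sq, bins, length))
  )
  out$n_pairs[is.na(out$n_pairs)] <- 0
  out[!is.na(out$gamma), , drop = FALSE]
}

#' Fit a variogram model by weighted least squares
#'
#' Computes the Matheron empirical semivariogram and fits the chosen family
#' by minimising `sum(N_j * (gamma_j - model_j)^2 / model_j^2)` (Cressie
#' weights) over nugget, partial sill and range.
#'
#' @param coords Two-column coordinate matrix (>= 10 points).
#' @param values Numeric vector.
#' @param n_lags Number of lag bins.
#' @param model Family: `"spherical"` (default), `"exponential"`,
#'   `"gaussian"`.
#' @param cutoff Maximum lag (default half the maximum distance).
#' @return An object of class `variogram_model` with `model`, `nugget`,
#'   `partial_sill`, `range` and the `empirical` bins.
#' @export
fit_variogram <- function(coords, values, n_lags = 12,
                          model = c("spherical", "exponential", "gaussian"),
                          cutoff = NULL) {
  model <- match.arg(model)
  coords <- as.matrix(coords)
  if (nrow(coords) < 10) stop("need >= 10 points", call. = FALSE)
  emp <- empirical_variogram(coords, values, n_lags, cutoff)
  if (all(emp$gamma < .Machine$double.eps)) {
    warning("constant field: degenerate variogram (nugget = sill = 0)")
    return(structure(list(model = model, nugget = 0, partial_sill = 0,
                          range = max(emp$lag), empirical = emp),
                     class = "variogram_model"))
  }
  s2 <- stats::var(values)
  obj <- function(par) {
    vg <- list(model = model, nugget = par[1]^2, partial_sill = par[2]^2,
               range = par[3]^2)
    g <- variogram_gamma(vg, emp$lag)
    g <- pmax(g, 1e-10)
    sum(emp$n_pairs * (emp$gamma - g)^2 / g^2)
  }
  init <- c(sqrt(s2 * 0.1), sqrt(s2 * 0.9), sqrt(max(emp$lag) / 2))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(model = model, nugget = fit$par[1]^2,
                 partial_sill = fit$par[2]^2, range = fit$par[3]^2,
                 empirical = emp),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g\n",
              x$model, x$nugget, x$partial_sill, x$range))
  invisible(x)
}

#' Ordinary kriging interpolation
#'
#' Solves the ordinary-kriging system in semivariance form with the
#' unbiasedness constraint (weights sum to one) for every target location.
#' Duplicate data locations are averaged before solving (with a warning).
#' With a zero-nugget model the predictor is exact at data locations.
#'
#' @param coords Two-column matrix of data coordinates (>= 3 points).
#' @param values Data values.
#' @param variogram A `variogram_model`.
#' @param targets Either a two-column coordinate matrix or a `grid_field`
#'   (all cell centers are predicted).
#' @param max_neighbors Optional neighborhood size; if set, each target
#'   uses only its nearest `max_neighbors` data points.
#' @param return_weights If `TRUE`, also return the weight matrix
#'   (targets x data).
#' @return If `targets` is a `grid_field`: that grid with an added
#'   `kriged` property. Otherwise a list with `prediction`, `variance`
#'   and optionally `weights`.
#' @export
ordinary_kriging <- function(coords, values, variogram, targets,
                             max_neighbors = NULL, return_weights = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need >= 3 points", call. = FALSE)
  key <- paste(coords[, 1], coords[, 2], sep = "_")
  if (anyDuplicated(key)) {
    warning("duplicate data locations averaged before kriging")
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    coords <- coords[first, , drop = FALSE]
    values <- as.numeric(agg[paste(coords[, 1], coords[, 2], sep = "_")])
  }
  as_grid <- inherits(targets, "grid_field")
  tcoords <- if (as_grid) grid_coords(targets) else as.matrix(targets)
  n <- nrow(coords)
  m <- nrow(tcoords)

  solve_block <- function(didx, tidx) {
    nd <- length(didx)
    dmat <- as.matrix(stats::dist(coords[didx, , drop = FALSE]))
    A <- rbind(cbind(variogram_gamma(variogram, dmat), 1), c(rep(1, nd), 0))
    d0 <- sqrt(outer(tcoords[tidx, 1], coords[didx, 1], "-")^2 +
                 outer(tcoords[tidx, 2], coords[didx, 2], "-")^2)
    B <- rbind(t(variogram_gamma(variogram, d0)), 1)
    sol <- solve(A, B)
    w <- sol[seq_len(nd), , drop = FALSE]
    list(pred = as.numeric(crossprod(w, values[didx])),
         var = pmax(0, colSums(sol * B)),
         w = t(w))
  }

  if (is.null(max_neighbors) || max_neighbors >= n) {
    res <- solve_block(seq_len(n), seq_len(m))
    pred <- res$pred; krig_var <- res$var; wmat <- res$w
  } else {
    pred <- krig_var <- numeric(m)
    wmat <- matrix(0, m, n)
    for (t in seq_len(m)) {
      dd <- sqrt((coords[, 1] - tcoords[t, 1])^2 +
                   (coords[, 2] - tcoords[t, 2])^2)
      didx <- order(dd)[seq_len(max_neighbors)]
      res <- solve_block(didx, t)
      pred[t] <- res$pred; krig_var[t] <- res$var
      wmat[t, didx] <- res$w
    }
  }

  if (as_grid) {
    targets$values$kriged <- matrix(pred, nrow = targets$ny,
                                    ncol = targets$nx)
    return(targets)
  }
  out <- list(prediction = pred, variance = krig_var)
  if (return_weights) out$weights <- wmat
  out
}

#' Regional geometric means with coefficients of variation
#'
#' Per-region `exp(mean(log(x)))` with arithmetic `CV = 100 * sd / mean`.
#'
#' @param values Strictly positive values.
#' @param region_labels Region label per value.
#' @return `data.frame` with `region`, `geometric_mean`, `n`, `cv`.
#' @export
regional_geometric_mean <- function(values, region_labels) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("nonpositive value at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  regions <- sort(unique(region_labels))
  out <- do.call(rbind, lapply(regions, function(r) {
    v <- values[region_labels == r]
    data.frame(region = r, geometric_mean = exp(mean(log(v))),
               n = length(v),
               cv = if (length(v) > 1) 100 * stats::sd(v) / mean(v) else 0,
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Predict bioaccessibility over a property grid with regional Cd means
#'
#' For every grid cell, builds the model covariates from the cell's soil
#' properties and the geometric-mean total Cd of the cell's region, then
#' back-transforms to bioaccessible content and percent. Cells with any
#' missing covariate propagate nodata. Optionally smooths the percent
#' surface by ordinary kriging fitted on (a subsample of) the cells.
#'
#' @param model Fitted model (log-scale predictor).
#' @param grid `grid_field` holding the model covariates plus `region_id`.
#' @param regional_cd `data.frame` with `region_id` and `cd_total`
#'   (regional geometric-mean total Cd, mg/kg).
#' @param krige If `TRUE`, add a `ba_percent_kriged` property.
#' @param krige_sample Max cells used to fit the smoothing variogram.
#' @param seed Optional seed for the kriging subsample.
#' @return A list: `grid` (with `ba_content` and `ba_percent` properties)
#'   and `regional` (regional geometric means of `ba_percent`).
#' @export
map_national_bioaccessibility <- function(model, grid, regional_cd,
                                          krige = FALSE, krige_sample = 400,
                                          seed = NULL) {
  stopifnot(inherits(grid, "grid_field"))
  if (!"region_id" %in% names(grid$values)) {
    stop("grid must carry a `region_id` property", call. = FALSE)
  }
  rid <- as.vector(grid$values$region_id)
  cd_lookup <- stats::setNames(regional_cd$cd_total, regional_cd$region_id)
  unknown <- setdiff(unique(rid[!is.na(rid)]), as.numeric(names(cd_lookup)))
  if (length(unknown)) {
    stop("no regional Cd value for region id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cd <- unname(cd_lookup[as.character(rid)])

  covars <- setdiff(names(grid$values), "region_id")
  newdata <- as.data.frame(lapply(grid$values[covars], as.vector))
  newdata$cd_total <- cd
  newdata$log_cd <- log(cd)
  complete <- stats::complete.cases(newdata)

  ba_content <- ba_percent <- rep(NA_real_, length(cd))
  if (any(complete)) {
    pb <- predict_bioaccessibility(model, newdata[complete, , drop = FALSE],
                                   cd_total = cd[complete])
    ba_content[complete] <- pb$ba_content
    ba_percent[complete] <- pb$ba_percent
  }
  grid$values$ba_content <- matrix(ba_content, grid$ny, grid$nx)
  grid$values$ba_percent <- matrix(ba_percent, grid$ny, grid$nx)

  ok <- complete & is.finite(ba_percent)
  regional <- regional_geometric_mean(ba_percent[ok],
                                      sprintf("region_%d", as.integer(rid[ok])))

  if (krige) {
    if (!is.null(seed)) set.seed(seed)
    cells <- which(ok)
    if (length(cells) > krige_sample) {
      cells <- sort(sample(cells, krige_sample))
    }
    xy <- grid_coords(grid)[cells, , drop = FALSE]
    vgm <- fit_variogram(xy, ba_percent[cells])
    smoothed <- ordinary_kriging(xy, ba_percent[cells], vgm, grid)
    grid$values$ba_percent_kriged <- smoothed$values$kriged
  }
  list(grid = grid, regional = regional)
}
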