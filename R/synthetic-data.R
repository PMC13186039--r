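# Synthetic soil/bioaccessibility data generator.
#
# The generator reproduces the statistical structure of compiled national
# soil Cd bioaccessibility surveys: soil properties bounded by the published
# survey ranges, a three-part texture composition summing to 100, a
# multinomial in-vitro method mixture dominated by PBET, and an
# intestinal-phase bioaccessible Cd content that is log-linear in total Cd
# and sand fraction with an optional pH x Cd interaction.

.soil_ranges <- list(
  ph   = c(3.01, 11.37),
  som  = c(0.17, 131.03),
  clay = c(0.02, 44.43),
  silt = c(10.82, 78.26),
  sand = c(2.30, 89.16)
)

.method_levels <- c("PBET", "UBM", "DIN", "IVG", "SBET")

.method_mix <- c(PBET = 0.733, UBM = 0.158,
                 DIN = 0.109 / 3, IVG = 0.109 / 3, SBET = 0.109 / 3)

.region_levels <- c("NEC", "NC", "NWC", "EC", "CC", "SC", "SWC")

#' Generative ground truth for the soil Cd simulator
#'
#' Defines the data-generating process for intestinal-phase bioaccessible Cd
#' content on the natural-log scale:
#' \deqn{\ln BA_{ip} = b_0 + b_1 \ln Cd + b_2 \, sand
#'   + i \,(pH - 7)\, \ln Cd + shift_{method} + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' The interaction term makes high pH suppress bioaccessibility in
#' low-Cd soils but not in heavily contaminated ones, the nonlinearity a
#' forest model can exploit and a main-effects linear model cannot.
#'
#' Defaults give a dominant log-linear dependence on total Cd (unit slope)
#' and sand, a median bioaccessibility around 10%, and method offsets such
#' that PBET and UBM are exchangeable while DIN/IVG/SBET are shifted.
#'
#' @param b0 Intercept on the log scale.
#' @param b1_logcd Slope on `log(cd_total)`.
#' @param b2_sand Slope on sand percentage.
#' @param interaction_strength Nonnegative coefficient of the
#'   `(pH - 7) * log(cd_total)` interaction; 0 gives a purely affine truth.
#' @param sigma_noise Log-scale Gaussian noise standard deviation (>= 0).
#' @param method_shifts Named additive log-scale offsets, one per in-vitro
#'   method (`PBET`, `UBM`, `DIN`, `IVG`, `SBET`).
#' @return An object of class `cd_ground_truth`.
#' @export
#' @examples
#' truth <- default_ground_truth(sigma_noise = 0)
default_ground_truth <- function(b0 = -3.0, b1_logcd = 1.0, b2_sand = 0.02,
                                 interaction_strength = 0.15,
                                 sigma_noise = 0.35,
                                 method_shifts = c(PBET = 0, UBM = 0,
                                                   DIN = 0.4, IVG = 0.5,
                                                   SBET = -0.4)) {
  if (sigma_noise < 0) {
    stop("`sigma_noise` must be >= 0", call. = FALSE)
  }
  if (interaction_strength < 0) {
    stop("`interaction_strength` must be >= 0", call. = FALSE)
  }
  if (!all(.method_levels %in% names(method_shifts))) {
    stop("`method_shifts` must name all of: ",
         paste(.method_levels, collapse = ", "), call. = FALSE)
  }
  structure(list(b0 = b0, b1_logcd = b1_logcd, b2_sand = b2_sand,
                 interaction_strength = interaction_strength,
                 sigma_noise = sigma_noise,
                 method_shifts = method_shifts[.method_levels]),
            class = "cd_ground_truth")
}

# truncated samplers: plain rejection, bounds are hard survey limits
.rtrunc <- function(n, rfun, lower, upper, max_tries = 1000L) {
  out <- rfun(n)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    out[bad] <- rfun(length(bad))
    bad <- bad[out[bad] < lower | out[bad] > upper]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) stop("truncated sampler failed to converge", call. = FALSE)
  out
}

# 3-part Dirichlet-like texture composition inside the survey ranges,
# renormalised to exactly 100
.rtexture <- function(n, alpha = c(clay = 8, silt = 18, sand = 14)) {
  draw <- function(m) {
    g <- cbind(stats::rgamma(m, alpha[1]), stats::rgamma(m, alpha[2]),
               stats::rgamma(m, alpha[3]))
    100 * g / rowSums(g)
  }
  out <- draw(n)
  ok <- function(x) {
    x[, 1] >= .soil_ranges$clay[1] & x[, 1] <= .soil_ranges$clay[2] &
      x[, 2] >= .soil_ranges$silt[1] & x[, 2] <= .soil_ranges$silt[2] &
      x[, 3] >= .soil_ranges$sand[1] & x[, 3] <= .soil_ranges$sand[2]
  }
  bad <- which(!ok(out))
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    out[bad, ] <- draw(length(bad))
    bad <- bad[!ok(out[bad, , drop = FALSE])]
    tries <- tries + 1L
  }
  colnames(out) <- c("clay", "silt", "sand")
  out
}

#' Simulate a compiled soil Cd bioaccessibility dataset
#'
#' Draws `n` soil samples whose physicochemical properties fall inside the
#' published survey ranges (pH 3.01-11.37, SOM 0.17-131.03 g/kg, clay
#' 0.02-44.43%, silt 10.82-78.26%, sand 2.30-89.16%), with in-vitro method
#' labels drawn from the compiled mixture (PBET 73.3%, UBM 15.8%, others
#' 10.9% combined) and intestinal- and gastric-phase bioaccessible Cd
#' contents generated from `truth` and clipped to the physical bound
#' `ba <= cd_total`.
#'
#' @param n Number of samples (>= 10).
#' @param truth A [default_ground_truth()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return A `data.frame` with columns `sample_id`, `ph`, `som`, `cec`,
#'   `fe`, `clay`, `silt`, `sand`, `cd_total`, `ba_content_gp`,
#'   `ba_content_ip`, `method`, `region`.
#' @export
#' @examples
#' soil <- generate_soil_dataset(50, seed = 1)
#' stopifnot(all(soil$ba_content_ip <= soil$cd_total))
generate_soil_dataset <- function(n, truth = default_ground_truth(),
                                  seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop("`n` must be a single count >= 10", call. = FALSE)
  }
  if (!inherits(truth, "cd_ground_truth")) {
    stop("`truth` must be a `cd_ground_truth` object", call. = FALSE)
  }
  if (truth$sigma_noise < 0) stop("negative `sigma_noise`", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  ph <- .rtrunc(n, function(m) stats::rnorm(m, 6.8, 1.5),
                .soil_ranges$ph[1], .soil_ranges$ph[2])
  som <- .rtrunc(n, function(m) stats::rlnorm(m, log(15), 0.9),
                 .soil_ranges$som[1], .soil_ranges$som[2])
  cec <- .rtrunc(n, function(m) stats::rlnorm(m, log(12), 0.5), 0.5, 80)
  fe <- .rtrunc(n, function(m) stats::rlnorm(m, log(28), 0.4), 3, 150)
  tex <- .rtexture(n)
  cd_total <- .rtrunc(n, function(m) stats::rlnorm(m, log(0.8), 1.1),
                      0.005, 400)
  method <- sample(.method_levels, n, replace = TRUE, prob = .method_mix)
  region <- sample(.region_levels, n, replace = TRUE)

  mu_ip <- truth$b0 + truth$b1_logcd * log(cd_total) +
    truth$b2_sand * tex[, "sand"] +
    truth$interaction_strength * (ph - 7) * log(cd_total) +
    truth$method_shifts[method]
  eps <- stats::rnorm(n, 0, truth$sigma_noise)
  ba_ip <- pmin(exp(mu_ip + eps), cd_total)
  # gastric phase dissolves more than the intestinal phase on average
  eps_gp <- stats::rnorm(n, 0, truth$sigma_noise)
  ba_gp <- pmin(exp(mu_ip + 0.35 + eps_gp), cd_total)

  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    ph = ph, som = som, cec = cec, fe = fe,
    clay = tex[, "clay"], silt = tex[, "silt"], sand = tex[, "sand"],
    cd_total = cd_total,
    ba_content_gp = ba_gp, ba_content_ip = ba_ip,
    method = method, region = region,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Degrade a dataset with missingness and gross response outliers
#'
#' Produces fixtures for imputation and influence-diagnostic benchmarks:
#' missing-completely-at-random cells in the covariate columns (exactly
#' `floor(missing_rate * n * n_covariates)` cells) and `n_outliers` rows
#' whose `ba_content_ip` is multiplied by a gross factor. Outliers are
#' deliberately not re-clipped to `cd_total` so that a regression-influence
#' filter can catch them.
#'
#' @param samples A soil-sample `data.frame` from [generate_soil_dataset()].
#' @param missing_rate Fraction of covariate cells to blank, in `[0, 0.5)`.
#' @param n_outliers Number of response outliers to inject (< n/10).
#' @param outlier_factor Multiplicative factor applied to outlier responses.
#' @param seed Optional integer seed.
#' @return A list with `samples` (degraded table), `mask` (data.frame of
#'   row, column, true value for every blanked cell), and `outlier_ids`.
#' @export
degrade_dataset <- function(samples, missing_rate = 0.1, n_outliers = 0,
                            outlier_factor = 50, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop("`missing_rate` must be in [0, 0.5)", call. = FALSE)
  }
  n <- nrow(samples)
  if (n_outliers < 0 || n_outliers >= n / 10) {
    stop("`n_outliers` must be a count < n/10", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  covars <- intersect(c("ph", "som", "cec", "fe", "clay", "silt", "sand"),
                      names(samples))
  n_cells <- n * length(covars)
  n_miss <- floor(missing_rate * n_cells)
  mask <- data.frame(row = integer(0), column = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  if (n_miss > 0) {
    cells <- sample.int(n_cells, n_miss)
    rows <- ((cells - 1L) %% n) + 1L
    cols <- covars[((cells - 1L) %/% n) + 1L]
    mask <- data.frame(row = rows, column = cols,
                       value = vapply(seq_len(n_miss), function(i)
                         samples[rows[i], cols[i]], numeric(1)),
                       stringsAsFactors = FALSE)
    for (i in seq_len(n_miss)) samples[rows[i], cols[i]] <- NA_real_
  }
  outlier_ids <- character(0)
  if (n_outliers > 0) {
    idx <- sample.int(n, n_outliers)
    samples$ba_content_ip[idx] <- samples$ba_content_ip[idx] * outlier_factor
    outlier_ids <- samples$sample_id[idx]
  }
  list(samples = samples, mask = mask, outlier_ids = outlier_ids)
}

#' Synthetic exposure-parameter distributions per population
#'
#' Returns one distribution specification per exposure parameter of the
#' average-daily-dose equations (IngR, InhR, EF, ED, BW, SA, AF, ABF, PEF,
#' AT, BA). The values are synthetic stand-ins with handbook-plausible
#' medians; children receive a higher soil ingestion rate and a lower body
#' weight than adults, and a wider relative spread of exposure duration.
#' `AT` defaults to a point mass at the maximum exposure duration times
#' 365 d/yr, so `AT >= ED * 365` holds for every draw while exposure
#' duration retains its own variability (the alternative derived law
#' `ed365`, AT = ED x 365 per iteration, is supported by the risk engine
#' but cancels ED out of every dose).
#'
#' @param population `"adult"` or `"child"`.
#' @param region Region label; a non-`"default"` region applies a small
#'   reproducible multiplicative jitter to the location parameters.
#' @param seed Optional integer seed (only used for regional jitter).
#' @param point_mass If `TRUE`, every law collapses to a point mass at its
#'   median (zero variance).
#' @return A `data.frame` with columns `parameter`, `population`, `region`,
#'   `law`, `p1`, `p2`, `p3`, `lower`, `upper`, `units`.
#' @export
generate_exposure_distributions <- function(population = c("adult", "child"),
                                            region = "default", seed = NULL,
                                            point_mass = FALSE) {
  population <- match.arg(population)
  spec <- function(parameter, law, p1, p2 = NA_real_, p3 = NA_real_,
                   lower = NA_real_, upper = NA_real_, units = "") {
    data.frame(parameter = parameter, population = population,
               region = region, law = law, p1 = p1, p2 = p2, p3 = p3,
               lower = lower, upper = upper, units = units,
               stringsAsFactors = FALSE)
  }
  tab <- if (population == "adult") {
    rbind(
      spec("IngR", "lognormal", log(100), 0.30, lower = 20, upper = 300,
           units = "mg/d"),
      spec("InhR", "lognormal", log(14.5), 0.15, lower = 5, upper = 25,
           units = "m3/d"),
      spec("EF", "triangular", 180, 350, 365, units = "d/yr"),
      spec("ED", "triangular", 15, 25, 35, units = "yr"),
      spec("BW", "lognormal", log(60.6), 0.12, lower = 40, upper = 100,
           units = "kg"),
      spec("SA", "lognormal", log(5000), 0.15, lower = 2000, upper = 9000,
           units = "cm2"),
      spec("AF", "point", 0.07, units = "mg/cm2"),
      spec("ABF", "point", 0.001, units = "-"),
      spec("PEF", "point", 1.36e9, units = "m3/kg"),
      spec("AT", "point", 35 * 365, units = "d"),
      spec("BA", "lognormal", log(0.15), 0.5, lower = 1e-4, upper = 1,
           units = "-")
    )
  } else {
    rbind(
      spec("IngR", "lognormal", log(200), 0.35, lower = 50, upper = 600,
           units = "mg/d"),
      spec("InhR", "lognormal", log(7.5), 0.20, lower = 2, upper = 15,
           units = "m3/d"),
      spec("EF", "triangular", 180, 350, 365, units = "d/yr"),
      spec("ED", "uniform", 1, 6, units = "yr"),
      spec("BW", "lognormal", log(16), 0.15, lower = 8, upper = 30,
           units = "kg"),
      spec("SA", "lognormal", log(2000), 0.20, lower = 800, upper = 4500,
           units = "cm2"),
      spec("AF", "point", 0.2, units = "mg/cm2"),
      spec("ABF", "point", 0.001, units = "-"),
      spec("PEF", "point", 1.36e9, units = "m3/kg"),
      spec("AT", "point", 6 * 365, units = "d"),
      spec("BA", "lognormal", log(0.15), 0.5, lower = 1e-4, upper = 1,
           units = "-")
    )
  }
  if (!identical(region, "default")) {
    if (!is.null(seed)) {
      set.seed(seed + sum(utf8ToInt(region)) %% 10000L)
    }
    jit <- stats::rnorm(nrow(tab), 0, 0.05)
    loc <- tab$law == "lognormal"
    tab$p1[loc] <- tab$p1[loc] + jit[loc]
  }
  if (point_mass) {
    med <- vapply(seq_len(nrow(tab)), function(i) {
      switch(tab$law[i],
             point = tab$p1[i],
             lognormal = exp(tab$p1[i]),
             normal = tab$p1[i],
             uniform = (tab$p1[i] + tab$p2[i]) / 2,
             triangular = tab$p2[i],
             ed365 = NA_real_)
    }, numeric(1))
    keep <- tab$law != "ed365"
    tab$p1[keep] <- med[keep]
    tab$law[keep] <- "point"
    tab$p2[keep] <- NA_real_
    tab$p3[keep] <- NA_real_
    tab$lower[keep] <- NA_real_
    tab$upper[keep] <- NA_real_
  }
  row.names(tab) <- NULL
  tab
}

#' Simulate a gridded soil-property field
#'
#' Builds spatially autocorrelated raster fields (moving-average smoothing
#' of white noise) for pH, SOM and texture, rescaled into the published
#' survey ranges, plus a quadrant `region_id` layer. The texture triplet is
#' constructed so every cell satisfies clay + silt + sand = 100 with each
#' component inside its range.
#'
#' @param nx,ny Cell counts (>= 4).
#' @param cell_size Cell edge length (distance units).
#' @param smoothness Moving-average half-width in cells; 0 gives white noise.
#' @param seed Optional integer seed.
#' @param constant If `TRUE`, every property is flat at its range midpoint.
#' @return A `grid_field` object (see [grid_field()]).
#' @export
generate_property_grid <- function(nx, ny, cell_size = 1, smoothness = 3,
                                   seed = NULL, constant = FALSE) {
  if (nx < 4 || ny < 4) stop("`nx` and `ny` must be >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nx <- as.integer(nx); ny <- as.integer(ny)

  smooth_noise <- function() {
    h <- max(0L, as.integer(round(smoothness)))
    z <- matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx)
    if (h == 0L) return(z)
    out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) {
      ri <- max(1L, i - h):min(ny, i + h)
      for (j in seq_len(nx)) {
        rj <- max(1L, j - h):min(nx, j + h)
        out[i, j] <- mean(z[ri, rj])
      }
    }
    out
  }
  rescale <- function(z, lo, hi) {
    u <- stats::pnorm((z - mean(z)) / max(stats::sd(z), 1e-12))
    lo + u * (hi - lo)
  }
  mid <- function(r) matrix((r[1] + r[2]) / 2, ny, nx)

  if (constant) {
    ph <- mid(.soil_ranges$ph); som <- mid(.soil_ranges$som)
    sand <- mid(.soil_ranges$sand)
    clay <- matrix(20, ny, nx)
  } else {
    ph <- rescale(smooth_noise(), .soil_ranges$ph[1], .soil_ranges$ph[2])
    som <- rescale(smooth_noise(), .soil_ranges$som[1], .soil_ranges$som[2])
    sand <- rescale(smooth_noise(), .soil_ranges$sand[1], .soil_ranges$sand[2])
    rem <- 100 - sand
    clay_lo <- pmax(.soil_ranges$clay[1], rem - .soil_ranges$silt[2])
    clay_hi <- pmin(.soil_ranges$clay[2], rem - .soil_ranges$silt[1])
    u <- stats::pnorm(matrix(stats::rnorm(nx * ny), ny, nx))
    clay <- clay_lo + u * pmax(clay_hi - clay_lo, 0)
  }
  silt <- 100 - sand - clay
  region_id <- outer(seq_len(ny) > ny / 2, seq_len(nx) > nx / 2,
                     function(a, b) 1L + a * 2L + b * 1L)
  storage.mode(region_id) <- "double"

  grid_field(nx = nx, ny = ny, cell_size = cell_size,
             origin = c(cell_size / 2, cell_size / 2),
             values = list(ph = ph, som = som, clay = clay, silt = silt,
                           sand = sand, region_id = region_id))
}

#' Construct a regular raster container
#'
#' A `grid_field` stores one or more properties on a regular grid. Each
#' property is a `ny x nx` matrix whose row 1 is the southernmost row;
#' `origin` gives the coordinates of the lower-left *cell center*.
#'
#' @param nx,ny Cell counts.
#' @param cell_size Cell edge length.
#' @param origin Numeric length-2, lower-left cell-center coordinates.
#' @param values Named list of `ny x nx` matrices (`NA` = nodata).
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(nx, ny, cell_size = 1, origin = c(0.5, 0.5),
                       values = list()) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0, length(origin) == 2)
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.matrix(v) || nrow(v) != ny || ncol(v) != nx) {
      stop("property `", nm, "` must be a ", ny, " x ", nx, " matrix",
           call. = FALSE)
    }
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_size = cell_size, origin = as.numeric(origin),
                 values = values),
            class = "grid_field")
}

#' Cell-center coordinates of a grid
#'
#' @param grid A `grid_field`.
#' @return A two-column matrix (x, y), one row per cell, in column-major
#'   order over the `ny x nx` property matrices (south row first).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_field"))
  x <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$cell_size
  y <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$cell_size
  cbind(x = rep(x, each = grid$ny), y = rep(y, times = grid$nx))
}

#' @export
print.grid_field <- function(x, ...) {
  cat("grid_field:", x$ny, "x", x$nx, "cells, cell size", x$cell_size, "\n")
  cat("properties:", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}
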