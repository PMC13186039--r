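# Plain-text interchange: soil-sample tables and exposure tables as CSV
# (UTF-8, header row, "." decimal, empty cell = missing); rasters as ESRI
# ASCII grids.

.soil_columns <- c("sample_id", "ph", "som", "cec", "fe", "clay", "silt",
                   "sand", "cd_total", "ba_content_gp", "ba_content_ip",
                   "method", "region")

#' Write / read a soil-sample table as CSV
#'
#' @param samples Soil-sample `data.frame`.
#' @param path File path.
#' @return `write_soil_csv` returns `path` invisibly; `read_soil_csv`
#'   returns the table with canonical column order and types.
#' @export
write_soil_csv <- function(samples, path) {
  cols <- intersect(.soil_columns, names(samples))
  utils::write.csv(samples[, cols, drop = FALSE], path,
                   row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_soil_csv
#' @export
read_soil_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  num <- setdiff(intersect(.soil_columns, names(out)),
                 c("sample_id", "method", "region"))
  for (nm in num) out[[nm]] <- as.numeric(out[[nm]])
  out
}

#' Write / read exposure-parameter distribution tables as CSV
#'
#' Schema: `parameter, population, region, law, p1, p2, p3, lower, upper,
#' units`.
#'
#' @param specs Distribution-spec `data.frame`.
#' @param path File path.
#' @export
write_exposure_csv <- function(specs, path) {
  utils::write.csv(specs, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  for (nm in c("p1", "p2", "p3", "lower", "upper")) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out
}

#' Write one grid property as an ESRI ASCII grid
#'
#' Header lines `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' followed by rows north to south. `NA` cells become the nodata value.
#'
#' @param grid A `grid_field`.
#' @param property Property name to export.
#' @param path File path.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, property, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_field"))
  if (!property %in% names(grid$values)) {
    stop("unknown property `", property, "`", call. = FALSE)
  }
  v <- grid$values[[property]]
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcorner", format(grid$origin[1] - grid$cell_size / 2, digits = 15)),
    paste("yllcorner", format(grid$origin[2] - grid$cell_size / 2, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  for (i in rev(seq_len(grid$ny))) {
    writeLines(paste(format(v[i, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid into a single-property `grid_field`
#'
#' @param path File path.
#' @param property Name to give the imported property.
#' @return A `grid_field` with one property.
#' @export
read_ascii_grid <- function(path, property = "value") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  cell <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  rows <- lapply(lines[i:(i + ny - 1L)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  v <- do.call(rbind, rev(rows))   # file is north-first; store south-first
  v[v == nodata] <- NA_real_
  vals <- list(v)
  names(vals) <- property
  grid_field(nx = nx, ny = ny, cell_size = cell,
             origin = c(hdr$xllcorner + cell / 2, hdr$yllcorner + cell / 2),
             values = vals)
}
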