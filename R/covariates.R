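#' Annual covariate raster stack
#'
#' A set of environmental covariate bands on a common grid, one multi-band
#' layer per year over a contiguous year range (the mapping workflow uses
#' annual layers for 2001-2012 at 5 x 5 km resolution).
#'
#' @param grid a [vs_grid()].
#' @param band_names character vector of unique band names.
#' @param years contiguous integer year range.
#' @param data named list (one element per year, names = years) of
#'   `ny x nx x n_bands` arrays; `NA` encodes nodata.
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, band_names, years, data) {
  stopifnot(inherits(grid, "vs_grid"),
            !anyDuplicated(band_names),
            identical(as.integer(years), seq(min(years), max(years))),
            length(data) == length(years))
  names(data) <- as.character(years)
  for (a in data)
    stopifnot(identical(dim(a), c(grid$ny, grid$nx, length(band_names))))
  structure(list(grid = grid, band_names = band_names,
                 years = as.integer(years), data = data),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack %d bands x %d years (%d-%d), %d x %d px>\n",
              length(x$band_names), length(x$years), min(x$years),
              max(x$years), x$grid$ny, x$grid$nx))
  invisible(x)
}

#' Clamp a collection year to the available covariate years
#'
#' Records collected before the first covariate year use the first year's
#' layers; records after the last use the last year's (2001 and 2012 in the
#' original workflow). Idempotent and monotone.
#'
#' @param year integer vector of collection years.
#' @param years_available contiguous year range.
#' @return clamped years.
#' @export
clamp_year <- function(year, years_available) {
  as.integer(pmin(pmax(year, min(years_available)), max(years_available)))
}

#' Extract covariates at points for their collection years
#'
#' Looks up the containing pixel (no interpolation: bands are 5 x 5 km area
#' summaries) in the layer of each point's clamped collection year. Rows
#' whose pixel is nodata in any band are returned as `NA` rows; callers
#' drop and count them.
#'
#' @param stack a [covariate_stack()].
#' @param points data.frame with columns `x`, `y`.
#' @param year_per_point integer vector (recycled) of collection years.
#' @return numeric matrix, one row per point, columns = band names, with
#'   attribute `"year_used"` (the clamped years).
#' @export
extract_at_points <- function(stack, points, year_per_point) {
  n <- nrow(points)
  yr <- clamp_year(rep_len(year_per_point, n), stack$years)
  cc <- cell_at(stack$grid, points$x, points$y)
  if (any(!cc$inside))
    stop("point(s) outside covariate extent: ",
         paste(head(which(!cc$inside), 10), collapse = ", "))
  nb <- length(stack$band_names)
  out <- matrix(NA_real_, n, nb, dimnames = list(NULL, stack$band_names))
  for (y in unique(yr)) {
    sel <- which(yr == y)
    arr <- stack$data[[as.character(y)]]
    for (b in seq_len(nb))
      out[sel, b] <- arr[cbind(cc$row[sel], cc$col[sel], b)]
  }
  attr(out, "year_used") <- yr
  out
}

#' Covariate matrix of all valid pixels for one year
#'
#' Flattens one year's layers into a prediction matrix with one row per
#' pixel that is non-nodata in every band, plus the linear pixel index
#' needed to put predictions back on the grid.
#'
#' @param stack a [covariate_stack()].
#' @param year prediction year (clamped; default = most recent layer).
#' @return list with `matrix` (rows = valid pixels, columns = bands) and
#'   `index` (column-major pixel indices into the grid).
#' @export
prediction_matrix <- function(stack, year = max(stack$years)) {
  y <- clamp_year(year, stack$years)
  arr <- stack$data[[as.character(y)]]
  nb <- length(stack$band_names)
  m <- matrix(arr, stack$grid$ny * stack$grid$nx, nb,
              dimnames = list(NULL, stack$band_names))
  valid <- rowSums(is.na(m)) == 0
  list(matrix = m[valid, , drop = FALSE], index = which(valid),
       year = y, grid = stack$grid)
}

#' Reassemble a pixel-value vector into a raster
#'
#' Inverse of [prediction_matrix()]: values land at their pixel indices,
#' everything else is nodata.
#'
#' @param values numeric vector, one per index.
#' @param index column-major pixel indices.
#' @param grid the [vs_grid()].
#' @return a [vs_raster()].
#' @export
raster_from_vector <- function(values, index, grid) {
  stopifnot(length(values) == length(index))
  v <- matrix(NA_real_, grid$ny, grid$nx)
  v[index] <- values
  vs_raster(grid, v)
}

#' Covariate stack I/O
#'
#' One ESRI ASCII grid per year and band, named
#' `covariates_<year>_b<band index>.asc`, plus a `covariates.json` manifest
#' holding the band names, year range and CRS tag.
#'
#' @param stack a [covariate_stack()].
#' @param dir output directory (created if missing).
#' @export
write_covariates <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (y in stack$years) {
    arr <- stack$data[[as.character(y)]]
    for (b in seq_len(dim(arr)[3]))
      write_raster_asc(vs_raster(stack$grid, arr[, , b]),
                       file.path(dir, sprintf("covariates_%d_b%02d.asc",
                                              y, b)))
  }
  jsonlite::write_json(
    list(band_names = stack$band_names, years = stack$years,
         crs = stack$grid$crs),
    file.path(dir, "covariates.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "covariates.json"),
                             simplifyVector = TRUE)
  years <- as.integer(man$years)
  grid <- NULL
  data <- lapply(years, function(y) {
    arr <- NULL
    for (b in seq_along(man$band_names)) {
      r <- read_raster_asc(file.path(dir, sprintf("covariates_%d_b%02d.asc",
                                                  y, b)), crs = man$crs)
      if (is.null(arr))
        arr <- array(NA_real_, c(r$grid$ny, r$grid$nx,
                                 length(man$band_names)))
      grid <<- r$grid
      arr[, , b] <- r$values
    }
    arr
  })
  covariate_stack(grid, man$band_names, years, data)
}
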