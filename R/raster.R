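#' Planar raster grid
#'
#' Defines a regular grid in planar kilometre coordinates (1 pixel = 5 km by
#' default, mirroring a 5 x 5 km mapping resolution). Row 1 of the value
#' matrix is the top (north) row; pixels are half-open in both axes, so a
#' point on an interior pixel boundary belongs to the pixel to its
#' east/south, deterministically.
#'
#' @param nx,ny number of columns and rows (pixels).
#' @param xmin,ymin lower-left corner of the extent, in km.
#' @param pixel pixel edge length in km.
#' @param crs coordinate tag, `"planar-km"` or `"geographic"`.
#' @return an object of class `vs_grid`.
#' @export
vs_grid <- function(nx, ny, xmin = 0, ymin = 0, pixel = 5,
                    crs = "planar-km") {
  stopifnot(nx >= 1, ny >= 1, pixel > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 xmin = xmin, ymin = ymin, pixel = pixel,
                 xmax = xmin + nx * pixel, ymax = ymin + ny * pixel,
                 crs = crs),
            class = "vs_grid")
}

#' Single-band raster on a `vs_grid`
#'
#' @param grid a [vs_grid()].
#' @param values matrix `ny x nx` (row 1 = top) or a single value to fill.
#'   `NA` encodes nodata.
#' @return an object of class `vs_raster`.
#' @export
vs_raster <- function(grid, values = NA_real_) {
  stopifnot(inherits(grid, "vs_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$ny, grid$nx)
  stopifnot(nrow(values) == grid$ny, ncol(values) == grid$nx)
  structure(list(grid = grid, values = values), class = "vs_raster")
}

#' @export
print.vs_grid <- function(x, ...) {
  cat(sprintf("<vs_grid %d x %d px, %.6g km/px, extent [%g,%g] x [%g,%g], %s>\n",
              x$nx, x$ny, x$pixel, x$xmin, x$xmax, x$ymin, x$ymax, x$crs))
  invisible(x)
}

#' @export
print.vs_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<vs_raster %d x %d px, %d nodata, range [%.4g, %.4g]>\n",
              x$grid$ny, x$grid$nx, sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Pixel centre coordinates
#'
#' @param grid a [vs_grid()].
#' @param rows,cols integer vectors of equal length.
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(grid, rows, cols) {
  data.frame(x = grid$xmin + (cols - 0.5) * grid$pixel,
             y = grid$ymax - (rows - 0.5) * grid$pixel)
}

#' Locate points on the grid
#'
#' Maps planar coordinates to (row, col) indices under the half-open pixel
#' convention with origin at the upper-left.
#'
#' @param grid a [vs_grid()].
#' @param x,y coordinate vectors.
#' @return data.frame with columns `row`, `col` and logical `inside`.
#' @export
cell_at <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$pixel) + 1L
  row <- floor((grid$ymax - y) / grid$pixel) + 1L
  inside <- !is.na(x) & !is.na(y) &
    x >= grid$xmin & x < grid$xmax & y > grid$ymin & y <= grid$ymax
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract raster values at points
#'
#' @param r a [vs_raster()].
#' @param x,y coordinate vectors.
#' @return numeric vector; `NA` for nodata pixels.
#' @export
raster_extract <- function(r, x, y) {
  cc <- cell_at(r$grid, x, y)
  if (any(!cc$inside))
    stop("point(s) outside raster extent: ",
         paste(which(!cc$inside), collapse = ", "))
  r$values[cbind(cc$row, cc$col)]
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a[c("nx", "ny", "xmin", "ymin", "pixel")],
                   b[c("nx", "ny", "xmin", "ymin", "pixel")])) &&
    identical(a$crs, b$crs)
}

#' Raster I/O in ESRI ASCII grid format
#'
#' Plain-text single-band raster format: a six-line header
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`) followed by
#' rows of values, top row first. Values are written with 17 significant
#' digits, enough to round-trip doubles. The format carries no CRS, so the
#' tag is an argument to [read_raster_asc()]; planar kilometre coordinates
#' are the package-wide convention for synthetic worlds.
#'
#' @param r a [vs_raster()].
#' @param path output file path (`.asc`).
#' @param nodata value standing for `NA` in the file.
#' @export
write_raster_asc <- function(r, path, nodata = -9999) {
  g <- r$grid
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.17g\n",
                        "yllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g"),
                 g$nx, g$ny, g$xmin, g$ymin, g$pixel, nodata)
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @param crs CRS tag to attach to the grid.
#' @export
read_raster_asc <- function(path, crs = "planar-km") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[[`, "", 2))
  names(vals) <- keys
  nx <- as.integer(vals[["ncols"]]); ny <- as.integer(vals[["nrows"]])
  v <- t(vapply(lines[7:(6 + ny)],
                function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                numeric(nx), USE.NAMES = FALSE))
  v[v == vals[["nodata_value"]]] <- NA_real_
  vs_raster(vs_grid(nx, ny, vals[["xllcorner"]], vals[["yllcorner"]],
                    vals[["cellsize"]], crs), v)
}
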