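#' Species range geometry
#'
#' A species range is a union of buffered shapes. Each shape is a polygon
#' ring (possibly degenerate: a single point, standing for a disc centre)
#' plus a non-negative buffer distance; a point belongs to the shape if it
#' falls inside the ring or within the buffer distance of its boundary.
#' This representation makes buffering exact (it only increments the
#' per-shape distance) and containment queries cheap, at the price of
#' computing areas by rasterisation (see [range_area()]).
#'
#' @param species species label.
#' @param polygons a single open `N x 2` ring matrix or a list of them.
#' @param buffers per-shape buffer distance(s), km; recycled.
#' @param crs `"planar-km"` (Euclidean) or `"geographic"`.
#' @return object of class `species_range`.
#' @export
species_range <- function(species, polygons, buffers = 0,
                          crs = "planar-km") {
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (length(polygons) == 0) stop("range must contain at least one polygon")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) >= 3) validate_ring(p) else p
  })
  buffers <- rep_len(as.numeric(buffers), length(polygons))
  stopifnot(all(buffers >= 0))
  shapes <- Map(function(p, b) list(ring = p, buffer = b), polygons, buffers)
  structure(list(species = species, shapes = shapes, crs = crs),
            class = "species_range")
}

#' @export
print.species_range <- function(x, ...) {
  cat(sprintf("<species_range '%s': %d shape(s), buffers [%g, %g] km, %s>\n",
              x$species, length(x$shapes),
              min(vapply(x$shapes, `[[`, 0, "buffer")),
              max(vapply(x$shapes, `[[`, 0, "buffer")), x$crs))
  invisible(x)
}

#' Point-in-range test
#'
#' @param range a [species_range()].
#' @param x,y coordinate vectors.
#' @return logical vector: inside the union of buffered shapes.
#' @export
range_contains <- function(range, x, y) {
  inside <- rep(FALSE, length(x))
  for (s in range$shapes) {
    todo <- !inside
    if (!any(todo)) break
    hit <- if (nrow(s$ring) >= 3)
      point_in_ring(x[todo], y[todo], s$ring) else rep(FALSE, sum(todo))
    if (s$buffer > 0 || nrow(s$ring) < 3) {
      miss <- !hit
      if (any(miss)) {
        d <- point_ring_distance(x[todo][miss], y[todo][miss], s$ring)
        hit[miss] <- d <= s$buffer
      }
    }
    inside[todo] <- hit
  }
  inside
}

#' Buffer a species range
#'
#' Enlarges the range by a fixed distance in every direction, the device
#' used to absorb uncertainty in mapped range limits (300 km in the vector
#' mapping workflow this package implements). Buffering is exact for the
#' membership predicate: it adds `distance_km` to each shape's buffer.
#'
#' @param range a [species_range()].
#' @param distance_km buffer distance, km; `>= 0`.
#' @return the buffered [species_range()].
#' @export
buffer_range <- function(range, distance_km = 300) {
  stopifnot(distance_km >= 0)
  range$shapes <- lapply(range$shapes, function(s) {
    s$buffer <- s$buffer + distance_km
    s
  })
  range
}

#' Extend a range to cover confirmed records
#'
#' Molecularly confirmed presences falling outside the mapped range trigger
#' an extension: a disc of radius `disc_km` around each such point is
#' unioned into the range, so the new locations are encompassed without
#' inflating the range wholesale.
#'
#' @param range a [species_range()].
#' @param presences data.frame with columns `x`, `y`.
#' @param disc_km radius of the disc added around each outside point.
#' @return the extended [species_range()]; records the number of outside
#'   points in attribute `"n_extended"`.
#' @export
extend_range <- function(range, presences, disc_km = 25) {
  if (NROW(presences) == 0) {
    attr(range, "n_extended") <- 0L
    return(range)
  }
  out <- !range_contains(range, presences$x, presences$y)
  if (any(out)) {
    discs <- lapply(which(out), function(i)
      list(ring = matrix(c(presences$x[i], presences$y[i]), 1, 2),
           buffer = disc_km))
    range$shapes <- c(range$shapes, discs)
  }
  attr(range, "n_extended") <- sum(out)
  range
}

#' Composite range for a species complex or group
#'
#' Union of member-species ranges, then extension by the pooled confirmed
#' presences of all members.
#'
#' @param ranges list of [species_range()] objects (>= 1).
#' @param presences data.frame with `x`, `y` (pooled presences); may be
#'   empty.
#' @param species label for the composite taxon.
#' @param disc_km passed to [extend_range()].
#' @return a [species_range()].
#' @export
composite_range <- function(ranges, presences = NULL,
                            species = "composite", disc_km = 25) {
  if (length(ranges) == 0) stop("composite_range needs at least one range")
  crs <- unique(vapply(ranges, `[[`, "", "crs"))
  if (length(crs) != 1) stop("member ranges use different CRS tags")
  out <- structure(list(species = species,
                        shapes = do.call(c, lapply(ranges, `[[`, "shapes")),
                        crs = crs),
                   class = "species_range")
  if (!is.null(presences)) out <- extend_range(out, presences, disc_km)
  out
}

#' Range area by rasterisation
#'
#' Buffered shapes have no closed-form union area in general, so area is
#' measured by point-in-range tests at the centres of a fine grid laid over
#' the buffered bounding box. The relative error is of order
#' (boundary length x cell size) / area.
#'
#' @param range a [species_range()].
#' @param n number of cells along the longer bounding-box side.
#' @return area in squared coordinate units.
#' @export
range_area <- function(range, n = 600) {
  bb <- range_bbox(range)
  w <- bb[2] - bb[1]; h <- bb[4] - bb[3]
  step <- max(w, h) / n
  xs <- seq(bb[1] + step / 2, bb[2], by = step)
  ys <- seq(bb[3] + step / 2, bb[4], by = step)
  pts <- expand.grid(x = xs, y = ys)
  sum(range_contains(range, pts$x, pts$y)) * step * step
}

range_bbox <- function(range) {
  xs <- unlist(lapply(range$shapes, function(s) s$ring[, 1] + c(-1, 1) * s$buffer))
  ys <- unlist(lapply(range$shapes, function(s) s$ring[, 2] + c(-1, 1) * s$buffer))
  c(min(xs), max(xs), min(ys), max(ys))
}

#' Sample desert pseudo-absences
#'
#' Draws `n` pixel centres uniformly without replacement from the `TRUE`
#' pixels of a desert mask. Deserts hold no anophelines but are never
#' surveyed, so these points anchor the model as known absences; they carry
#' background class 2 (no survey, so the capable-method upweighting cannot
#' apply).
#'
#' @param desert_mask a logical-valued [vs_raster()] (`TRUE` = desert).
#' @param n number of points (default 210).
#' @param seed integer RNG seed.
#' @return labelled-point data.frame (`label = 0`, `background_class = 2`).
#' @export
sample_pseudo_absences <- function(desert_mask, n = 210, seed = 1) {
  cells <- which(desert_mask$values == 1 | desert_mask$values == TRUE)
  if (n == 0)
    return(labelled_points(numeric(0), numeric(0), integer(0)))
  if (length(cells) < n)
    stop(sprintf("desert mask too small: %d pixels available, %d required",
                 length(cells), n))
  g <- desert_mask$grid
  set.seed(seed)
  pick <- cells[sample.int(length(cells), n, replace = FALSE)]
  rows <- ((pick - 1L) %% g$ny) + 1L
  cols <- ((pick - 1L) %/% g$ny) + 1L
  cc <- cell_centers(g, rows, cols)
  labelled_points(cc$x, cc$y, label = 0L, background_class = 2L,
                  source = "pseudo_absence")
}

#' Mask a raster to a (buffered) range
#'
#' Pixels whose centre lies outside the range become nodata; pixels inside
#' keep their value bit-exactly.
#'
#' @param prediction a [vs_raster()].
#' @param buffered_range a [species_range()] on the same CRS.
#' @return the masked [vs_raster()].
#' @export
mask_to_range <- function(prediction, buffered_range) {
  g <- prediction$grid
  if (!identical(g$crs, buffered_range$crs))
    stop("CRS mismatch between raster (", g$crs, ") and range (",
         buffered_range$crs, ")")
  cc <- cell_centers(g, rep(seq_len(g$ny), g$nx),
                     rep(seq_len(g$nx), each = g$ny))
  keep <- range_contains(buffered_range, cc$x, cc$y)
  v <- prediction$values
  v[!matrix(keep, g$ny, g$nx)] <- NA_real_
  vs_raster(g, v)
}

#' Range GeoJSON I/O
#'
#' Writes the range's shape rings as a GeoJSON `GeometryCollection` of
#' polygons/points with per-shape buffer distances and the CRS tag in
#' `properties`, inside a `Feature`.
#'
#' @param range a [species_range()].
#' @param path output `.geojson` path.
#' @export
write_range_geojson <- function(range, path) {
  geoms <- lapply(range$shapes, function(s) {
    if (nrow(s$ring) >= 3) {
      closed <- rbind(s$ring, s$ring[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(closed)),
                                     function(i) closed[i, ])))
    } else if (nrow(s$ring) == 2) {
      list(type = "LineString",
           coordinates = lapply(1:2, function(i) s$ring[i, ]))
    } else {
      list(type = "Point", coordinates = s$ring[1, ])
    }
  })
  obj <- list(type = "Feature",
              properties = list(species = range$species, crs = range$crs,
                                buffers = vapply(range$shapes, `[[`, 0,
                                                 "buffer")),
              geometry = list(type = "GeometryCollection",
                              geometries = geoms))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_range_geojson
#' @export
read_range_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  buffers <- unlist(obj$properties$buffers)
  rings <- lapply(obj$geometry$geometries, function(gm) {
    if (gm$type == "Polygon") {
      ring <- do.call(rbind, lapply(gm$coordinates[[1]], unlist))
      ring[-nrow(ring), , drop = FALSE]
    } else if (gm$type == "LineString") {
      do.call(rbind, lapply(gm$coordinates, unlist))
    } else {
      matrix(unlist(gm$coordinates), 1, 2)
    }
  })
  species_range(obj$properties$species, rings, buffers,
                crs = obj$properties$crs)
}
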