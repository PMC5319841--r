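# Minimal planar geometry engine: ray-casting point-in-polygon, point-to-
# boundary distance, ring validity. Rings are open N x 2 matrices (the
# closing edge last->first is implied). All distances in the same planar
# units as the coordinates (km for synthetic worlds).

#' Test points against a single polygon ring
#'
#' Even-odd ray casting; points exactly on the boundary are treated as
#' inside (distance to boundary is zero, so buffered membership is
#' unaffected by the convention).
#'
#' @param x,y point coordinate vectors.
#' @param ring open `N x 2` matrix of ring vertices, `N >= 3`.
#' @return logical vector.
#' @export
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Distance from points to a ring boundary
#'
#' Minimum Euclidean distance from each point to the closed boundary of the
#' ring. Degenerate "rings" with one vertex (a point) or two vertices (a
#' segment) are supported; they arise as disc/segment centres of buffered
#' shapes.
#'
#' @inheritParams point_in_ring
#' @return numeric vector of distances (>= 0).
#' @export
point_ring_distance <- function(x, y, ring) {
  n <- nrow(ring)
  if (n == 1L) return(sqrt((x - ring[1, 1])^2 + (y - ring[1, 2])^2))
  d2 <- rep(Inf, length(x))
  idx <- if (n == 2L) list(c(1L, 2L)) else
    lapply(seq_len(n), function(i) c(i, if (i == n) 1L else i + 1L))
  for (e in idx) {
    ax <- ring[e[1], 1]; ay <- ring[e[1], 2]
    bx <- ring[e[2], 1]; by <- ring[e[2], 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
    d2 <- pmin(d2, (x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
  }
  sqrt(d2)
}

# segment proper/improper intersection test used by ring validity check
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Validate and repair a polygon ring
#'
#' Drops repeated consecutive vertices, requires at least three distinct
#' vertices and nonzero area, and rejects self-intersecting rings.
#'
#' @param ring open `N x 2` matrix.
#' @return the repaired ring.
#' @export
validate_ring <- function(ring) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2)
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(ring) < 3) stop("ring has fewer than 3 distinct vertices")
  if (abs(ring_area(ring)) < .Machine$double.eps)
    stop("ring has zero area")
  n <- nrow(ring)
  edges <- lapply(seq_len(n), function(i) rbind(ring[i, ],
                                                ring[if (i == n) 1 else i + 1, ]))
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (segments_cross(edges[[i]][1, ], edges[[i]][2, ],
                         edges[[j]][1, ], edges[[j]][2, ]))
        stop("self-intersecting ring (edges ", i, " and ", j, ")")
    }
  }
  ring
}

#' Shoelace area of a ring
#'
#' @param ring open `N x 2` matrix.
#' @return unsigned area.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
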