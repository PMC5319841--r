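test_that("zero-distance buffering is the identity for membership and area", {
  r <- species_range("sp", unit_square())
  b0 <- buffer_range(r, 0)
  pts <- expand.grid(x = seq(-0.5, 1.5, by = 0.1),
                     y = seq(-0.5, 1.5, by = 0.1))
  expect_identical(range_contains(r, pts$x, pts$y),
                   range_contains(b0, pts$x, pts$y))
})

test_that("buffered unit square area matches the closed form within 1%", {
  r <- species_range("sp", unit_square())
  b <- buffer_range(r, 1)
  a <- range_area(b, n = 1000)
  expect_lt(abs(a - (1 + 4 + pi)) / (1 + 4 + pi), 0.01)
})

test_that("buffers nest: original inside 100 km inside 300 km", {
  r <- species_range("sp", unit_square(0, 0, 50))
  b100 <- buffer_range(r, 100)
  b300 <- buffer_range(r, 300)
  set.seed(4)
  x <- runif(500, -400, 450); y <- runif(500, -400, 450)
  in0 <- range_contains(r, x, y)
  in1 <- range_contains(b100, x, y)
  in3 <- range_contains(b300, x, y)
  expect_true(all(in1[in0]))
  expect_true(all(in3[in1]))
})

test_that("range extension encompasses outside presences and only those", {
  r <- species_range("sp", unit_square(0, 0, 100))
  inside <- data.frame(x = c(10, 90), y = c(10, 50))
  same <- extend_range(r, inside)
  expect_equal(attr(same, "n_extended"), 0L)
  expect_equal(length(same$shapes), length(r$shapes))

  pres <- data.frame(x = c(10, 150), y = c(10, 50))  # one 50 km outside
  ext <- extend_range(r, pres, disc_km = 25)
  expect_equal(attr(ext, "n_extended"), 1L)
  expect_true(all(range_contains(ext, pres$x, pres$y)))
  # containment chain original - extended - buffered
  set.seed(9)
  x <- runif(400, -50, 250); y <- runif(400, -50, 250)
  expect_true(all(range_contains(ext, x, y)[range_contains(r, x, y)]))
  bext <- buffer_range(ext, 30)
  expect_true(all(range_contains(bext, x, y)[range_contains(ext, x, y)]))
})

test_that("extension area equals input area plus the disc overhangs", {
  r <- species_range("sp", unit_square(0, 0, 100))
  out_pts <- data.frame(x = c(150, 200, 150, -40, 50),
                        y = c(50, 120, -60, -40, 190))
  ext <- extend_range(r, out_pts, disc_km = 25)
  # rasterised area oracle: count cells inside square or in any disc
  step <- 0.5
  xs <- seq(-80 + step / 2, 240, by = step)
  ys <- seq(-100 + step / 2, 230, by = step)
  g <- expand.grid(x = xs, y = ys)
  in_sq <- g$x >= 0 & g$x <= 100 & g$y >= 0 & g$y <= 100
  in_disc <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(out_pts)))
    in_disc <- in_disc |
      ((g$x - out_pts$x[i])^2 + (g$y - out_pts$y[i])^2 <= 25^2)
  oracle <- sum(in_sq | in_disc) * step^2
  expect_lt(abs(range_area(ext, n = 800) - oracle) / oracle, 0.01)
})

test_that("composite ranges union members and honour inclusion-exclusion", {
  a <- species_range("a", unit_square(0, 0, 10))
  single <- composite_range(list(a))
  expect_equal(range_area(single, 400), range_area(a, 400))

  b <- species_range("b", unit_square(20, 20, 10))
  disjoint <- composite_range(list(a, b))
  expect_lt(abs(range_area(disjoint, 600) - 200) / 200, 0.02)

  # three overlapping 10x10 squares along a diagonal: by
  # inclusion-exclusion 3*100 - 2*25 + 0 = 250
  c1 <- species_range("c", unit_square(5, 5, 10))
  c2 <- species_range("d", unit_square(10, 10, 10))
  over <- composite_range(list(a, c1, c2))
  expect_lt(abs(range_area(over, 800) - 250) / 250, 0.02)
  expect_error(composite_range(list()), "at least one")
})

test_that("desert pseudo-absences sample the mask uniformly and reproducibly", {
  g <- vs_grid(20, 20, pixel = 5)
  mask <- vs_raster(g, matrix(1, 20, 20))
  ps <- sample_pseudo_absences(mask, 210, seed = 5)
  expect_equal(nrow(ps), 210)
  expect_true(all(raster_extract(mask, ps$x, ps$y) == 1))
  expect_true(all(ps$label == 0L))
  expect_true(all(ps$background_class == 2L))
  expect_identical(ps, sample_pseudo_absences(mask, 210, seed = 5))

  expect_equal(nrow(sample_pseudo_absences(mask, 0)), 0)
  small <- vs_raster(g, matrix(c(rep(1, 50), rep(0, 350)), 20, 20))
  expect_error(sample_pseudo_absences(small, 210), "50")

  # chi-squared uniformity over the four quadrants, 20 seeds
  big <- vs_raster(vs_grid(100, 100, pixel = 5), matrix(1, 100, 100))
  reject <- 0
  for (s in 1:20) {
    p <- sample_pseudo_absences(big, 2000, seed = s)
    quad <- 2 * (p$x > 250) + (p$y > 250)
    pval <- suppressWarnings(
      chisq.test(table(factor(quad, levels = 0:3)))$p.value)
    if (pval < 0.01) reject <- reject + 1
  }
  expect_lte(reject, 1)
})

test_that("pseudo-absences avoid the species range in synthetic worlds", {
  w <- small_world(17)
  ps <- sample_pseudo_absences(w$desert_mask, 50, seed = 1)
  d <- raster_extract(w$desert_mask, ps$x, ps$y)
  expect_true(all(d == 1))
})

test_that("masking to a range keeps inside pixels bit-exact", {
  g <- vs_grid(10, 10, pixel = 1)
  set.seed(2)
  r <- vs_raster(g, matrix(runif(100), 10, 10))
  whole <- species_range("sp", unit_square(-1, -1, 12))
  expect_identical(mask_to_range(r, whole)$values, r$values)

  nowhere <- species_range("sp", unit_square(100, 100, 1))
  expect_true(all(is.na(mask_to_range(r, nowhere)$values)))

  # half-plane: left 5 columns inside
  half <- species_range("sp", matrix(c(-1, -1, 5, -1, 5, 12, -1, 12),
                                     4, 2, byrow = TRUE))
  m <- mask_to_range(r, half)
  expect_equal(sum(!is.na(m$values)), 50)
  expect_identical(m$values[, 1:5], r$values[, 1:5])
  expect_true(all(is.na(m$values[, 6:10])))
  expect_error(mask_to_range(r, species_range("sp", unit_square(),
                                              crs = "geographic")),
               "CRS mismatch")
})

test_that("ring validation repairs duplicates and rejects bow-ties", {
  sq <- rbind(unit_square(), unit_square()[1, , drop = FALSE])
  expect_equal(nrow(validate_ring(sq)), 4)
  bowtie <- matrix(c(0, 0, 2, 2, 2, 0, 0, 1), 4, 2, byrow = TRUE)
  expect_error(validate_ring(bowtie), "self-intersecting")
  # degenerate symmetric bow-tie collapses to zero area, also rejected
  flat <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  expect_error(validate_ring(flat), "zero area")
  expect_error(validate_ring(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)),
               "fewer than 3")
})

test_that("range GeoJSON round-trips shapes, buffers and discs", {
  r <- species_range("sp", list(unit_square(0, 0, 10)), buffers = 3)
  r <- extend_range(r, data.frame(x = 50, y = 50), disc_km = 7)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_range_geojson(r, path)
  r2 <- read_range_geojson(path)
  expect_equal(r2$species, r$species)
  set.seed(3)
  x <- runif(300, -10, 70); y <- runif(300, -10, 70)
  expect_identical(range_contains(r, x, y), range_contains(r2, x, y))
})
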