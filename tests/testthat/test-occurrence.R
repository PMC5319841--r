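grid20 <- vs_grid(20, 20, xmin = 0, ymin = 0, pixel = 5)  # 100 x 100 km

rec <- function(id, x, y, ys = 2005L, ye = 2005L, pub = 2007L,
                sp = "focal", methods = "PCR", mol = TRUE) {
  data.frame(record_id = id, species_label = sp, x = x, y = y,
             year_start = ys, year_end = ye, publication_year = pub,
             id_methods = methods, is_molecular = mol,
             source_id = "s1", stringsAsFactors = FALSE)
}

test_that("record validation accepts complete in-extent records and rejects with reasons", {
  good <- rec("a", 50, 50)
  out <- validate_records(good, grid20)
  expect_equal(nrow(out$valid), 1)
  expect_equal(nrow(out$rejected), 0)

  bad <- rec("b", 50, 9500)  # far outside the declared extent
  out <- validate_records(bad, grid20)
  expect_equal(out$rejected$reason, "coordinate_out_of_range")

  swapped <- rec("c", 50, 50, ys = 2008L, ye = 2005L)
  expect_equal(validate_records(swapped, grid20)$rejected$reason,
               "year_order")

  undated <- rec("d", 50, 50, ys = NA, ye = NA, pub = NA)
  expect_equal(validate_records(undated, grid20)$rejected$reason,
               "missing_year")
})

test_that("validation flags exactly the deliberately corrupted records", {
  set.seed(42)
  n <- 100
  recs <- rec(sprintf("r%03d", 1:n), runif(n, 1, 99), runif(n, 1, 99))
  bad_idx <- sort(sample(n, 7))
  kinds <- rep_len(c("coord", "order", "nodate"), 7)
  for (k in seq_along(bad_idx)) {
    i <- bad_idx[k]
    if (kinds[k] == "coord") recs$x[i] <- 500
    if (kinds[k] == "order") { recs$year_start[i] <- 2010L }
    if (kinds[k] == "nodate") {
      recs$year_start[i] <- NA; recs$year_end[i] <- NA
      recs$publication_year[i] <- NA
    }
  }
  out <- validate_records(recs, grid20)
  expect_setequal(out$rejected$record_id, recs$record_id[bad_idx])
  # independent re-application of each rule
  redo <- (recs$x < 0 | recs$x >= 100 | recs$y <= 0 | recs$y > 100) |
    (!is.na(recs$year_start) & !is.na(recs$year_end) &
       recs$year_start > recs$year_end) |
    (is.na(recs$year_start) & is.na(recs$publication_year))
  expect_equal(sort(out$rejected$record_id), sort(recs$record_id[redo]))
})

test_that("collection year uses recorded years, midpoints, or publication - 2", {
  r <- rbind(rec("a", 1, 1, ys = NA, ye = NA, pub = 2010L),
             rec("b", 1, 1, ys = 2005L, ye = 2005L, pub = 2010L),
             rec("c", 1, 1, ys = 2003L, ye = 2005L, pub = 2010L),
             rec("d", 1, 1, ys = 2003L, ye = 2006L, pub = 2010L))
  expect_equal(impute_collection_year(r), c(2008L, 2005L, 2004L, 2004L))
  undated <- rec("e", 1, 1, ys = NA, ye = NA, pub = NA)
  expect_error(impute_collection_year(undated), "without collection")
})

test_that("background classing follows detection capability with 2:1 weights", {
  cap <- detection_capability(list(PCR = c("focal", "other"),
                                   ELISA = "other",
                                   MORPH = character(0)))
  set.seed(7)
  n <- 50
  methods <- sample(c("PCR", "ELISA", "MORPH", "PCR;ELISA", "XX"),
                    n, replace = TRUE)
  recs <- rec(sprintf("b%02d", 1:n), runif(n, 1, 99), runif(n, 1, 99),
              sp = "other", methods = methods, mol = methods != "MORPH")
  pts <- classify_background(recs, "focal", cap, weighting = "plain")
  # brute-force membership re-check
  expected1 <- vapply(strsplit(methods, ";"), function(m)
    any(vapply(m, function(x)
      "focal" %in% switch(x, PCR = c("focal", "other"), ELISA = "other",
                          character(0)), logical(1))), logical(1))
  expect_equal(pts$background_class == 1L, expected1)
  expect_equal(unique(pts$weight[pts$background_class == 1L] /
                        unique(pts$weight[pts$background_class == 2L])),
               2)
  expect_true(all(pts$label == 0L))
  # unknown method codes land in class 2
  expect_true(all(pts$background_class[methods == "XX"] == 2L))
  expect_error(classify_background(recs, "unheard_of", cap),
               "unknown focal species")
})

test_that("balanced weighting equates total presence and background weight", {
  cap <- detection_capability(list(PCR = "focal", MORPH = character(0)))
  pres <- labelled_points(runif(30), runif(30), 1, year_used = 2005)
  recs <- rec(sprintf("b%02d", 1:40), runif(40, 1, 99), runif(40, 1, 99),
              sp = "other",
              methods = rep(c("PCR", "MORPH"), c(15, 25)),
              mol = rep(c(TRUE, FALSE), c(15, 25)))
  bg <- classify_background(recs, "focal", cap, presences = pres)
  expect_equal(sum(bg$weight), sum(pres$weight), tolerance = 1e-12)
  w1 <- unique(bg$weight[bg$background_class == 1])
  w2 <- unique(bg$weight[bg$background_class == 2])
  expect_equal(w1 / w2, 2)
  # classification partitions the table whatever the composition
  expect_equal(sum(bg$background_class == 1) +
                 sum(bg$background_class == 2), nrow(recs))
})

test_that("historical composite-taxon records resolve on toy square ranges", {
  coluzzii <- buffer_range(species_range("coluzzii", unit_square(0, 0, 10)), 1)
  gambiae <- buffer_range(species_range("gambiae", unit_square(5, 5, 10)), 1)
  recs <- rec(c("g1", "g2", "g3"), c(20, 7, 2), c(20, 7, 2),
              sp = "gambiae_old")
  out <- resolve_gambiae_old(recs, coluzzii, gambiae)
  expect_equal(out$assigned$record_id, "g1")
  expect_equal(out$assigned$species_label, "gambiae")
  expect_equal(out$discarded$record_id, c("g2", "g3"))
  expect_equal(out$discarded$reason,
               c("in_range_overlap", "in_coluzzii_range_only"))
  # partition: every record ends in exactly one bucket
  expect_setequal(c(out$assigned$record_id, out$discarded$record_id),
                  recs$record_id)
  expect_error(resolve_gambiae_old(recs, NULL, gambiae), "required")
})

test_that("presence extraction keeps only molecular records of the focal species", {
  recs <- rbind(rec("p1", 10, 10, sp = "focal", mol = TRUE),
                rec("p2", 20, 20, sp = "focal", mol = FALSE,
                    methods = "MORPH"),
                rec("p3", 30, 30, sp = "other", mol = TRUE))
  pres <- extract_presence(recs, "focal")
  expect_equal(nrow(pres), 1)
  expect_equal(pres$label, 1L)
  expect_equal(pres$weight, 1)
  expect_true(is.na(pres$background_class))
})

test_that("presence count matches generator ground truth", {
  w <- small_world(13)
  pres <- extract_presence(w$occurrence, w$config$species)
  truth_n <- sum(w$truth$capable &
                   w$truth$u < w$truth$suitability_at_survey)
  expect_equal(nrow(pres), truth_n)
})

test_that("co-located records share a location id", {
  pts <- labelled_points(c(1.2345678, 1.2345678, 2), c(3, 3, 3), 0,
                         background_class = 2)
  expect_equal(pts$location_id[1], pts$location_id[2])
  expect_false(pts$location_id[1] == pts$location_id[3])
})
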