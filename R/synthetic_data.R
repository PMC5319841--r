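#' Configuration of a synthetic world
#'
#' Parameters of the seeded generator that emulates the inputs of the
#' vector mapping workflow: smooth annual covariate fields on a 5 km grid,
#' a desert region with no surveys, a clustered (spatially biased) survey
#' process, presence labels driven by a known inverse-logit suitability
#' over a subset of bands, two background classes defined by
#' identification-method capability, and a species range.
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 64 x 64 pixel (320 x 320 km) world, 8 covariate bands of which
#' 2 drive suitability (effect 3 on the logit, intercept -1, so the focal
#' species is locally prevalent but globally rare, as mapped vector
#' species are), 12 annual layers (2001-2012), 900 clustered surveys of
#' which 70% use a molecular method capable of detecting the focal
#' species, and a desert covering ~15% of the grid in the most arid
#' (lowest linear predictor) corner of the world. Under these defaults a
#' world yields about 300 presence records and 600 survey background
#' records, and the true suitability surface separates withheld presences
#' from background at AUC around 0.88.
#'
#' @param grid_width,grid_height grid size in pixels (>= 8).
#' @param n_bands number of covariate bands.
#' @param years inclusive covariate year range.
#' @param n_survey_locations number of survey points.
#' @param cluster_count,cluster_spread number of survey clusters and the
#'   s.d. (km) of point scatter around cluster centres (sampling bias).
#' @param active_bands indices of bands with nonzero effect on suitability.
#' @param true_coefficients per-band effects on the logit of suitability;
#'   default 1.5 on `active_bands`, 0 elsewhere.
#' @param intercept logit-scale intercept of the suitability surface.
#' @param desert_fraction fraction of pixels designated desert (0, 0.5).
#' @param detection_capability_fraction fraction of surveys using a
#'   molecular method able to detect the focal species.
#' @param band_correlation optional correlation between successive bands
#'   (0 = independent fields, the default).
#' @param missing_year_fraction fraction of records with the collection
#'   year blanked (publication year kept) to exercise imputation.
#' @param drift_amplitude s.d. of the additive smooth year-to-year
#'   perturbation of each band, in band-s.d. units.
#' @param species focal species label used for presence records.
#' @param pixel_km pixel edge, km.
#' @param seed integer seed; fixed seed gives bit-identical worlds.
#' @return object of class `world_config`.
#' @export
world_config <- function(grid_width = 64, grid_height = 64, n_bands = 8,
                         years = 2001:2012, n_survey_locations = 900,
                         cluster_count = 15, cluster_spread = 20,
                         active_bands = c(1L, 3L),
                         true_coefficients = NULL, intercept = -1,
                         desert_fraction = 0.15,
                         detection_capability_fraction = 0.7,
                         band_correlation = 0,
                         missing_year_fraction = 0.1,
                         drift_amplitude = 0.1,
                         species = "sim_species", pixel_km = 5, seed = 1) {
  stopifnot(grid_width >= 8, grid_height >= 8, n_bands >= 1,
            desert_fraction > 0, desert_fraction < 0.5,
            all(active_bands %in% seq_len(n_bands)),
            detection_capability_fraction >= 0,
            detection_capability_fraction <= 1,
            band_correlation >= 0, band_correlation < 1)
  if (is.null(true_coefficients)) {
    true_coefficients <- numeric(n_bands)
    true_coefficients[active_bands] <- 3
  }
  stopifnot(length(true_coefficients) == n_bands)
  if (any(true_coefficients[setdiff(seq_len(n_bands), active_bands)] != 0))
    stop("non-active bands must have zero coefficients")
  structure(as.list(environment()), class = "world_config")
}

# smooth standardized Gaussian random field via FFT circular convolution;
# sigma is the Gaussian s.d. in pixels
gaussian_field <- function(ny, nx, sigma) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  dy <- pmin(0:(ny - 1), ny - (0:(ny - 1)))
  dx <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  k <- outer(dnorm(dy, sd = sigma), dnorm(dx, sd = sigma))
  k <- k / sum(k)
  s <- Re(fft(fft(z) * fft(k), inverse = TRUE)) / (ny * nx)
  (s - mean(s)) / sd(s)
}

#' Generate a synthetic world
#'
#' Builds covariate rasters (Gaussian-filtered white noise with filter
#' width `grid_width / 8` pixels, drifting slightly across years), a desert
#' mask (top `desert_fraction` quantile of its own smooth field), the true
#' suitability surface (inverse-logit of the linear predictor over the
#' active bands, evaluated on the most recent year's layers), a species
#' range (bounding box of the high-suitability quartile of non-desert
#' pixels), a clustered survey process excluded from desert, the resulting
#' occurrence table, and a bioassay table. All random draws used for
#' labelling are stored in `$truth` so labels can be reproduced exactly
#' from the stored suitability.
#'
#' @param config a [world_config()].
#' @return object of class `synthetic_world`: list with `config`, `stack`
#'   ([covariate_stack()]), `desert_mask`, `suitability` ([vs_raster()]s),
#'   `range` ([species_range()]), `occurrence` (data.frame), `bioassay`
#'   (data.frame), `truth` (coefficients, active bands, uniform draws,
#'   capability flags).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nx <- config$grid_width; ny <- config$grid_height
  grid <- vs_grid(nx, ny, pixel = config$pixel_km)
  # Gaussian filter of width (FWHM) grid_width / 8 pixels
  sigma <- (nx / 8) / (2 * sqrt(2 * log(2)))
  nb <- config$n_bands
  years <- config$years

  base <- lapply(seq_len(nb), function(b) gaussian_field(ny, nx, sigma))
  if (config$band_correlation > 0 && nb > 1) {
    rho <- config$band_correlation
    for (b in 2:nb)
      base[[b]] <- rho * base[[b - 1]] + sqrt(1 - rho^2) * base[[b]]
  }
  data <- lapply(years, function(y) {
    arr <- array(NA_real_, c(ny, nx, nb))
    for (b in seq_len(nb))
      arr[, , b] <- base[[b]] +
        config$drift_amplitude * gaussian_field(ny, nx, sigma)
    arr
  })
  band_names <- sprintf("band_%02d", seq_len(nb))
  stack <- covariate_stack(grid, band_names, years, data)

  # desert = the most environmentally hostile corner of the world: low
  # linear predictor (aridity tracks the suitability-driving covariates)
  # plus an independent smooth perturbation for irregular borders
  desert_noise <- gaussian_field(ny, nx, sigma)
  lp_base <- matrix(0, ny, nx)
  for (b in config$active_bands)
    lp_base <- lp_base + config$true_coefficients[b] * base[[b]]
  aridity <- if (sd(lp_base) > 0)
    -(lp_base - mean(lp_base)) / sd(lp_base) + 0.5 * desert_noise
  else desert_noise
  thr <- quantile(aridity, 1 - config$desert_fraction, type = 7)
  desert <- aridity > thr
  desert_mask <- vs_raster(grid, desert * 1)

  ref <- stack$data[[as.character(max(years))]]
  lp <- matrix(config$intercept, ny, nx)
  for (b in config$active_bands)
    lp <- lp + config$true_coefficients[b] * ref[, , b]
  suit <- vs_raster(grid, plogis(lp))

  # species range: bounding box of the top-quartile suitability pixels
  # outside the desert, padded by one pixel
  good <- suit$values >= quantile(suit$values[!desert], 0.75) & !desert
  rows <- range(which(rowSums(good) > 0)); cols <- range(which(colSums(good) > 0))
  pad <- grid$pixel
  x0 <- grid$xmin + (cols[1] - 1) * grid$pixel - pad
  x1 <- grid$xmin + cols[2] * grid$pixel + pad
  y1 <- grid$ymax - (rows[1] - 1) * grid$pixel + pad
  y0 <- grid$ymax - rows[2] * grid$pixel - pad
  rng <- species_range(config$species,
                       matrix(c(x0, y0, x1, y0, x1, y1, x0, y1),
                              4, 2, byrow = TRUE))

  # clustered, spatially biased survey process, rejected from desert
  n <- config$n_survey_locations
  nondesert <- which(!desert)
  centers_idx <- sample(nondesert, config$cluster_count)
  ccent <- cell_centers(grid, ((centers_idx - 1L) %% ny) + 1L,
                        ((centers_idx - 1L) %/% ny) + 1L)
  cl <- sample(config$cluster_count, n, replace = TRUE)
  px <- py <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- ccent$x[cl[i]] + rnorm(1, sd = config$cluster_spread)
      y <- ccent$y[cl[i]] + rnorm(1, sd = config$cluster_spread)
      cc <- cell_at(grid, x, y)
      if (cc$inside && !desert[cc$row, cc$col]) break
    }
    px[i] <- x; py[i] <- y
  }

  capable <- runif(n) < config$detection_capability_fraction
  u <- runif(n)
  suit_at <- raster_extract(suit, px, py)
  presence <- capable & (u < suit_at)

  yr <- sample(seq(min(years) - 3L, max(years) + 2L), n, replace = TRUE)
  pub <- yr + 2L
  blank <- runif(n) < config$missing_year_fraction
  occurrence <- data.frame(
    record_id = sprintf("occ%04d", seq_len(n)),
    species_label = ifelse(presence, config$species, "other_anopheline"),
    x = px, y = py,
    year_start = ifelse(blank, NA_integer_, yr),
    year_end = ifelse(blank, NA_integer_, yr),
    publication_year = pub,
    id_methods = ifelse(capable, "PCR", "MORPH"),
    is_molecular = capable,
    source_id = sprintf("src%02d", cl),
    stringsAsFactors = FALSE)

  bioassay <- generate_bioassay_table(
    n_records = 200,
    species_pool = c(config$species, "sibling_A", "sibling_B"),
    seed = config$seed + 1L)

  structure(list(config = config, stack = stack, desert_mask = desert_mask,
                 suitability = suit, range = rng, occurrence = occurrence,
                 bioassay = bioassay,
                 truth = list(coefficients = config$true_coefficients,
                              active_bands = config$active_bands,
                              intercept = config$intercept,
                              u = u, capable = capable,
                              suitability_at_survey = suit_at)),
            class = "synthetic_world")
}

#' Generate a synthetic bioassay table
#'
#' Emulates the structure of an insecticide-resistance susceptibility
#' bioassay compilation: per record a species-composition vector summing to
#' 1, an insecticide and its class (carbamate, organochlorine,
#' organophosphate or pyrethroid), a collection year in 1995-2015, a
#' country label, and a percent mortality. A configurable fraction of
#' records are mixed-species samples (majority proportion <= 0.95) to
#' exercise the purity filter, and a fraction lack molecular
#' identification.
#'
#' @param n_records number of records (>= 1).
#' @param species_pool character vector of species labels (non-empty).
#' @param seed integer seed.
#' @param mixed_fraction fraction of mixed-species records.
#' @param nonmolecular_fraction fraction of records without molecular
#'   identification.
#' @return data.frame with one row per record; composition is stored in
#'   columns `prop_<species>`.
#' @export
generate_bioassay_table <- function(n_records, species_pool, seed = 1,
                                    mixed_fraction = 0.3,
                                    nonmolecular_fraction = 0) {
  stopifnot(n_records >= 1)
  if (length(species_pool) == 0) stop("species pool must be non-empty")
  set.seed(seed)
  classes <- c(carbamate = "bendiocarb", organochlorine = "DDT",
               organophosphate = "malathion", pyrethroid = "deltamethrin")
  countries <- sprintf("Country_%02d", 1:12)
  ins_class <- sample(names(classes), n_records, replace = TRUE)
  mixed <- runif(n_records) < mixed_fraction
  if (length(species_pool) == 1) mixed[] <- FALSE
  major <- sample(species_pool, n_records, replace = TRUE)
  p_major <- ifelse(mixed, runif(n_records, 0.5, 0.95),
                    runif(n_records, 0.96, 1.0))
  comp <- matrix(0, n_records, length(species_pool),
                 dimnames = list(NULL, species_pool))
  for (i in seq_len(n_records)) {
    comp[i, major[i]] <- p_major[i]
    rest <- setdiff(species_pool, major[i])
    if (length(rest) && p_major[i] < 1) {
      shares <- runif(length(rest))
      comp[i, rest] <- (1 - p_major[i]) * shares / sum(shares)
    } else comp[i, major[i]] <- 1
  }
  out <- data.frame(
    record_id = sprintf("bio%04d", seq_len(n_records)),
    insecticide = unname(classes[ins_class]),
    insecticide_class = ins_class,
    year = sample(1995:2015, n_records, replace = TRUE),
    country = sample(countries, n_records, replace = TRUE),
    mortality_pct = round(runif(n_records, 0, 100), 1),
    molecular_id = runif(n_records) >= nonmolecular_fraction,
    generation_ok = TRUE,
    protocol = "WHO tube",
    deviations = "",
    stringsAsFactors = FALSE)
  colnames(comp) <- paste0("prop_", species_pool)
  cbind(out, as.data.frame(comp))
}

#' Write a synthetic world to disk
#'
#' Covariates as per-band ASCII grids, desert mask and true suitability as
#' ASCII grids, the range as GeoJSON, occurrence and bioassay tables as
#' CSV, and the ground truth (coefficients, active bands, label draws) as
#' JSON.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_covariates(world$stack, file.path(dir, "covariates"))
  write_raster_asc(world$desert_mask, file.path(dir, "desert_mask.asc"))
  write_raster_asc(world$suitability, file.path(dir, "true_suitability.asc"))
  write_range_geojson(world$range, file.path(dir, "range.geojson"))
  write.csv(world$occurrence, file.path(dir, "occurrence.csv"),
            row.names = FALSE)
  write.csv(world$bioassay, file.path(dir, "bioassay.csv"),
            row.names = FALSE)
  jsonlite::write_json(world$truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  jsonlite::write_json(unclass(world$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_world
#' @param dir directory previously written by [write_world()].
#' @export
read_world <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  structure(list(
    config = structure(cfg, class = "world_config"),
    stack = read_covariates(file.path(dir, "covariates")),
    desert_mask = read_raster_asc(file.path(dir, "desert_mask.asc")),
    suitability = read_raster_asc(file.path(dir, "true_suitability.asc")),
    range = read_range_geojson(file.path(dir, "range.geojson")),
    occurrence = read.csv(file.path(dir, "occurrence.csv"),
                          stringsAsFactors = FALSE),
    bioassay = read.csv(file.path(dir, "bioassay.csv"),
                        stringsAsFactors = FALSE),
    truth = truth), class = "synthetic_world")
}
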