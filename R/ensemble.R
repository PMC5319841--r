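#' Ensemble configuration
#'
#' @param n_submodels number of bootstrap submodels (default 200; >= 2 for
#'   quantile summaries).
#' @param quantiles lower and upper summary quantiles, strictly inside
#'   (0, 1) (default 0.025 and 0.975).
#' @param brt a [brt_config()] shared by all submodels.
#' @param master_seed integer; per-submodel seeds are derived from it, so
#'   results do not depend on fitting order.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_submodels = 200, quantiles = c(0.025, 0.975),
                            brt = brt_config(), master_seed = 1) {
  stopifnot(n_submodels >= 1, length(quantiles) == 2,
            all(quantiles > 0), all(quantiles < 1),
            quantiles[1] < quantiles[2])
  structure(list(n_submodels = as.integer(n_submodels),
                 quantiles = quantiles, brt = brt,
                 master_seed = as.integer(master_seed)),
            class = "ensemble_config")
}

# deterministic submodel seed from (master seed, index); a small LCG-style
# integer hash keeping values in [1, 2^31 - 2]
submodel_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index) * 1299721) %% m
  as.integer(s + 1)
}

#' Bootstrap resample of a labelled-point table
#'
#' Samples records with replacement. The default stratified mode resamples
#' presences among presences and background among background, preserving
#' the original class sizes, so every resample remains fittable; pooled
#' mode resamples all records together.
#'
#' @param points [labelled_points()] (optionally with covariate columns);
#'   both labels must be present.
#' @param seed integer seed.
#' @param stratified logical; stratify by label (default `TRUE`).
#' @return resampled points (weights and covariates carried along).
#' @export
bootstrap_dataset <- function(points, seed = 1, stratified = TRUE) {
  if (length(unique(points$label)) < 2)
    stop("bootstrap needs both presence and background records")
  set.seed(seed)
  if (stratified) {
    idx <- unlist(lapply(split(seq_len(nrow(points)), points$label),
                         function(i)
                           i[sample.int(length(i), length(i),
                                        replace = TRUE)]),
                  use.names = FALSE)
  } else {
    idx <- sample.int(nrow(points), nrow(points), replace = TRUE)
  }
  out <- points[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a bootstrap ensemble of BRT submodels
#'
#' Fits `n_submodels` models, each to an independent seeded bootstrap of
#' the training points (the original workflow uses 200). Submodel seeds
#' are derived deterministically from the master seed.
#'
#' @param points [labelled_points()] with covariate columns named as in
#'   `band_names`.
#' @param band_names covariate column names used as model input.
#' @param econfig an [ensemble_config()].
#' @param stratified passed to [bootstrap_dataset()].
#' @return list of `brt_model` objects with attribute `"seeds"`.
#' @export
fit_ensemble <- function(points, band_names, econfig = ensemble_config(),
                         stratified = TRUE) {
  stopifnot(all(band_names %in% colnames(points)))
  models <- vector("list", econfig$n_submodels)
  seeds <- integer(econfig$n_submodels)
  for (k in seq_len(econfig$n_submodels)) {
    seeds[k] <- submodel_seed(econfig$master_seed, k)
    boot <- bootstrap_dataset(points, seed = seeds[k],
                              stratified = stratified)
    cfg <- econfig$brt
    cfg$seed <- submodel_seed(econfig$master_seed, -k)
    models[[k]] <- tryCatch(
      fit_brt(as.matrix(boot[, band_names, drop = FALSE]), boot$label,
              boot$weight, cfg),
      error = function(e) stop("submodel ", k, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  attr(models, "seeds") <- seeds
  models
}

#' Summarise an ensemble into prediction and uncertainty maps
#'
#' Predicts every submodel at every valid pixel of the chosen year's
#' covariate layers, then summarises the per-pixel distribution of
#' predictions to its mean, median and outer quantiles (type-7 linear
#' interpolation), and masks all four surfaces to the buffered species
#' range.
#'
#' @param models list of `brt_model` objects (>= 2 for quantiles).
#' @param stack a [covariate_stack()].
#' @param year prediction year (default most recent).
#' @param buffered_range a [species_range()]; `NULL` skips masking.
#' @param quantiles summary quantiles.
#' @return object of class `ensemble_summary`: rasters `mean`, `median`,
#'   `q_low`, `q_high`, plus `n_submodels`, `year` and provenance.
#' @export
summarise_ensemble <- function(models, stack, year = max(stack$years),
                               buffered_range = NULL,
                               quantiles = c(0.025, 0.975)) {
  stopifnot(length(models) >= 1)
  pm <- prediction_matrix(stack, year)
  pred <- vapply(models, function(m) predict(m, pm$matrix),
                 numeric(nrow(pm$matrix)))
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  mu <- rowMeans(pred)
  med <- apply(pred, 1, median)
  qs <- t(apply(pred, 1, quantile, probs = quantiles, type = 7,
                names = FALSE))
  to_raster <- function(v) {
    r <- raster_from_vector(v, pm$index, pm$grid)
    if (!is.null(buffered_range)) r <- mask_to_range(r, buffered_range)
    r
  }
  structure(list(mean = to_raster(mu), median = to_raster(med),
                 q_low = to_raster(qs[, 1]), q_high = to_raster(qs[, 2]),
                 n_submodels = length(models), year = pm$year,
                 quantiles = quantiles,
                 provenance = list(seeds = attr(models, "seeds"),
                                   config = models[[1]]$config)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_summary: %d submodels, year %d, ",
                     "quantiles [%g, %g]>\n"),
              x$n_submodels, x$year, x$quantiles[1], x$quantiles[2]))
  invisible(x)
}

#' Write an ensemble summary to disk
#'
#' Mean, median and quantile maps as ESRI ASCII grids plus a provenance
#' JSON (submodel count, seeds, quantiles, BRT configuration).
#'
#' @param summary an `ensemble_summary`.
#' @param dir output directory.
#' @export
write_ensemble_summary <- function(summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_raster_asc(summary$mean, file.path(dir, "mean.asc"))
  write_raster_asc(summary$median, file.path(dir, "median.asc"))
  write_raster_asc(summary$q_low, file.path(dir, "q025.asc"))
  write_raster_asc(summary$q_high, file.path(dir, "q975.asc"))
  jsonlite::write_json(
    list(n_submodels = summary$n_submodels, year = summary$year,
         quantiles = summary$quantiles,
         seeds = summary$provenance$seeds,
         brt_config = unclass(summary$provenance$config)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
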