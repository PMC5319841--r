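#' Rebalance presence/background weights
#'
#' Scales background weights by a common factor so total background weight
#' equals total presence weight, preserving the exact 2:1 class-1:class-2
#' ratio. Presence weights are untouched.
#'
#' @param points [labelled_points()] containing both labels.
#' @return the points with rescaled background weights.
#' @export
rebalance_weights <- function(points) {
  wp <- sum(points$weight[points$label == 1])
  wb <- sum(points$weight[points$label == 0])
  if (wb == 0 || wp == 0) return(points)
  points$weight[points$label == 0] <-
    points$weight[points$label == 0] * wp / wb
  points
}

#' Pipeline run configuration
#'
#' Houses the workflow constants: a 300 km range buffer, 210 desert
#' pseudo-absences, a 200-submodel ensemble summarised at the 0.025/0.975
#' quantiles, and a 10% location-withheld validation split.
#'
#' @param focal_species species label to model.
#' @param buffer_km range buffer distance.
#' @param n_pseudo_absences desert pseudo-absence count.
#' @param disc_km range-extension disc radius.
#' @param split_fraction fraction of locations withheld for validation.
#' @param ensemble an [ensemble_config()].
#' @param weighting background weighting mode (see
#'   [classify_background()]).
#' @param master_seed integer seed driving every random stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(focal_species, buffer_km = 300,
                       n_pseudo_absences = 210, disc_km = 25,
                       split_fraction = 0.10,
                       ensemble = ensemble_config(),
                       weighting = c("balanced", "plain"),
                       master_seed = 1) {
  weighting <- match.arg(weighting)
  stopifnot(buffer_km >= 0, n_pseudo_absences >= 0,
            split_fraction > 0, split_fraction < 1)
  structure(list(focal_species = focal_species, buffer_km = buffer_km,
                 n_pseudo_absences = n_pseudo_absences, disc_km = disc_km,
                 split_fraction = split_fraction, ensemble = ensemble,
                 weighting = weighting,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

# polynomial rolling hash of a string, reported as 8 hex digits; cheap
# provenance tag for frozen configurations
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full mapping pipeline for one species
#'
#' Executes, in order: record validation, collection-year imputation,
#' presence extraction, background classification and weighting, range
#' extension and buffering, desert pseudo-absence sampling, covariate
#' extraction with year clamping, the location-withheld split, the
#' bootstrap BRT ensemble, per-pixel summarisation masked to the buffered
#' range, and AUC validation of the mean map against the withheld points.
#' Every stage logs its record counts; any stage error aborts with the
#' stage name. Rerunning with the same inputs and seed writes
#' byte-identical outputs.
#'
#' @param world a `synthetic_world` (or a list with elements `occurrence`,
#'   `stack`, `desert_mask`, `range`).
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param capability a [detection_capability()]; defaults to the synthetic
#'   convention (method `"PCR"` detects the focal species, `"MORPH"`
#'   detects nothing at species level).
#' @return list of class `species_run`: `points`, `split`, `models`,
#'   `summary`, `report`, `log`, `config`.
#' @export
run_species <- function(world, config, out_dir = NULL,
                        capability = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  focal <- config$focal_species
  if (is.null(capability))
    capability <- detection_capability(list(PCR = focal,
                                            MORPH = character(0)))

  val <- stage("validate_records",
               validate_records(world$occurrence, world$stack$grid))
  note("validate_records: %d valid, %d rejected", nrow(val$valid),
       nrow(val$rejected))

  recs <- val$valid
  old <- recs$species_label == "gambiae_old"
  if (any(old)) {
    res <- stage("resolve_gambiae_old",
                 resolve_gambiae_old(recs[old, , drop = FALSE],
                                     buffer_range(world$coluzzii_range,
                                                  config$buffer_km),
                                     buffer_range(world$range,
                                                  config$buffer_km)))
    recs <- rbind(recs[!old, , drop = FALSE], res$assigned)
    note("resolve_gambiae_old: %d assigned, %d discarded",
         nrow(res$assigned), nrow(res$discarded))
  }

  presence <- stage("extract_presence", extract_presence(recs, focal))
  if (nrow(presence) == 0) stop("stage extract_presence: no presences")
  note("extract_presence: %d molecular presences", nrow(presence))

  is_pres <- recs$species_label == focal &
    (recs$is_molecular %||% rep(FALSE, nrow(recs)))
  background <- stage("classify_background",
                      classify_background(recs[!is_pres, , drop = FALSE],
                                          focal, capability,
                                          weighting = "plain"))
  note("classify_background: %d class 1, %d class 2",
       sum(background$background_class == 1),
       sum(background$background_class == 2))

  rng <- stage("extend_range",
               extend_range(world$range, presence, config$disc_km))
  note("extend_range: %d presences outside mapped range",
       attr(rng, "n_extended"))
  brange <- buffer_range(rng, config$buffer_km)

  pseudo <- stage("sample_pseudo_absences",
                  sample_pseudo_absences(world$desert_mask,
                                         config$n_pseudo_absences,
                                         seed = config$master_seed + 1L))
  pseudo$year_used <- max(world$stack$years)
  pseudo$weight <- 1
  note("sample_pseudo_absences: %d points", nrow(pseudo))

  points <- rbind(presence, background, pseudo)
  if (config$weighting == "balanced") points <- rebalance_weights(points)

  covs <- stage("extract_covariates",
                extract_at_points(world$stack, points, points$year_used))
  ok <- rowSums(is.na(covs)) == 0
  note("extract_covariates: %d points, %d dropped on nodata",
       nrow(covs), sum(!ok))
  points <- cbind(points[ok, , drop = FALSE],
                  as.data.frame(covs[ok, , drop = FALSE]))

  split <- stage("split_by_location",
                 split_by_location(points, config$split_fraction,
                                   seed = config$master_seed + 2L))
  note("split_by_location: %d train, %d test records (%d locations withheld)",
       nrow(split$train), nrow(split$test),
       length(split$withheld_locations))

  econfig <- config$ensemble
  econfig$master_seed <- config$master_seed
  models <- stage("fit_ensemble",
                  fit_ensemble(split$train, world$stack$band_names,
                               econfig))
  note("fit_ensemble: %d submodels", length(models))

  summary <- stage("summarise_ensemble",
                   summarise_ensemble(models, world$stack,
                                      buffered_range = brange,
                                      quantiles = econfig$quantiles))
  report <- stage("validate_map", validate_map(summary, split$test))
  note("validate_map: AUC %.4f on %d test points", report$auc,
       report$n_presence + report$n_background)

  run <- structure(list(points = points, split = split, models = models,
                        summary = summary, report = report, log = log,
                        config = config),
                   class = "species_run")
  if (!is.null(out_dir)) write_species_run(run, out_dir)
  run
}

#' Write a pipeline run to disk
#'
#' Summary rasters (mean/median/q025/q975 ASCII grids with provenance),
#' the AUC report, the labelled point table, the frozen resolved
#' configuration (with its hash and master seed), and the stage log.
#'
#' @param run a `species_run`.
#' @param out_dir output directory.
#' @export
write_species_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_ensemble_summary(run$summary, out_dir)
  cfg <- run$config
  frozen <- list(focal_species = cfg$focal_species,
                 buffer_km = cfg$buffer_km,
                 n_pseudo_absences = cfg$n_pseudo_absences,
                 disc_km = cfg$disc_km,
                 split_fraction = cfg$split_fraction,
                 weighting = cfg$weighting,
                 master_seed = cfg$master_seed,
                 ensemble = list(n_submodels = cfg$ensemble$n_submodels,
                                 quantiles = cfg$ensemble$quantiles,
                                 brt = unclass(cfg$ensemble$brt)))
  frozen$config_hash <- config_hash(frozen)
  jsonlite::write_json(frozen, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(auc = run$report$auc, n_presence = run$report$n_presence,
         n_background = run$report$n_background,
         n_nodata_dropped = run$report$n_nodata_dropped,
         n_locations = run$report$n_locations,
         config_hash = frozen$config_hash,
         master_seed = cfg$master_seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(run$points, file.path(out_dir, "points.csv"),
            row.names = FALSE)
  writeLines(run$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.species_run <- function(x, ...) {
  cat(sprintf("<species_run '%s': AUC %.3f, %d submodels>\n",
              x$config$focal_species, x$report$auc,
              length(x$models)))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
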