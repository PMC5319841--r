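#' Withhold a fraction of locations for validation
#'
#' Samples a random fraction of unique locations (not records) to the test
#' set, independently within the presence-location set and the
#' background-location set, so co-located records never straddle the
#' split. The withheld count per set is the fraction rounded half-up with
#' a minimum of 1. `pooled = TRUE` instead samples from the pooled
#' location set.
#'
#' @param points [labelled_points()] with a `location_id` column.
#' @param fraction fraction of locations withheld (default 0.10).
#' @param seed integer seed.
#' @param pooled sample locations from the pooled set instead of within
#'   each class.
#' @return list of class `split_result`: `train`, `test`,
#'   `withheld_locations`, `fraction`, `seed`.
#' @export
split_by_location <- function(points, fraction = 0.10, seed = 1,
                              pooled = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  take <- function(locs, n_basis = length(locs)) {
    k <- max(1L, as.integer(floor(fraction * n_basis + 0.5)))
    sample(locs, min(k, length(locs)))
  }
  if (pooled) {
    locs <- unique(points$location_id)
    if (length(locs) < 2) stop("fewer than 2 locations")
    withheld <- take(locs)
  } else {
    ploc <- unique(points$location_id[points$label == 1])
    bloc <- unique(points$location_id[points$label == 0])
    if (length(ploc) < 2 || length(bloc) < 2)
      stop("fewer than 2 locations in presence or background set")
    withheld <- c(take(ploc), take(setdiff(bloc, ploc), length(bloc)))
  }
  test <- points$location_id %in% withheld
  structure(list(train = points[!test, , drop = FALSE],
                 test = points[test, , drop = FALSE],
                 withheld_locations = withheld,
                 fraction = fraction, seed = seed),
            class = "split_result")
}

#' Rank-based AUC
#'
#' Area under the receiver operating characteristic curve by the
#' Mann-Whitney statistic: the fraction of presence-background score pairs
#' in which the presence scores higher, ties counted one half. 1 is a
#' perfect ranking, 0.5 no better than random, 0 a complete inversion.
#'
#' @param scores_presence,scores_background non-empty numeric score
#'   vectors.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Validate a mean map against withheld test points
#'
#' Reads each test point's score off the ensemble mean raster and computes
#' the AUC of presence versus background test points. Test points landing
#' on nodata pixels (e.g. outside the buffered range) are dropped and
#' counted.
#'
#' @param summary an `ensemble_summary` (or any [vs_raster()] via
#'   `summary$mean`).
#' @param test_points [labelled_points()] withheld by
#'   [split_by_location()].
#' @return list of class `auc_report`: `auc`, `n_presence`,
#'   `n_background`, `n_nodata_dropped`, `n_locations`.
#' @export
validate_map <- function(summary, test_points) {
  r <- if (inherits(summary, "vs_raster")) summary else summary$mean
  scores <- raster_extract(r, test_points$x, test_points$y)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all test points fall on nodata pixels")
  lab <- test_points$label[ok]
  sc <- scores[ok]
  structure(list(auc = compute_auc(sc[lab == 1], sc[lab == 0]),
                 n_presence = sum(lab == 1),
                 n_background = sum(lab == 0),
                 n_nodata_dropped = sum(!ok),
                 n_locations = length(unique(test_points$location_id))),
            class = "auc_report")
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf(paste0("<auc_report: AUC %.3f (%d presence / %d background",
                     " test points, %d locations, %d dropped on nodata)>\n"),
              x$auc, x$n_presence, x$n_background, x$n_locations,
              x$n_nodata_dropped))
  invisible(x)
}
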