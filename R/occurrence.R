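#' Labelled model-ready points
#'
#' Constructor for the point table consumed by the model: coordinates, a
#' presence (1) / background (0) label, the background detection-capability
#' class (1 = the survey's identification methods could have detected the
#' focal species, 2 = they could not; `NA` for presences), a positive
#' weight, the calendar year used for covariate matching, and a location id
#' shared by co-located records (coordinates rounded to 6 decimals), which
#' is the unit of the validation split.
#'
#' @param x,y coordinates.
#' @param label 1 presence, 0 background.
#' @param background_class 1, 2 or `NA`.
#' @param weight positive weights.
#' @param year_used calendar year for covariate matching.
#' @param source provenance tag.
#' @return data.frame of class `labelled_points`.
#' @export
labelled_points <- function(x, y, label, background_class = NA_integer_,
                            weight = 1, year_used = NA_integer_,
                            source = "survey") {
  n <- length(x)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   label = rep_len(as.integer(label), n),
                   background_class = rep_len(as.integer(background_class), n),
                   weight = rep_len(as.numeric(weight), n),
                   year_used = rep_len(as.integer(year_used), n),
                   source = rep_len(source, n),
                   stringsAsFactors = FALSE)
  df$location_id <- location_id(df$x, df$y)
  if (any(df$label == 1 & !is.na(df$background_class)))
    stop("presence points must not carry a background class")
  if (any(!is.na(df$weight) & df$weight <= 0)) stop("weights must be positive")
  class(df) <- c("labelled_points", "data.frame")
  df
}

#' @rdname labelled_points
#' @export
location_id <- function(x, y) sprintf("%.6f_%.6f", round(x, 6), round(y, 6))

#' Detection capability table
#'
#' Maps identification-method codes to the species labels each method can
#' detect. Method codes found in the data but absent from the table are
#' treated as unable to detect any sibling species (conservative: unknown
#' identifications behave like non-molecular ones).
#'
#' @param methods named list: method code -> character vector of detectable
#'   species labels.
#' @return object of class `detection_capability`.
#' @export
detection_capability <- function(methods) {
  stopifnot(is.list(methods), !is.null(names(methods)))
  structure(list(methods = methods), class = "detection_capability")
}

#' @rdname detection_capability
#' @param capability a `detection_capability`.
#' @param method_string `";`"-separated method codes for one record.
#' @param species focal species label.
#' @export
can_detect <- function(capability, method_string, species) {
  vapply(strsplit(as.character(method_string), ";", fixed = TRUE),
         function(codes) {
           codes <- trimws(codes)
           any(vapply(codes, function(m)
             species %in% (capability$methods[[m]] %||% character(0)),
             logical(1)))
         }, logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate occurrence records
#'
#' Applies the automated surrogates of the manual data checks: coordinates
#' present and inside the declared extent, temporally coherent collection
#' years, and at least one usable date field. Failing records are rejected
#' with per-record reason codes; rejections are data, not errors.
#'
#' @param records occurrence data.frame (columns `record_id`, `x`, `y`,
#'   `year_start`, `year_end`, `publication_year`, ...).
#' @param extent a [vs_grid()] or [species_range()] giving the admissible
#'   area.
#' @return list with elements `valid` (records unchanged) and `rejected`
#'   (records plus a `reason` column; multiple reasons joined with `;`).
#' @export
validate_records <- function(records, extent) {
  n <- nrow(records)
  reasons <- vector("list", n)
  add <- function(idx, code) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)

  miss_xy <- is.na(records$x) | is.na(records$y)
  add(miss_xy, "missing_coordinates")
  inside <- rep(FALSE, n)
  ok <- !miss_xy
  if (inherits(extent, "vs_grid")) {
    inside[ok] <- records$x[ok] >= extent$xmin & records$x[ok] < extent$xmax &
      records$y[ok] > extent$ymin & records$y[ok] <= extent$ymax
  } else if (inherits(extent, "species_range")) {
    inside[ok] <- range_contains(extent, records$x[ok], records$y[ok])
  } else stop("extent must be a vs_grid or species_range")
  add(ok & !inside, "coordinate_out_of_range")

  ys <- records$year_start %||% rep(NA_integer_, n)
  ye <- records$year_end %||% rep(NA_integer_, n)
  py <- records$publication_year %||% rep(NA_integer_, n)
  add(!is.na(ys) & !is.na(ye) & ys > ye, "year_order")
  add(is.na(ys) & is.na(py), "missing_year")

  bad <- !vapply(reasons, is.null, logical(1))
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- vapply(reasons[bad], paste, "", collapse = ";")
  else rejected$reason <- character(0)
  list(valid = records[!bad, , drop = FALSE], rejected = rejected)
}

#' Representative collection year
#'
#' Returns a single calendar year per record for covariate matching: the
#' floor of the midpoint of `year_start..year_end` when both are recorded,
#' `year_start` alone when only it is, and otherwise the imputation rule
#' `publication_year - 2` (collections are typically published about two
#' years after the field work).
#'
#' @param records occurrence data.frame.
#' @return integer vector of years, one per record.
#' @export
impute_collection_year <- function(records) {
  n <- nrow(records)
  ys <- records$year_start %||% rep(NA_integer_, n)
  ye <- records$year_end %||% rep(NA_integer_, n)
  py <- records$publication_year %||% rep(NA_integer_, n)
  year <- ifelse(!is.na(ys) & !is.na(ye), floor((ys + ye) / 2),
                 ifelse(!is.na(ys), ys, py - 2L))
  if (any(is.na(year)))
    stop("record(s) without collection or publication year: ",
         paste(which(is.na(year)), collapse = ", "))
  as.integer(year)
}

#' Extract the presence dataset for a focal species
#'
#' Keeps only records that identified the focal species with molecular
#' methods and recorded its presence; morphology-only identifications are
#' excluded as potentially misidentified. Presences get label 1 and unit
#' weight (class balancing happens in [classify_background()]).
#'
#' @param records validated occurrence data.frame.
#' @param focal_species species label.
#' @return [labelled_points()] of presences.
#' @export
extract_presence <- function(records, focal_species) {
  keep <- records$species_label == focal_species &
    (records$is_molecular %||% rep(FALSE, nrow(records)))
  r <- records[keep, , drop = FALSE]
  yr <- if (nrow(r)) impute_collection_year(r) else integer(0)
  labelled_points(r$x, r$y, label = 1L, weight = 1,
                  year_used = yr, source = "presence")
}

#' Classify and weight background records
#'
#' Splits the background survey records for a focal species into class 1
#' (identification methods that would have detected the species had it been
#' present) and class 2 (all others), and assigns weights with the class-1
#' points at exactly twice the class-2 weight. With `weighting =
#' "balanced"` (default) the common factor is chosen so total background
#' weight equals total presence weight; `"plain"` uses weights 2 and 1.
#'
#' @param records background occurrence data.frame (presence-survey records
#'   already excluded), with an `id_methods` column of `;`-separated codes.
#' @param focal_species species label (must appear in `capability`).
#' @param capability a [detection_capability()].
#' @param presences [labelled_points()] of presences (needed for
#'   `"balanced"`).
#' @param weighting `"balanced"` or `"plain"`.
#' @return [labelled_points()] of background points.
#' @export
classify_background <- function(records, focal_species, capability,
                                presences = NULL,
                                weighting = c("balanced", "plain")) {
  weighting <- match.arg(weighting)
  known <- unique(unlist(capability$methods))
  if (!focal_species %in% known)
    stop("unknown focal species label: ", focal_species)
  capable <- can_detect(capability, records$id_methods, focal_species)
  cls <- ifelse(capable, 1L, 2L)
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  if (weighting == "balanced") {
    if (is.null(presences))
      stop("balanced weighting requires the presence points")
    w2 <- sum(presences$weight) / (2 * n1 + n2)
  } else w2 <- 1
  yr <- if (nrow(records)) impute_collection_year(records) else integer(0)
  labelled_points(records$x, records$y, label = 0L, background_class = cls,
                  weight = ifelse(cls == 1L, 2 * w2, w2),
                  year_used = yr, source = "background")
}

#' Resolve historical composite-taxon records
#'
#' Before the split of *An. gambiae* s.s. into *An. gambiae* and *An.
#' coluzzii*, molecular identifications that did not separate the two (the
#' former M/S forms) are labelled `"gambiae_old"`. These are resolved
#' geographically: records outside the buffered *An. coluzzii* range can
#' only be the new *An. gambiae* and are relabelled; records inside the
#' overlap of both buffered ranges are ambiguous and discarded; records
#' inside the buffered *An. coluzzii* range but outside the overlap cannot
#' be attributed either way and are also discarded, with a distinct reason
#' code so the count is auditable.
#'
#' @param records data.frame of records labelled `"gambiae_old"`.
#' @param coluzzii_range_buffered,gambiae_range_buffered buffered
#'   [species_range()] objects.
#' @param new_label label given to resolved records (default `"gambiae"`).
#' @return list `assigned` (relabelled records) and `discarded` (records
#'   with a `reason` column).
#' @export
resolve_gambiae_old <- function(records, coluzzii_range_buffered,
                                gambiae_range_buffered,
                                new_label = "gambiae") {
  if (is.null(coluzzii_range_buffered) || is.null(gambiae_range_buffered))
    stop("both buffered ranges are required")
  in_col <- range_contains(coluzzii_range_buffered, records$x, records$y)
  in_gam <- range_contains(gambiae_range_buffered, records$x, records$y)
  assigned <- records[!in_col, , drop = FALSE]
  if (nrow(assigned)) assigned$species_label <- new_label
  disc <- records[in_col, , drop = FALSE]
  if (nrow(disc))
    disc$reason <- ifelse(in_gam[in_col], "in_range_overlap",
                          "in_coluzzii_range_only")
  else disc$reason <- character(0)
  list(assigned = assigned, discarded = disc)
}
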