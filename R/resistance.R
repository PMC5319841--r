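#' Species-purity filter for bioassay records
#'
#' Keeps a record only if it was molecularly identified and more than
#' `threshold` (strictly) of its mosquitoes belong to a single species;
#' the kept record is attributed to that majority species. Mixed samples
#' (majority proportion at or below the threshold) and records without
#' molecular identification are returned separately rather than deleted,
#' since they are tallied in their own strata.
#'
#' @param records bioassay data.frame with composition columns
#'   `prop_<species>` and a logical `molecular_id`.
#' @param threshold purity threshold (default 0.95; kept iff proportion
#'   `> threshold`).
#' @return list: `kept` (records with a `species` column), `rejected`
#'   (records with a `reason` column: `"mixed_sample"` or
#'   `"no_molecular_id"`).
#' @export
filter_single_species <- function(records, threshold = 0.95) {
  pcols <- grep("^prop_", colnames(records), value = TRUE)
  if (!length(pcols)) stop("no composition (prop_*) columns found")
  comp <- as.matrix(records[, pcols, drop = FALSE])
  if (any(abs(rowSums(comp) - 1) > 1e-9))
    stop("composition proportions must sum to 1")
  pmax_i <- max.col(comp, ties.method = "first")
  p_major <- comp[cbind(seq_len(nrow(comp)), pmax_i)]
  molecular <- records$molecular_id
  keep <- molecular & (p_major > threshold)
  kept <- records[keep, , drop = FALSE]
  if (nrow(kept))
    kept$species <- sub("^prop_", "", pcols)[pmax_i[keep]]
  else kept$species <- character(0)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(!molecular[!keep], "no_molecular_id",
                              "mixed_sample")
  else rejected$reason <- character(0)
  list(kept = kept, rejected = rejected)
}

#' Assign five-year period labels
#'
#' Bins collection years into the reporting periods "<=2000",
#' "2001-2005", "2006-2010", "2011-2015" and subsequent five-year bins.
#' Within each species x insecticide-class group holding fewer than
#' `min_records` records, all periods collapse to a single "all years"
#' bin, following the reporting convention for sparsely sampled species.
#'
#' @param records bioassay data.frame with `year` and (for the collapse
#'   rule) `species` and `insecticide_class` columns.
#' @param min_records group size below which periods are aggregated
#'   (default 10).
#' @return the records with a `period` column added.
#' @export
bin_periods <- function(records, min_records = 10) {
  if (any(is.na(records$year))) stop("record(s) with missing year")
  year_bin <- function(y) {
    ifelse(y <= 2000, "<=2000",
           sprintf("%d-%d", 2001 + 5 * ((y - 2001) %/% 5),
                   2005 + 5 * ((y - 2001) %/% 5)))
  }
  records$period <- year_bin(records$year)
  if (all(c("species", "insecticide_class") %in% colnames(records))) {
    grp <- interaction(records$species, records$insecticide_class,
                       drop = TRUE)
    small <- names(which(table(grp) < min_records))
    records$period[grp %in% small] <- "all years"
  }
  records
}

#' Summarise resistance bioassay records
#'
#' One row per species x insecticide class x period: record count,
#' minimum, maximum and unweighted arithmetic mean percent mortality (the
#' record, not the mosquito, is the unit), and the sorted unique list of
#' countries sampled.
#'
#' @param records filtered and period-binned bioassay records (columns
#'   `species`, `insecticide_class`, `period`, `mortality_pct`,
#'   `country`).
#' @return data.frame sorted by species, class and period, with columns
#'   `species`, `insecticide_class`, `period`, `n_records`, `min_mortality`,
#'   `max_mortality`, `mean_mortality` (1 d.p.), `countries`
#'   (`;`-separated).
#' @export
summarise_resistance <- function(records) {
  cols <- c("species", "insecticide_class", "period", "mortality_pct",
            "country")
  empty <- data.frame(species = character(0),
                      insecticide_class = character(0),
                      period = character(0), n_records = integer(0),
                      min_mortality = numeric(0),
                      max_mortality = numeric(0),
                      mean_mortality = numeric(0),
                      countries = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  stopifnot(all(cols %in% colnames(records)))
  key <- interaction(records$species, records$insecticide_class,
                     records$period, drop = TRUE, sep = "\r")
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    data.frame(species = g$species[1],
               insecticide_class = g$insecticide_class[1],
               period = g$period[1],
               n_records = nrow(g),
               min_mortality = min(g$mortality_pct),
               max_mortality = max(g$mortality_pct),
               mean_mortality = round(mean(g$mortality_pct), 1),
               countries = paste(sort(unique(g$country)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$insecticide_class, out$period), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end bioassay summary
#'
#' Convenience wrapper: purity filter, period binning, then the
#' species x class x period summary table, plus the tallies of records
#' excluded as mixed samples or for lacking molecular identification.
#'
#' @param records raw bioassay data.frame.
#' @param threshold purity threshold (default 0.95).
#' @param min_records period-collapse group size (default 10).
#' @return list: `summary` (the table), `n_kept`, `n_mixed`,
#'   `n_no_molecular`.
#' @export
resistance_summary <- function(records, threshold = 0.95,
                               min_records = 10) {
  f <- filter_single_species(records, threshold)
  binned <- bin_periods(f$kept, min_records)
  list(summary = summarise_resistance(binned),
       n_kept = nrow(f$kept),
       n_mixed = sum(f$rejected$reason == "mixed_sample"),
       n_no_molecular = sum(f$rejected$reason == "no_molecular_id"))
}
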