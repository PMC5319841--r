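# Shared fixtures built in code. small_world() memoises one compact
# synthetic world per seed so several test files can reuse it.

.world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 101, ...) {
  key <- paste0("w", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(
      world_config(grid_width = 32, grid_height = 32,
                   n_survey_locations = 250, cluster_count = 8,
                   seed = seed, ...))
  .world_cache[[key]]
}

# brute-force AUC by pair enumeration, ties counted half
auc_bruteforce <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}

# unit square [0,1]^2 and friends for geometry tests
unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         4, 2, byrow = TRUE)
}

# a constant-prediction BRT model (no trees): handy for ensemble fixtures
constant_model <- function(p, bands = c("b1", "b2")) {
  structure(list(intercept = qlogis(p), trees = list(), shrinkage = 1,
                 band_names = bands, train_deviance = numeric(0),
                 holdout_deviance = numeric(0), n_trees = 0L,
                 config = brt_config()),
            class = "brt_model")
}

# tiny covariate stack with prescribed band matrices (list year -> list of
# ny x nx matrices)
tiny_stack <- function(mats_by_year, years, pixel = 5) {
  ny <- nrow(mats_by_year[[1]][[1]])
  nx <- ncol(mats_by_year[[1]][[1]])
  nb <- length(mats_by_year[[1]])
  grid <- vs_grid(nx, ny, pixel = pixel)
  data <- lapply(mats_by_year, function(ms) {
    arr <- array(NA_real_, c(ny, nx, nb))
    for (b in seq_len(nb)) arr[, , b] <- ms[[b]]
    arr
  })
  covariate_stack(grid, sprintf("band_%02d", seq_len(nb)), years, data)
}

# exhaustive stump-search oracle: all midpoints between sorted unique
# values, weighted SSE reduction, independent of the C++ path
stump_oracle <- function(x, r, w) {
  ux <- sort(unique(x))
  S <- sum(w * r); W <- sum(w)
  best <- list(gain = 0, threshold = NA)
  for (t in utils::head(ux, -1) + diff(ux) / 2) {
    L <- x <= t
    WL <- sum(w[L]); WR <- W - WL
    SL <- sum(w[L] * r[L]); SR <- S - SL
    gain <- SL^2 / WL + SR^2 / WR - S^2 / W
    if (gain > best$gain) best <- list(gain = gain, threshold = t,
                                       SL = SL, WL = WL, SR = SR, WR = WR)
  }
  best
}

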