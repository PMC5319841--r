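#' Boosted regression tree configuration
#'
#' Hyperparameters of the stagewise boosting fit. Defaults follow the
#' conventions of BRT-based species distribution modelling: many small
#' trees at low shrinkage with moderate bagging.
#'
#' @param n_trees number of boosting stages (default 1000).
#' @param shrinkage learning rate in (0, 1] (default 0.005).
#' @param tree_complexity maximum terminal nodes per tree (default 5,
#'   i.e. up to 4 splits).
#' @param bag_fraction fraction of (weighted) observations drawn for each
#'   stage's tree, in (0, 1]; 1 disables bagging and makes the fit
#'   deterministic.
#' @param min_obs_leaf minimum in-bag observations per leaf (default 5).
#' @param early_stopping if `TRUE`, hold out `holdout_fraction` of rows
#'   internally and stop when the holdout deviance has not improved for
#'   `patience` stages, keeping the best stage.
#' @param holdout_fraction,patience early-stopping controls.
#' @param seed integer seed recorded with the model; the caller's RNG
#'   state drives the fit when `seed` is `NA`.
#' @return object of class `brt_config`.
#' @export
brt_config <- function(n_trees = 1000, shrinkage = 0.005,
                       tree_complexity = 5, bag_fraction = 0.75,
                       min_obs_leaf = 5, early_stopping = FALSE,
                       holdout_fraction = 0.2, patience = 50,
                       seed = NA_integer_) {
  stopifnot(n_trees >= 1, shrinkage > 0, shrinkage <= 1,
            tree_complexity >= 2, bag_fraction > 0, bag_fraction <= 1,
            min_obs_leaf >= 1, holdout_fraction > 0, holdout_fraction < 1,
            patience >= 1)
  structure(as.list(environment()), class = "brt_config")
}

#' Fit a weighted boosted regression tree model
#'
#' Stagewise gradient boosting of the Bernoulli deviance for a weighted
#' presence/background response. The intercept is the log-odds of the
#' weighted prevalence; each stage fits a least-squares regression tree
#' (greedy binary splits maximising weighted SSE reduction, grown
#' best-first to at most `tree_complexity` leaves) to the pseudo-residuals
#' `y - p` on a weighted bag of observations, sets each leaf value by the
#' Newton step `sum(w r) / sum(w p (1-p))`, and updates the score by
#' `shrinkage` times the tree. The fit is invariant to rescaling all
#' weights, and an observation of weight 2 is equivalent to the same
#' observation duplicated (at `bag_fraction = 1` and `min_obs_leaf = 1`).
#'
#' @param X numeric covariate matrix with column names.
#' @param y response in {0, 1}.
#' @param w positive observation weights (default 1).
#' @param config a [brt_config()].
#' @return object of class `brt_model`: intercept, list of trees,
#'   shrinkage, band names, training deviance trace, config.
#' @export
fit_brt <- function(X, y, w = rep(1, length(y)), config = brt_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("band_%02d", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), length(y) == length(w))
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2)
    stop("both classes must be present to fit a BRT")
  if (any(!is.finite(X))) stop("non-finite covariate values")
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive")
  if (!is.na(config$seed)) set.seed(config$seed)
  fit <- .brt_fit_cpp(X, as.numeric(y), as.numeric(w),
                      as.integer(config$n_trees), config$shrinkage,
                      as.integer(config$tree_complexity),
                      config$bag_fraction, as.integer(config$min_obs_leaf),
                      isTRUE(config$early_stopping),
                      config$holdout_fraction, as.integer(config$patience))
  structure(list(intercept = fit$intercept, trees = fit$trees,
                 shrinkage = config$shrinkage,
                 band_names = colnames(X),
                 train_deviance = fit$train_deviance,
                 holdout_deviance = fit$holdout_deviance,
                 n_trees = fit$n_trees, config = config),
            class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf(paste0("<brt_model: %d trees, shrinkage %g, %d bands, ",
                     "final train deviance %.4f>\n"),
              x$n_trees, x$shrinkage, length(x$band_names),
              tail_value(x$train_deviance)))
  invisible(x)
}

tail_value <- function(v) if (length(v)) v[length(v)] else NA_real_

#' Predict occurrence probabilities from a BRT model
#'
#' @param object a `brt_model`.
#' @param newdata covariate matrix; columns must match the model's band
#'   names (any order).
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.brt_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!all(object$band_names %in% colnames(newdata)))
      stop("newdata is missing band(s): ",
           paste(setdiff(object$band_names, colnames(newdata)),
                 collapse = ", "))
    newdata <- newdata[, object$band_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$band_names)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$band_names))
  }
  .brt_predict_cpp(object$trees, object$intercept, object$shrinkage,
                   newdata)
}

#' Relative variable influence
#'
#' Per band, the sum of the weighted SSE reductions of all splits on that
#' band across all trees, normalised to percentages (summing to 100).
#'
#' @param model a `brt_model` with at least one tree.
#' @return named numeric vector of percentages, in band order.
#' @export
variable_importance <- function(model) {
  if (length(model$trees) == 0) stop("model has no trees")
  gains <- numeric(length(model$band_names))
  for (tree in model$trees) {
    splits <- tree[tree[, "feature"] >= 0, , drop = FALSE]
    if (nrow(splits))
      for (k in seq_len(nrow(splits)))
        gains[splits[k, "feature"] + 1] <-
          gains[splits[k, "feature"] + 1] + splits[k, "gain"]
  }
  total <- sum(gains)
  out <- if (total > 0) 100 * gains / total else gains
  names(out) <- model$band_names
  out
}

#' BRT model JSON serialisation
#'
#' Trees, intercept, band names, deviance traces and configuration are
#' written with 17 significant digits, so a round trip reproduces the
#' model's predictions exactly.
#'
#' @param model a `brt_model`.
#' @param path output `.json` path.
#' @export
write_brt_json <- function(model, path) {
  obj <- list(intercept = model$intercept, shrinkage = model$shrinkage,
              band_names = model$band_names, n_trees = model$n_trees,
              train_deviance = model$train_deviance,
              holdout_deviance = model$holdout_deviance,
              config = unclass(model$config),
              trees = lapply(model$trees, function(t)
                as.data.frame(t)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_brt_json
#' @export
read_brt_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(obj$trees, function(df) {
    m <- as.matrix(df)
    colnames(m) <- c("feature", "threshold", "left", "right", "value",
                     "gain", "weight")
    m
  })
  cfg <- obj$config
  config <- brt_config(cfg$n_trees, cfg$shrinkage, cfg$tree_complexity,
                       cfg$bag_fraction, cfg$min_obs_leaf,
                       isTRUE(cfg$early_stopping), cfg$holdout_fraction,
                       cfg$patience,
                       if (is.null(cfg$seed)) NA_integer_ else cfg$seed)
  structure(list(intercept = obj$intercept, trees = trees,
                 shrinkage = obj$shrinkage, band_names = obj$band_names,
                 train_deviance = obj$train_deviance,
                 holdout_deviance = obj$holdout_deviance,
                 n_trees = obj$n_trees, config = config),
            class = "brt_model")
}
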