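# manual tree traversal oracle in R
traverse <- function(tree, xrow) {
  node <- 1
  while (tree[node, "feature"] >= 0) {
    node <- if (xrow[tree[node, "feature"] + 1] <= tree[node, "threshold"])
      tree[node, "left"] + 1 else tree[node, "right"] + 1
  }
  tree[node, "value"]
}

test_that("intercept is the log-odds of weighted prevalence", {
  X <- matrix(rnorm(20), 20, 1)
  y <- rep(c(0, 1), 10)
  m <- fit_brt(X, y, config = brt_config(n_trees = 1, bag_fraction = 1))
  expect_equal(m$intercept, 0)
  w <- ifelse(y == 1, 3, 1)
  m2 <- fit_brt(X, y, w, brt_config(n_trees = 1, bag_fraction = 1))
  expect_equal(m2$intercept, qlogis(sum(w * y) / sum(w)))
})

test_that("a single stump matches the exhaustive split-search oracle", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  w <- c(1, 1, 2, 1, 2, 1)
  m <- fit_brt(matrix(x, ncol = 1), y, w,
               brt_config(n_trees = 1, shrinkage = 1, tree_complexity = 2,
                          bag_fraction = 1, min_obs_leaf = 1))
  tree <- m$trees[[1]]
  # oracle works on the stage-0 pseudo-residuals r = y - p0
  p0 <- plogis(m$intercept)
  oracle <- stump_oracle(x, y - p0, w)
  expect_equal(unname(tree[1, "threshold"]), oracle$threshold)
  expect_equal(unname(tree[1, "gain"]), oracle$gain, tolerance = 1e-12)
  # Newton leaf values sum(w r) / sum(w p (1-p)) on each side
  h0 <- p0 * (1 - p0)
  left_val <- oracle$SL / (oracle$WL * h0)
  right_val <- oracle$SR / (oracle$WR * h0)
  expect_equal(unname(tree[tree[1, "left"] + 1, "value"]), left_val,
               tolerance = 1e-12)
  expect_equal(unname(tree[tree[1, "right"] + 1, "value"]), right_val,
               tolerance = 1e-12)
})

test_that("predictions equal manual tree traversal summed over trees", {
  set.seed(31)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rbinom(20, 1, plogis(X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  m <- fit_brt(X, y, config = brt_config(n_trees = 25, shrinkage = 0.1,
                                         bag_fraction = 1,
                                         min_obs_leaf = 2))
  manual <- plogis(m$intercept + m$shrinkage *
                     rowSums(sapply(m$trees, function(tr)
                       apply(X, 1, function(xr) traverse(tr, xr)))))
  expect_equal(predict(m, X), manual, tolerance = 1e-12)
  # duplicate rows get identical predictions
  p <- predict(m, X[c(1, 1, 5, 5), ])
  expect_equal(p[1], p[2])
  expect_equal(p[3], p[4])
})

test_that("a model with no trees predicts the constant intercept probability", {
  m <- constant_model(0.3)
  expect_equal(predict(m, matrix(rnorm(10), 5, 2)), rep(0.3, 5))
})

test_that("training deviance is non-increasing without bagging", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 3]))
  m <- fit_brt(X, y, config = brt_config(n_trees = 300, shrinkage = 0.05,
                                         bag_fraction = 1))
  expect_true(all(diff(m$train_deviance) <= 1e-12))
  expect_length(m$train_deviance, m$n_trees)
})

test_that("rescaling all weights leaves structure and predictions unchanged", {
  set.seed(13)
  X <- matrix(rnorm(150 * 3), 150, 3)
  y <- rbinom(150, 1, plogis(1.5 * X[, 2]))
  w <- runif(150, 0.5, 3)
  cfg <- brt_config(n_trees = 60, shrinkage = 0.1, seed = 99)
  m1 <- fit_brt(X, y, w, cfg)
  m2 <- fit_brt(X, y, 2 * w, cfg)
  for (k in seq_along(m1$trees)) {
    expect_identical(m1$trees[[k]][, c("feature", "threshold", "left",
                                       "right", "value")],
                     m2$trees[[k]][, c("feature", "threshold", "left",
                                       "right", "value")])
  }
  expect_equal(predict(m1, X), predict(m2, X), tolerance = 1e-12)
  expect_equal(m1$train_deviance, m2$train_deviance, tolerance = 1e-12)
})

test_that("a weight-2 observation equals the same observation duplicated", {
  set.seed(17)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  w <- rep(1, n); w[c(4, 9)] <- 2
  cfg <- brt_config(n_trees = 30, shrinkage = 0.2, bag_fraction = 1,
                    min_obs_leaf = 1)
  m_w <- fit_brt(X, y, w, cfg)
  Xd <- rbind(X, X[c(4, 9), ])
  yd <- c(y, y[c(4, 9)])
  m_d <- fit_brt(Xd, yd, rep(1, n + 2), cfg)
  for (k in seq_along(m_w$trees))
    expect_equal(m_w$trees[[k]][, 1:5], m_d$trees[[k]][, 1:5],
                 tolerance = 1e-12)
  expect_equal(predict(m_w, X), predict(m_d, X), tolerance = 1e-12)
})

test_that("boosting long enough separates a separable 1-D problem", {
  x <- seq(-3, 3, length.out = 60)
  y <- as.integer(x > 0.2)
  m <- fit_brt(matrix(x, ncol = 1), y,
               config = brt_config(n_trees = 400, shrinkage = 0.02,
                                   bag_fraction = 1, min_obs_leaf = 1))
  p <- predict(m, matrix(x, ncol = 1))
  expect_equal(compute_auc(p[y == 1], p[y == 0]), 1.0)
})

test_that("variable influence credits split gains and sums to 100", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(x, jitter_col = rep(0, 6))
  m <- fit_brt(X, y, config = brt_config(n_trees = 1, shrinkage = 1,
                                         tree_complexity = 2,
                                         bag_fraction = 1,
                                         min_obs_leaf = 1))
  vi <- variable_importance(m)
  expect_equal(unname(vi), c(100, 0))
  set.seed(23)
  X2 <- matrix(rnorm(200 * 5), 200, 5)
  y2 <- rbinom(200, 1, plogis(X2[, 4]))
  m2 <- fit_brt(X2, y2, config = brt_config(n_trees = 100,
                                            shrinkage = 0.1, seed = 3))
  expect_equal(sum(variable_importance(m2)), 100, tolerance = 1e-9)
  expect_error(variable_importance(constant_model(0.5)), "no trees")
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_brt(X, rep(1, 10)), "both classes")
  expect_error(fit_brt(X, rep(c(0, 1), 5), w = rep(-1, 10)), "positive")
  X2 <- X; X2[3, 1] <- NA
  expect_error(fit_brt(X2, rep(c(0, 1), 5)), "non-finite")
  expect_error(fit_brt(X, c(rep(0, 5), rep(2, 5))), "0/1")
})

test_that("early stopping keeps the best holdout stage", {
  set.seed(41)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- rbinom(300, 1, plogis(0.8 * X[, 1]))
  m <- fit_brt(X, y, config = brt_config(n_trees = 500, shrinkage = 0.1,
                                         early_stopping = TRUE,
                                         patience = 20, seed = 6))
  expect_lte(m$n_trees, 500)
  expect_length(m$holdout_deviance, m$n_trees)
  expect_equal(which.min(m$holdout_deviance), m$n_trees)
})

test_that("model JSON serialisation round-trips predictions exactly", {
  set.seed(3)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- rbinom(100, 1, plogis(X[, 1]))
  m <- fit_brt(X, y, config = brt_config(n_trees = 40, shrinkage = 0.1,
                                         seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_brt_json(m, path)
  m2 <- read_brt_json(path)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_identical(m2$band_names, m$band_names)
})

test_that("an independent gradient-boosting implementation agrees on signal", {
  set.seed(55)
  n <- 600
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rbinom(n, 1, plogis(1.2 * X[, 2] - 1.2 * X[, 5]))
  m <- fit_brt(X, y, config = brt_config(n_trees = 400, shrinkage = 0.05,
                                         seed = 4))
  p_ours <- predict(m, X)
  xgb <- xgboost::xgboost(x = X, y = factor(y), nrounds = 400,
                          learning_rate = 0.05, max_depth = 2,
                          verbosity = 0, nthread = 1)
  p_xgb <- predict(xgb, X)
  auc_ours <- compute_auc(p_ours[y == 1], p_ours[y == 0])
  auc_xgb <- compute_auc(p_xgb[y == 1], p_xgb[y == 0])
  expect_lt(abs(auc_ours - auc_xgb), 0.05)
  vi <- variable_importance(m)
  expect_setequal(names(sort(vi, decreasing = TRUE))[1:2],
                  c("band_02", "band_05"))
})
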