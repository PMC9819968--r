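make_xy <- function(n = 60, seed = 61, noise = 0) {
  set.seed(seed)
  X <- as.data.frame(matrix(stats::rlnorm(n * 9), n, 9))
  names(X) <- paste0("X", 1:9)
  list(X = X, y = log(X$X1) + noise * stats::rnorm(n))
}

test_that("forest fitting is reproducible and validates inputs", {
  d <- make_xy()
  cfg <- analysis_config(n_trees = 50, seed = 9)
  f1 <- fit_forest(d$X, d$y, cfg)
  f2 <- fit_forest(d$X, d$y, cfg)
  expect_identical(predict(f1$rf, d$X), predict(f2$rf, d$X))
  expect_identical(variable_importance(f1), variable_importance(f2))

  expect_error(fit_forest(d$X[1:3, ], d$y[1:3], cfg), "at least 5")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(fit_forest(Xna, d$y, cfg), "missing")
  expect_warning(fit_forest(d$X[1:8, ], d$y[1:8], cfg), "unstable")
})

test_that("a constant response gives constant predictions and zero VI", {
  d <- make_xy()
  y0 <- rep(2.5, nrow(d$X))
  f <- fit_forest(d$X, y0, analysis_config(n_trees = 30, seed = 9))
  expect_equal(unname(predict(f$rf, d$X)), rep(2.5, nrow(d$X)))
  expect_equal(oob_mse(f), rep(0, 30))
  vi <- variable_importance(f)
  expect_equal(unname(vi), rep(0, 9))
  expect_error(importance_ratio(vi), "zero")
})

test_that("per-tree traversal reproduces randomForest predictions", {
  d <- make_xy(n = 80, seed = 62, noise = 0.2)
  f <- fit_forest(d$X, d$y, analysis_config(n_trees = 40, seed = 10))
  ind <- predict(f$rf, d$X, predict.all = TRUE)$individual
  Xm <- data.matrix(d$X)
  for (k in c(1, 7, 20, 40)) {
    expect_equal(footprint3d:::predict_tree(f, k, Xm), unname(ind[, k]),
                 tolerance = 1e-12)
  }
})

test_that("ensemble OOB predictions agree with randomForest's own", {
  d <- make_xy(n = 80, seed = 63, noise = 0.3)
  f <- fit_forest(d$X, d$y, analysis_config(n_trees = 100, seed = 11))
  r2_rf <- 1 - mean((d$y - f$rf$predicted)^2) / stats::var(d$y)
  expect_equal(oob_r2(f), r2_rf, tolerance = 1e-10)
})

test_that("permuting a variable a tree never splits on leaves its MSE", {
  d <- make_xy(n = 60, seed = 64)
  f <- fit_forest(d$X, d$y, analysis_config(n_trees = 60, seed = 12))
  used <- randomForest::varUsed(f$rf, by.tree = TRUE, count = TRUE)
  base <- oob_mse(f)
  perm <- permuted_oob_mse(f, "X7", seed = 99)
  unused <- which(used[7, ] == 0)
  expect_gt(length(unused), 0)
  expect_equal(perm[unused], base[unused], tolerance = 1e-14)
  # reproducibility of the permutation stream
  expect_identical(perm, permuted_oob_mse(f, "X7", seed = 99))
  expect_error(permuted_oob_mse(f, "X42"), "unknown variable")
})

test_that("permuting the informative variable inflates the OOB error", {
  d <- make_xy(n = 100, seed = 65)
  f <- fit_forest(d$X, d$y, analysis_config(n_trees = 100, seed = 13))
  base <- oob_mse(f)
  perm <- permuted_oob_mse(f, "X1", seed = 1)
  expect_gt(mean(perm - base), 0)
  expect_gt(mean(perm > base), 0.95)

  vi <- variable_importance(f)
  expect_equal(names(which.max(vi)), "X1")
  r <- importance_ratio(vi)
  expect_gt(r[["X1"]], 0.5)
})

test_that("the informative variable wins across seeds", {
  wins <- 0
  for (s in 1:10) {
    d <- make_xy(n = 60, seed = 100 + s, noise = 0.1)
    f <- fit_forest(d$X, d$y,
                    analysis_config(n_trees = 150, seed = 200 + s))
    vi <- variable_importance(f)
    wins <- wins + (names(which.max(vi)) == "X1")
  }
  expect_gte(wins, 9)
})

test_that("importance is stable under relabeling of noise variables", {
  d <- make_xy(n = 100, seed = 66)
  cfg <- analysis_config(n_trees = 300, seed = 14)
  r1 <- importance_ratio(variable_importance(fit_forest(d$X, d$y, cfg)))
  Xsw <- d$X
  Xsw[, c("X5", "X7")] <- d$X[, c("X7", "X5")]  # swap two noise columns
  r2 <- importance_ratio(variable_importance(fit_forest(Xsw, d$y, cfg)))
  expect_lt(abs(r1[["X1"]] - r2[["X1"]]), 0.1)
})

test_that("importance ratios normalize with negative handling", {
  expect_equal(unname(importance_ratio(c(a = 3, b = 1))), c(0.75, 0.25))
  expect_equal(unname(importance_ratio(c(a = 2))), 1)
  expect_equal(unname(importance_ratio(c(a = 3, b = -1))), c(1, 0))
  expect_equal(unname(importance_ratio(c(a = 3, b = -1),
                                       negative = "absolute")),
               c(0.75, 0.25))
  expect_equal(sum(importance_ratio(stats::runif(9) - 0.3)), 1)
})

test_that("OOB R2 is high for a noiseless strong signal", {
  d <- make_xy(n = 200, seed = 67, noise = 0)
  f <- fit_forest(d$X, d$y, analysis_config(n_trees = 500, seed = 15))
  expect_gt(oob_r2(f), 0.9)
  expect_lte(oob_r2(f), 1)
})

test_that("category sums reproduce the reference importance table", {
  imp <- cua_importance()
  row2019 <- unlist(imp[imp$response == "ef_size" & imp$slice == "2019",
                        paste0("X", 1:9)])
  cats <- category_importance(row2019)
  expect_equal(unname(cats), c(24.2, 37.4, 38.4), tolerance = 1e-10)

  row2000 <- unlist(imp[imp$response == "ef_size" & imp$slice == "2000",
                        paste0("X", 1:9)])
  cats0 <- category_importance(row2000)
  expect_equal(cats0[["economic"]], 16.0, tolerance = 1e-10)
  expect_equal(cats0[["social"]], 19.4, tolerance = 1e-10)
  # the published environment share (64.4) reflects rounding; the
  # printed cells themselves sum to 64.6
  expect_equal(cats0[["environment"]], 64.6, tolerance = 1e-10)

  pooled <- imp[imp$slice == "pooled", paste0("X", 1:9)]
  avg <- (category_importance(unlist(pooled[1, ])) +
            category_importance(unlist(pooled[2, ]))) / 2
  expect_equal(unname(avg), c(15.95, 25.9, 58.2), tolerance = 1e-10)

  unif <- stats::setNames(rep(1 / 9, 9), paste0("X", 1:9))
  expect_equal(unname(category_importance(unif)), c(2, 3, 4) / 9)
  expect_error(category_importance(c(Z1 = 1)), "no category")
})

test_that("the slice analysis has the published layout", {
  panel <- generate_panel(scenario_config(seed = 71))
  td <- threedef(footprint_accounts(panel))
  cfg <- analysis_config(n_trees = 60, seed = 16)
  imp <- suppressWarnings(run_importance_analysis(panel, td, cfg))
  expect_equal(nrow(imp), 10)  # 2 responses x (4 years + pooled)
  expect_equal(sort(unique(imp$slice)),
               sort(c("2000", "2010", "2015", "2019", "pooled")))
  sums <- rowSums(imp[, paste0("X", 1:9)])
  expect_equal(unname(sums), rep(100, 10), tolerance = 1e-6)
  expect_equal(imp$economic + imp$social + imp$environment,
               unname(sums), tolerance = 1e-9)
  expect_true(all(imp$r2 <= 1))
  expect_true(all(imp$n_obs == ifelse(imp$slice == "pooled", 32, 8)))
  # tiny per-year slices must warn loudly
  expect_warning(run_importance_analysis(panel, td, cfg,
                                         slices = "per-year"),
                 "unstable")
})
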