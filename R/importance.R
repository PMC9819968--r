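#' Fit a random-forest regression for importance analysis
#'
#' Fits a bootstrap ensemble of CART regression trees (via
#' \pkg{randomForest}) keeping, for every tree, its in-bag multiplicities
#' -- the ingredients the out-of-bag (OOB) permutation-importance
#' statistics need.  Each tree is grown on a size-n bootstrap sample; the
#' rows not drawn form the tree's OOB set and act as its internal
#' validation data.
#'
#' @param X Data frame or matrix of predictors (no missing values).
#' @param y Numeric response.
#' @param config An [analysis_config()]; `n_trees`, `mtry`, `min_node`
#'   and `seed` are used.
#' @return An object of class `ef_forest`: list with the fitted
#'   `randomForest`, the training data, `inbag` counts (n x n_trees),
#'   `feature_names` and the config.
#' @export
fit_forest <- function(X, y, config = analysis_config()) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("fit_forest: missing values",
                                 call. = FALSE)
  if (nrow(X) < 5) stop("fit_forest: need at least 5 observations",
                        call. = FALSE)
  if (nrow(X) < config$min_node) {
    stop("fit_forest: fewer observations than the minimum node size",
         call. = FALSE)
  }
  if (nrow(X) < 15) {
    warning("fit_forest: only ", nrow(X), " observations; OOB error and ",
            "importance estimates will be unstable", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = X, y = as.numeric(y), ntree = config$n_trees,
    mtry = min(config$mtry, ncol(X)), nodesize = config$min_node,
    keep.forest = TRUE, keep.inbag = TRUE, importance = FALSE
  )
  structure(
    list(rf = rf, X = data.matrix(X), y = as.numeric(y),
         inbag = rf$inbag, feature_names = colnames(X), config = config),
    class = "ef_forest"
  )
}

# Predict with a single stored regression tree by walking its split
# structure (left if x <= split).  Verified against
# predict(rf, predict.all = TRUE) in the test suite.
predict_tree <- function(forest, k, Xm) {
  f <- forest$rf$forest
  ls <- f$leftDaughter[, k]; rs <- f$rightDaughter[, k]
  bv <- f$bestvar[, k]; sp <- f$xbestsplit[, k]
  st <- f$nodestatus[, k]; pr <- f$nodepred[, k]
  node <- rep(1L, nrow(Xm))
  repeat {
    act <- which(st[node] != -1L)
    if (!length(act)) break
    cur <- node[act]
    goleft <- Xm[cbind(act, bv[cur])] <= sp[cur]
    node[act] <- ifelse(goleft, ls[cur], rs[cur])
  }
  pr[node]
}

oob_rows <- function(forest, k) which(forest$inbag[, k] == 0)

#' Per-tree out-of-bag mean squared error
#'
#' For every tree t, `MSE_t = mean((y_i - yhat_{i,t})^2)` over the
#' tree's own OOB rows, with `yhat_{i,t}` the single tree's prediction.
#' Trees with an empty OOB set are reported as `NA` and excluded from
#' downstream averages.
#'
#' @param forest An `ef_forest`.
#' @return Numeric vector of length `n_trees`.
#' @export
oob_mse <- function(forest) {
  vapply(seq_len(forest$rf$ntree), function(k) {
    rows <- oob_rows(forest, k)
    if (!length(rows)) return(NA_real_)
    pred <- predict_tree(forest, k, forest$X[rows, , drop = FALSE])
    mean((forest$y[rows] - pred)^2)
  }, numeric(1))
}

#' Per-tree OOB error after permuting one variable
#'
#' For every tree, the chosen variable's values are randomly permuted
#' within that tree's OOB rows (a fresh draw per tree from the seeded
#' stream), the tree re-predicts those rows, and the OOB MSE is
#' recomputed.  The increase over [oob_mse()] measures how much the
#' tree's accuracy relies on the variable.
#'
#' @param forest An `ef_forest`.
#' @param variable Name of the variable to permute.
#' @param seed Seed for the permutation stream.
#' @return Numeric vector of per-tree permuted MSEs (`NA` for trees with
#'   an empty OOB set).
#' @export
permuted_oob_mse <- function(forest, variable,
                             seed = forest$config$seed) {
  j <- match(variable, forest$feature_names)
  if (is.na(j)) stop("unknown variable: ", variable, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(forest$rf$ntree), function(k) {
    rows <- oob_rows(forest, k)
    if (!length(rows)) return(NA_real_)
    Xp <- forest$X[rows, , drop = FALSE]
    Xp[, j] <- Xp[sample.int(length(rows)), j]
    pred <- predict_tree(forest, k, Xp)
    mean((forest$y[rows] - pred)^2)
  }, numeric(1))
}

#' Permutation importance of every variable
#'
#' `VI(v) = mean_t(MSE_t(v) - MSE_t)`: the mean increase in per-tree OOB
#' error when variable v is permuted within each tree's OOB rows.  A
#' variable the trees do not rely on changes nothing and scores ~0; the
#' more predictions degrade under permutation, the larger the
#' importance.
#'
#' @param forest An `ef_forest`.
#' @param seed Seed for the permutation stream (one stream drives all
#'   variables and trees, so results are reproducible).
#' @return Named numeric vector of importances, one per predictor.
#' @export
variable_importance <- function(forest, seed = forest$config$seed) {
  base <- oob_mse(forest)
  p <- length(forest$feature_names)
  if (!is.null(seed)) set.seed(seed)
  perm_sum <- numeric(p)
  n_valid <- 0L
  for (k in seq_len(forest$rf$ntree)) {
    rows <- oob_rows(forest, k)
    if (!length(rows)) next
    n_valid <- n_valid + 1L
    m <- length(rows)
    Xo <- forest$X[rows, , drop = FALSE]
    # one traversal per tree: stack the p permuted copies of its OOB rows
    Xs <- Xo[rep(seq_len(m), p), , drop = FALSE]
    for (j in seq_len(p)) {
      Xs[(j - 1L) * m + seq_len(m), j] <- Xo[sample.int(m), j]
    }
    pred <- predict_tree(forest, k, Xs)
    err <- (rep(forest$y[rows], p) - pred)^2
    mse_j <- vapply(seq_len(p), function(j) {
      mean(err[(j - 1L) * m + seq_len(m)])
    }, numeric(1))
    perm_sum <- perm_sum + (mse_j - base[k])
  }
  if (n_valid == 0L) stop("no tree has OOB observations", call. = FALSE)
  stats::setNames(perm_sum / n_valid, forest$feature_names)
}

#' Importance ratios
#'
#' Normalizes permutation importances to fractions summing to 1:
#' `R(v) = VI(v) / sum(VI)`.  Small negative importances (sampling noise
#' of irrelevant variables) are truncated to zero (default) or replaced
#' by their absolute value before normalization, so ratios stay in
#' [0, 1].
#'
#' @param vi Named importance vector from [variable_importance()].
#' @param negative `"truncate"` or `"absolute"`.
#' @return Named vector of ratios summing to 1.
#' @export
importance_ratio <- function(vi, negative = c("truncate", "absolute")) {
  negative <- match.arg(negative)
  v <- if (negative == "truncate") pmax(vi, 0) else abs(vi)
  total <- sum(v)
  if (total <= 0) {
    stop("importance_ratio: total importance is zero", call. = FALSE)
  }
  v / total
}

#' Out-of-bag goodness of fit
#'
#' `R^2 = 1 - MSE_oob / var(y)`, where every observation is predicted by
#' averaging the trees for which it is out-of-bag, and `var(y)` is the
#' sample variance.  Observations that are never OOB (possible with very
#' few trees) are excluded with a message.
#'
#' @param forest An `ef_forest`.
#' @return OOB R-squared (<= 1; can be negative for a useless model).
#' @export
oob_r2 <- function(forest) {
  if (stats::var(forest$y) == 0) {
    stop("oob_r2: response has zero variance", call. = FALSE)
  }
  n <- length(forest$y)
  pred_sum <- numeric(n)
  pred_n <- integer(n)
  for (k in seq_len(forest$rf$ntree)) {
    rows <- oob_rows(forest, k)
    if (!length(rows)) next
    pred_sum[rows] <- pred_sum[rows] +
      predict_tree(forest, k, forest$X[rows, , drop = FALSE])
    pred_n[rows] <- pred_n[rows] + 1L
  }
  covered <- pred_n > 0
  if (!all(covered)) {
    message(sum(!covered), " observation(s) never out-of-bag; excluded")
  }
  pred <- pred_sum[covered] / pred_n[covered]
  1 - mean((forest$y[covered] - pred)^2) / stats::var(forest$y)
}

#' Aggregate importance ratios by indicator category
#'
#' Sums importance ratios over the economic, social and environment
#' indicator groups (see [default_indicator_categories()]).
#'
#' @param ratio Named ratio vector (fractions or percents).
#' @param categories Named character vector mapping every variable in
#'   `ratio` to a category.
#' @return Named numeric vector of category sums, in the scale of
#'   `ratio`.
#' @export
category_importance <- function(ratio,
                                categories =
                                  default_indicator_categories()) {
  uncovered <- setdiff(names(ratio), names(categories))
  if (length(uncovered)) {
    stop("category_importance: no category for ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  cats <- categories[names(ratio)]
  vapply(split(as.numeric(ratio), factor(
    cats, levels = unique(categories))), sum, numeric(1))
}

#' Importance analysis over panel time slices
#'
#' For each year of the panel and for all years pooled, fits two
#' random-forest regressions -- responses `ln(EF_size)` and
#' `ln(EF_depth)`, predictors X1-X9 -- and returns the importance
#' ratios, the category sums and the OOB R-squared, in the layout of a
#' published importance table.
#'
#' @param panel A `city_panel` with indicator columns X1-X9.
#' @param results A `threedef_result` for the same city-years.
#' @param config An [analysis_config()].
#' @param slices `"both"` (default), `"per-year"` or `"pooled"`.
#' @param per_capita Use per-capita (default) or total EF_size as the
#'   size response.
#' @return A data.frame of class `ef_importance`: one row per (response,
#'   slice) with percent ratios X1-X9, `economic`, `social`,
#'   `environment`, `r2` and `n_obs`.
#' @export
run_importance_analysis <- function(panel, results,
                                    config = analysis_config(),
                                    slices = c("both", "per-year",
                                               "pooled"),
                                    per_capita = TRUE) {
  slices <- match.arg(slices)
  key <- match(paste(panel$city, panel$year),
               paste(results$city, results$year))
  if (anyNA(key)) {
    stop("panel and results do not match on (city, year)", call. = FALSE)
  }
  size <- if (per_capita) results$ef_size_pc else results$ef_size_total
  size <- size[key]
  depth <- results$ef_depth[key]
  if (any(size <= 0)) {
    stop("EF_size must be positive to take logarithms; offending rows: ",
         paste(which(size <= 0), collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(panel)[, indicator_names()]
  responses <- list(ef_size = log(size), ef_depth = log(depth))

  slice_sets <- list()
  if (slices %in% c("both", "per-year")) {
    for (y in sort(unique(panel$year))) {
      slice_sets[[as.character(y)]] <- which(panel$year == y)
    }
  }
  if (slices %in% c("both", "pooled")) {
    slice_sets[["pooled"]] <- seq_len(nrow(panel))
  }

  rows <- list()
  i <- 0L
  for (resp in names(responses)) {
    for (sl in names(slice_sets)) {
      i <- i + 1L
      idx <- slice_sets[[sl]]
      cfg <- config
      cfg$seed <- config$seed + i  # distinct, reproducible sub-seeds
      fr <- fit_forest(X[idx, , drop = FALSE], responses[[resp]][idx],
                       cfg)
      ratio <- importance_ratio(variable_importance(fr),
                                negative = config$vi_negative)
      cats <- category_importance(ratio)
      rows[[i]] <- data.frame(
        response = resp, slice = sl,
        as.list(round(100 * ratio, 10)),
        economic = 100 * cats[["economic"]],
        social = 100 * cats[["social"]],
        environment = 100 * cats[["environment"]],
        r2 = oob_r2(fr), n_obs = length(idx),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ef_importance", "data.frame")
  out
}

#' @export
print.ef_forest <- function(x, ...) {
  cat("Random-forest regression:", x$rf$ntree, "trees,",
      length(x$y), "observations,", length(x$feature_names),
      "predictors\n")
  cat(sprintf("OOB R^2 = %.3f\n", oob_r2(x)))
  invisible(x)
}

#' @export
print.ef_importance <- function(x, ...) {
  cat("OOB permutation importance ratios (%):\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
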