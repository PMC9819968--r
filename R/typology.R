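#' Standardize a panel variable
#'
#' Z-scores with the sample (n-1) standard deviation:
#' `(x - mean(x)) / sd(x)`.
#'
#' @param x Numeric vector, length >= 2, nonzero variance.
#' @return Vector with mean 0 and sample sd 1.
#' @export
standardize_panel <- function(x) {
  if (length(x) < 2) stop("standardize_panel needs >= 2 values",
                          call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("standardize_panel: zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Hierarchical clustering of standardized size/depth pairs
#'
#' Agglomerative hierarchical clustering ("systematic clustering") of the
#' observations in the standardized (EF_size, EF_depth) plane: Euclidean
#' distance, Ward linkage, tree cut at `k` clusters.
#'
#' @param z A two-column matrix or data.frame of standardized
#'   coordinates (z_size, z_depth).
#' @param k Number of clusters.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"ward.D2"` (Ward's minimum-variance criterion on Euclidean
#'   distances).
#' @return Integer cluster ids of length `nrow(z)`.
#' @export
cluster_observations <- function(z, k = 4, linkage = "ward.D2") {
  z <- as.matrix(z)
  if (k < 1 || k > nrow(z)) {
    stop("cluster_observations: need 1 <= k <= number of observations",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(z), method = linkage)
  unname(stats::cutree(hc, k = k))
}

#' Assign the four sustainability types
#'
#' Maps `k = 4` clusters in the standardized (size, depth) plane onto the
#' ordered sustainability types:
#' * Type 1 -- high size and high depth: heavy flow occupation plus heavy
#'   stock depletion; least sustainable.
#' * Type 2 -- low size, moderate depth: stock is consumed faster than
#'   flow; low sustainability.
#' * Type 3 -- moderate size and depth: flow utilization outpaces stock
#'   depletion; high sustainability.
#' * Type 4 -- moderate size, low depth: flow-dominated use with lagging
#'   stock consumption; most sustainable.
#'
#' Operationally, cluster centroids are ranked: the highest-depth
#' centroid among clusters whose centroid size lies above the panel
#' median becomes Type 1; of the remainder, the highest-depth centroid at
#' or below the median size becomes Type 2; the rest are ordered by
#' decreasing depth into Types 3 and 4.  Ties are broken by decreasing
#' centroid size.
#'
#' @param clusters Integer cluster ids from [cluster_observations()]
#'   with `k = 4`.
#' @param z The standardized coordinates the clusters were built from.
#' @return Integer vector of types (1-4), one per observation.
#' @export
assign_types <- function(clusters, z) {
  z <- as.matrix(z)
  ids <- sort(unique(clusters))
  if (length(ids) != 4) {
    stop("assign_types requires exactly 4 clusters", call. = FALSE)
  }
  cen_size <- vapply(ids, function(i) mean(z[clusters == i, 1]),
                     numeric(1))
  cen_depth <- vapply(ids, function(i) mean(z[clusters == i, 2]),
                      numeric(1))
  med <- stats::median(z[, 1])
  type_of <- stats::setNames(integer(4), ids)

  pick <- function(cand) {
    # highest depth, ties by highest size
    cand[order(-cen_depth[cand], -cen_size[cand])][1]
  }
  remaining <- seq_along(ids)
  high <- remaining[cen_size[remaining] > med]
  t1 <- pick(if (length(high)) high else remaining)
  remaining <- setdiff(remaining, t1)
  low <- remaining[cen_size[remaining] <= med]
  t2 <- pick(if (length(low)) low else remaining)
  remaining <- setdiff(remaining, t2)
  rest <- remaining[order(-cen_depth[remaining], -cen_size[remaining])]
  type_of[c(t1, t2, rest)] <- 1:4
  unname(type_of[as.character(clusters)])
}

#' Classify city-years into sustainability types
#'
#' Standardizes EF_size and EF_depth jointly across the whole panel,
#' clusters the standardized pairs, and assigns the four ordered
#' sustainability types.
#'
#' @param x A `threedef_result`, see [threedef()].
#' @param k Number of clusters; the type assignment requires 4.
#' @param linkage Agglomeration method, see [cluster_observations()].
#' @param per_capita If `TRUE` (default) the per-capita EF_size is
#'   standardized, otherwise the city total.
#' @return A data.frame of class `ef_typology` with columns `city`,
#'   `year`, `z_size`, `z_depth`, `cluster`, `type`.
#' @export
classify_sustainability <- function(x, k = 4, linkage = "ward.D2",
                                    per_capita = TRUE) {
  if (k != 4) {
    stop("the four-type classification requires k = 4", call. = FALSE)
  }
  size <- if (per_capita) x$ef_size_pc else x$ef_size_total
  z <- cbind(z_size = standardize_panel(size),
             z_depth = standardize_panel(x$ef_depth))
  cl <- cluster_observations(z, k = k, linkage = linkage)
  out <- data.frame(city = x$city, year = x$year,
                    z_size = z[, 1], z_depth = z[, 2],
                    cluster = cl, type = assign_types(cl, z),
                    stringsAsFactors = FALSE)
  class(out) <- c("ef_typology", "data.frame")
  out
}

#' @export
print.ef_typology <- function(x, ...) {
  cat("Ecological sustainability typology:", nrow(x), "city-years\n")
  tab <- table(factor(x$type, levels = 1:4))
  cat("type 1 (least sustainable):", tab[["1"]],
      "| type 2:", tab[["2"]], "| type 3:", tab[["3"]],
      "| type 4 (most sustainable):", tab[["4"]], "\n")
  invisible(x)
}

#' Plot a sustainability typology
#'
#' Scatter of the standardized (size, depth) plane with quadrant axes,
#' colored by assigned type.
#'
#' @param x An `ef_typology`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ef_typology <- function(x, ...) {
  cols <- c("#b2182b", "#ef8a62", "#67a9cf", "#2166ac")
  graphics::plot(x$z_size, x$z_depth, col = cols[x$type], pch = 19,
                 xlab = "standardized EF_size",
                 ylab = "standardized EF_depth", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey50")
  graphics::legend("topleft", legend = paste("type", 1:4), col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}
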