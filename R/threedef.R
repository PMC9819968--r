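#' Ecological footprint size
#'
#' The flow component of the three-dimensional footprint: the portion of
#' demand met by annual regeneration, `sum_j min(EF_j, EC_j)`.
#' Carbon-capture land, whose biocapacity is zero, contributes nothing.
#'
#' @param ef Named per-land-type footprint vector, or a
#'   `footprint_account` (in which case `ec` is taken from it and the
#'   result is per capita).
#' @param ec Named per-land-type carrying-capacity vector, same units as
#'   `ef`.
#' @return Footprint size in the units of `ef` (hm2 or hm2/cap).
#' @export
ef_size <- function(ef, ec = NULL) {
  v <- ef_ec_pair(ef, ec)
  sum(pmin(v$ef, v$ec))
}

#' Ecological footprint depth
#'
#' The stock component of the three-dimensional footprint:
#' `1 + sum_j max(EF_j - EC_j, 0) / sum_j EC_j`.  Per-land-type deficits
#' are taken before summation, so a surplus on one land type cannot
#' offset a deficit on another (the revision of the classical 3D model
#' that removed regional deficit offsetting).  When every land type is in
#' surplus the depth is exactly the "original length" 1; depth > 1 means
#' natural capital stock is being depleted.  Scale-invariant: totals and
#' per-capita accounts give the same depth.
#'
#' @inheritParams ef_size
#' @return Dimensionless depth, always >= 1.
#' @export
ef_depth <- function(ef, ec = NULL) {
  v <- ef_ec_pair(ef, ec)
  denom <- sum(v$ec)
  if (denom <= 0) {
    stop("ef_depth undefined: total carrying capacity is zero",
         call. = FALSE)
  }
  1 + sum(pmax(v$ef - v$ec, 0)) / denom
}

ef_ec_pair <- function(ef, ec) {
  if (is.null(ec)) {
    if (!is.list(ef) || is.null(ef$ef) || is.null(ef$ec)) {
      stop("supply either (ef, ec) vectors or a footprint account",
           call. = FALSE)
    }
    return(list(ef = as.numeric(ef$ef), ec = as.numeric(ef$ec)))
  }
  if (length(ef) != length(ec)) {
    stop("ef and ec must have the same length", call. = FALSE)
  }
  list(ef = as.numeric(ef), ec = as.numeric(ec))
}

#' Per-land-type footprint depth
#'
#' Single-land-type specialization of the depth: `max(1, ef_j / ec_j)`
#' when the land type has biocapacity; 1 when both are zero; undefined
#' (`NA`) when a land type with zero biocapacity carries a positive
#' footprint, as carbon-capture land always does -- which is why
#' published per-land-type depth tables exclude it.
#'
#' @param ef_j,ec_j Footprint and carrying capacity of one land type
#'   (vectors recycle).
#' @return Numeric vector of depths (>= 1), `NA` where undefined.
#' @export
land_depth <- function(ef_j, ec_j) {
  if (any(ef_j < 0 | ec_j < 0, na.rm = TRUE)) {
    stop("land_depth: negative inputs", call. = FALSE)
  }
  out <- ifelse(ec_j > 0, pmax(1, ef_j / ec_j),
                ifelse(ef_j > 0, NA_real_, 1))
  out
}

#' Three-dimensional ecological footprint
#'
#' `EF3D = EF_size * EF_depth`: flow occupation scaled by the number of
#' "layers" of annual regeneration consumed.
#'
#' @param size Footprint size (hm2 or hm2/cap), >= 0.
#' @param depth Footprint depth, >= 1.
#' @return EF3D in the units of `size`.
#' @export
ef3d <- function(size, depth) {
  if (any(size < 0)) stop("ef3d: size must be >= 0", call. = FALSE)
  if (any(depth < 1)) stop("ef3d: depth must be >= 1", call. = FALSE)
  size * depth
}

#' Coefficient of variation
#'
#' Sample coefficient of variation in percent:
#' `100 * sd(x) / mean(x)` with the n-1 standard deviation.
#'
#' @param x Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) {
    stop("coefficient_of_variation needs at least 2 values",
         call. = FALSE)
  }
  m <- mean(x)
  if (m == 0) stop("coefficient_of_variation: mean is zero", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Change statistics between two time points
#'
#' Absolute change, percent change and geometric (compound) annualized
#' growth rate between a start and end value a given number of years
#' apart.  The ratio-based outputs are `NA` when the start value is not
#' positive.
#'
#' @param start,end Values at the two time points.
#' @param years Number of years separating them, >= 1.
#' @return A data.frame with columns `absolute`, `percent`,
#'   `annualized` (both rates in percent).
#' @export
change_stats <- function(start, end, years) {
  if (any(years < 1)) stop("change_stats: years must be >= 1",
                           call. = FALSE)
  ok <- start > 0
  data.frame(
    absolute = end - start,
    percent = ifelse(ok, 100 * (end - start) / start, NA_real_),
    annualized = ifelse(ok, 100 * ((end / start)^(1 / years) - 1),
                        NA_real_)
  )
}

#' Three-dimensional footprint indicators for a panel
#'
#' Computes EF_size, EF_depth and EF3D (per capita and total) and the
#' per-land-type depths for every city-year of a set of footprint
#' accounts.
#'
#' @param accounts A `footprint_accounts` table, see
#'   [footprint_accounts()].
#' @return A data.frame of class `threedef_result` with columns `city`,
#'   `year`, `population`, `ef_size_pc`, `ef_depth`, `ef3d_pc`,
#'   `ef_size_total`, `ef3d_total`, `ef_pc`, `ec_pc` (per-capita account
#'   totals) and `depth_<land_type>` columns (`NA` where undefined).
#' @export
threedef <- function(accounts) {
  accs <- accounts_as_list(accounts)
  n <- length(accs)
  out <- data.frame(
    city = vapply(accs, `[[`, character(1), "city"),
    year = vapply(accs, `[[`, numeric(1), "year"),
    population = vapply(accs, `[[`, numeric(1), "population"),
    stringsAsFactors = FALSE
  )
  out$ef_pc <- vapply(accs, function(a) sum(a$ef), numeric(1))
  out$ec_pc <- vapply(accs, function(a) sum(a$ec), numeric(1))
  out$ef_size_pc <- vapply(accs, function(a) ef_size(a$ef, a$ec),
                           numeric(1))
  out$ef_depth <- vapply(accs, function(a) ef_depth(a$ef, a$ec),
                         numeric(1))
  out$ef3d_pc <- ef3d(out$ef_size_pc, out$ef_depth)
  out$ef_size_total <- out$ef_size_pc * out$population
  out$ef3d_total <- out$ef3d_pc * out$population
  for (lt in land_types()) {
    out[[paste0("depth_", lt)]] <- vapply(accs, function(a) {
      land_depth(a$ef[[lt]], a$ec[[lt]])
    }, numeric(1))
  }
  class(out) <- c("threedef_result", "data.frame")
  out
}

#' Per-land-type depth matrix
#'
#' A wide city x land-type table of footprint depths for the requested
#' years, in the layout customary for published depth tables
#' (carbon-capture land, whose depth is undefined, is excluded by
#' default).
#'
#' @param x A `threedef_result`.
#' @param years Years to include; default all present.
#' @param exclude Land types to drop.
#' @return A data.frame with columns `city`, `year` and one column per
#'   remaining land type.
#' @export
land_depth_table <- function(x, years = NULL,
                             exclude = "carbon_capture_land") {
  if (!is.null(years)) x <- x[x$year %in% years, ]
  keep <- setdiff(land_types(), exclude)
  out <- x[, c("city", "year", paste0("depth_", keep))]
  names(out) <- c("city", "year", keep)
  rownames(out) <- NULL
  out
}

#' Change table between the first and last year of a panel
#'
#' Per-city change statistics of a chosen indicator between two years,
#' in the layout of a published change table: the value in every year,
#' the absolute change and the percent change.
#'
#' @param x A `threedef_result` (or any data.frame with `city`, `year`
#'   and the indicator column).
#' @param indicator Column to summarize, default per-capita EF3D.
#' @param from,to Start and end years; default first and last year
#'   present.
#' @return A data.frame with one row per city: the indicator by year,
#'   `absolute`, `percent` and `annualized` change columns.
#' @export
change_table <- function(x, indicator = "ef3d_pc", from = NULL,
                         to = NULL) {
  yrs <- sort(unique(x$year))
  if (is.null(from)) from <- yrs[1]
  if (is.null(to)) to <- yrs[length(yrs)]
  cities <- unique(x$city)
  wide <- data.frame(city = cities, stringsAsFactors = FALSE)
  for (y in yrs) {
    wide[[paste0("y", y)]] <- x[[indicator]][match(
      paste(cities, y), paste(x$city, x$year))]
  }
  if (to == from) {
    cs <- data.frame(absolute = rep(NA_real_, nrow(wide)),
                     percent = NA_real_, annualized = NA_real_)
  } else {
    cs <- change_stats(wide[[paste0("y", from)]], wide[[paste0("y", to)]],
                       years = to - from)
  }
  cbind(wide, cs)
}

#' @export
print.threedef_result <- function(x, ...) {
  cat("Three-dimensional footprint indicators:", nrow(x), "city-years\n")
  cols <- c("city", "year", "ef_size_pc", "ef_depth", "ef3d_pc")
  print.data.frame(utils::head(as.data.frame(x)[, cols], 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.threedef_result <- function(object, ...) {
  cat("EF_size (hm2/cap): range",
      sprintf("%.3f-%.3f", min(object$ef_size_pc), max(object$ef_size_pc)),
      "\nEF_depth: range",
      sprintf("%.2f-%.2f", min(object$ef_depth), max(object$ef_depth)),
      "\nshare of city-years depleting stock (depth > 1):",
      sprintf("%.0f%%", 100 * mean(object$ef_depth > 1)), "\n")
  invisible(object)
}
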