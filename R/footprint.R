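#' Biological-account ecological footprint
#'
#' Converts per-capita consumption of biological items into standardized
#' bioproductive area per land type: for each item i on land type j the
#' contribution is r_j * C_i / Y_i, with r_j the equivalence factor, C_i
#' the per-capita consumption (kg) and Y_i the item's provincial-hectare
#' average yield (kg/hm2).
#'
#' @param record A panel record (list with a `consumption` element) or a
#'   named per-capita consumption vector (names = item ids, kg/cap).
#' @param yields Yield table, see [read_yield_table()].
#' @param factors Factor table, see [read_factor_table()].
#' @return Named numeric vector over [land_types()], hm2/cap.
#' @export
ef_biological <- function(record, yields = default_yield_table(),
                          factors = default_factor_table()) {
  cons <- record_consumption(record, yields)
  items <- yields[yields$account == "biological", ]
  account_items(cons, items, factors, function(it, c_i, r_j) {
    r_j * c_i / it$average_yield
  })
}

#' Energy-account ecological footprint
#'
#' Converts per-capita energy consumption into fossil-energy and built-up
#' land: each item's contribution is C_i * q_i / D_i * r_j, where q_i is
#' the conversion coefficient (GJ per declared consumption unit, low
#' calorific value), D_i the energy footprint density (GJ/hm2) and r_j
#' the equivalence factor of the land type the item is assigned to
#' (fossil fuels to carbon-capture land, electricity to built-up land).
#'
#' @inheritParams ef_biological
#' @return Named numeric vector over [land_types()], hm2/cap.
#' @export
ef_energy <- function(record, yields = default_yield_table(),
                      factors = default_factor_table()) {
  cons <- record_consumption(record, yields)
  items <- yields[yields$account == "energy", ]
  account_items(cons, items, factors, function(it, c_i, r_j) {
    if (it$energy_footprint_density <= 0) {
      stop("ef_energy: zero energy_footprint_density for ", it$item,
           call. = FALSE)
    }
    c_i * it$convert_coefficient / it$energy_footprint_density * r_j
  })
}

record_consumption <- function(record, yields) {
  cons <- if (is.list(record) && !is.null(record$consumption)) {
    record$consumption
  } else if (is.numeric(record) && !is.null(names(record))) {
    record
  } else {
    stop("expected a panel record or a named consumption vector",
         call. = FALSE)
  }
  unknown <- setdiff(names(cons), yields$item)
  if (length(unknown)) {
    stop("consumption item(s) not in the yield table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cons
}

# shared accumulation loop over the items present in `cons`
account_items <- function(cons, items, factors, contribution) {
  out <- land_type_vector()
  present <- intersect(names(cons), items$item)
  for (nm in present) {
    c_i <- cons[[nm]]
    if (c_i == 0) next
    it <- items[items$item == nm, , drop = FALSE]
    r_j <- factors$equivalence_factor[factors$land_type == it$land_type]
    if (length(r_j) != 1) {
      stop("no equivalence factor for land type ", it$land_type,
           call. = FALSE)
    }
    out[it$land_type] <- out[it$land_type] +
      contribution(as.list(it), c_i, r_j)
  }
  out
}

#' Per-capita ecological carrying capacity
#'
#' Biocapacity per land type: a_j * r_j * y_j * retention, where a_j is
#' the per-capita bioproductive area (hm2/cap), r_j and y_j the
#' equivalence and yield factors, and `retention` the fraction remaining
#' after the biodiversity set-aside (default 0.88).  Carbon-capture land
#' has a yield factor of 0 and therefore contributes no biocapacity.
#'
#' @param record A panel record (list with a `land_area` element) or a
#'   named per-capita area vector (names = land types, hm2/cap).
#' @param factors Factor table.
#' @param retention Biodiversity retention fraction in (0, 1].
#' @return Named numeric vector over [land_types()], hm2/cap.
#' @export
ec_per_capita <- function(record, factors = default_factor_table(),
                          retention = 0.88) {
  stopifnot(retention > 0, retention <= 1)
  area <- if (is.list(record) && !is.null(record$land_area)) {
    record$land_area
  } else if (is.numeric(record) && !is.null(names(record))) {
    record
  } else {
    stop("expected a panel record or a named land-area vector",
         call. = FALSE)
  }
  a <- land_type_vector(area)
  r <- land_type_vector(stats::setNames(factors$equivalence_factor,
                                        factors$land_type))
  y <- land_type_vector(stats::setNames(factors$yield_factor,
                                        factors$land_type))
  a * r * y * retention
}

#' Build a per-city-year footprint account
#'
#' Composes the biological and energy footprint accounts and the
#' biocapacity account for one city-year record.
#'
#' @param record A panel record as produced internally from a
#'   `city_panel` row (list with `city`, `year`, `population`,
#'   `consumption`, `land_area`).
#' @inheritParams ef_biological
#' @param retention Biodiversity retention fraction.
#' @return A list of class `footprint_account` with elements `city`,
#'   `year`, `population`, `ef` and `ec` (named per-land-type vectors,
#'   hm2/cap).
#' @export
build_account <- function(record, yields = default_yield_table(),
                          factors = default_factor_table(),
                          retention = 0.88) {
  ef <- ef_biological(record, yields, factors) +
    ef_energy(record, yields, factors)
  ec <- ec_per_capita(record, factors, retention)
  structure(
    list(city = record$city, year = record$year,
         population = record$population, ef = ef, ec = ec),
    class = "footprint_account"
  )
}

#' Ecological profit and loss
#'
#' The total ecological balance ED = (sum(ef) - sum(ec)) * N in hm2;
#' positive values indicate an ecological deficit (footprint exceeding
#' carrying capacity), negative values a surplus.
#'
#' @param account A `footprint_account` (or a list with `ef`, `ec` and
#'   `population`).
#' @return Total ecological deficit (+) or surplus (-) in hm2.
#' @export
ecological_balance <- function(account) {
  (sum(account$ef) - sum(account$ec)) * account$population
}

#' Footprint accounts for a whole panel
#'
#' Runs [build_account()] over every city-year of a panel and returns the
#' per-capita accounts in tabular form, one row per city-year with
#' `ef_<land_type>` and `ec_<land_type>` columns plus the total ecological
#' balance `ed_total` (hm2).
#'
#' @param panel A `city_panel` data.frame, see [read_city_panel()].
#' @inheritParams build_account
#' @return A data.frame of class `footprint_accounts`.
#' @export
footprint_accounts <- function(panel, yields = default_yield_table(),
                               factors = default_factor_table(),
                               retention = 0.88) {
  recs <- panel_records(panel)
  accounts <- lapply(recs, build_account, yields = yields,
                     factors = factors, retention = retention)
  out <- data.frame(
    city = vapply(accounts, `[[`, character(1), "city"),
    year = vapply(accounts, `[[`, numeric(1), "year"),
    population = vapply(accounts, `[[`, numeric(1), "population"),
    stringsAsFactors = FALSE
  )
  for (lt in land_types()) {
    out[[paste0("ef_", lt)]] <- vapply(accounts, function(a) a$ef[[lt]],
                                       numeric(1))
  }
  for (lt in land_types()) {
    out[[paste0("ec_", lt)]] <- vapply(accounts, function(a) a$ec[[lt]],
                                       numeric(1))
  }
  out$ed_total <- vapply(accounts, ecological_balance, numeric(1))
  class(out) <- c("footprint_accounts", "data.frame")
  out
}

# rebuild the account list view from the tabular form
accounts_as_list <- function(accounts) {
  lapply(seq_len(nrow(accounts)), function(i) {
    structure(
      list(
        city = accounts$city[i], year = accounts$year[i],
        population = accounts$population[i],
        ef = stats::setNames(as.numeric(
          accounts[i, paste0("ef_", land_types())]), land_types()),
        ec = stats::setNames(as.numeric(
          accounts[i, paste0("ec_", land_types())]), land_types())
      ),
      class = "footprint_account"
    )
  })
}

#' @export
print.footprint_account <- function(x, ...) {
  cat("Footprint account:", x$city, x$year,
      sprintf("(N = %g)\n", x$population))
  m <- rbind(ef = x$ef, ec = x$ec)
  print(round(m, 6))
  cat(sprintf("per-capita totals: ef = %.6g, ec = %.6g, ED = %.6g hm2\n",
              sum(x$ef), sum(x$ec), ecological_balance(x)))
  invisible(x)
}

#' @export
print.footprint_accounts <- function(x, ...) {
  cat("Footprint accounts:", nrow(x), "city-years,",
      length(unique(x$city)), "cities\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
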