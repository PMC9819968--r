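#' Bioproductive land types
#'
#' The closed set of land types used throughout the accounts: croplands,
#' forests, grazing lands, fishing grounds, carbon-capture (fossil-energy)
#' land and built-up land.  All per-land-type vectors in the package are
#' named by, and ordered as, this set.
#'
#' @return Character vector of the six land-type identifiers.
#' @export
land_types <- function() {
  c("croplands", "forests", "grazing_lands", "fishing_grounds",
    "carbon_capture_land", "built_up")
}

# normalize free-text land-type labels onto the closed enum
normalize_land_type <- function(x) {
  z <- tolower(trimws(as.character(x)))
  z <- gsub("[ -]+", "_", z)
  aliases <- c(
    cropland = "croplands", cultivated_land = "croplands",
    forest = "forests",
    grazing_land = "grazing_lands", grassland = "grazing_lands",
    fishing_ground = "fishing_grounds", water_area = "fishing_grounds",
    fossil_energy_land = "carbon_capture_land",
    built_up_area = "built_up", built_up_areas = "built_up",
    building_land = "built_up"
  )
  hit <- z %in% names(aliases)
  z[hit] <- aliases[z[hit]]
  bad <- !(z %in% land_types())
  if (any(bad)) {
    stop("unknown land type(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  z
}

# a named per-land-type numeric vector, filling absent types with `fill`
land_type_vector <- function(x = NULL, fill = 0) {
  out <- stats::setNames(rep(fill, length(land_types())), land_types())
  if (!is.null(x) && length(x)) {
    nm <- normalize_land_type(names(x))
    out[nm] <- as.numeric(x)
  }
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a land-type factor table
#'
#' Reads per-land-type equivalence factors (weight converting physical
#' hectares of a land type to standardized hectares of world/province
#' average productivity) and yield factors (local productivity relative to
#' the reference average).  Carbon-capture land conventionally carries a
#' yield factor of zero: no area is set aside to absorb emissions, so it
#' contributes no biocapacity.
#'
#' @param path Path to a CSV file with columns `land_type`,
#'   `equivalence_factor`, `yield_factor`.
#' @return A data.frame with one validated row per land type present,
#'   land-type labels normalized onto [land_types()].
#' @seealso [default_factor_table()] for the packaged provincial-hectare
#'   defaults.
#' @export
read_factor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("land_type", "equivalence_factor", "yield_factor"),
                  "factor table")
  df$land_type <- normalize_land_type(df$land_type)
  if (anyDuplicated(df$land_type)) {
    stop("factor table: duplicated land type", call. = FALSE)
  }
  validate_factor_table(df)
  df[, c("land_type", "equivalence_factor", "yield_factor")]
}

validate_factor_table <- function(df) {
  if (any(!is.finite(df$equivalence_factor)) ||
      any(df$equivalence_factor <= 0)) {
    stop("factor table: equivalence_factor must be > 0", call. = FALSE)
  }
  if (any(!is.finite(df$yield_factor)) || any(df$yield_factor < 0)) {
    stop("factor table: yield_factor must be >= 0", call. = FALSE)
  }
  zero <- df$land_type[df$yield_factor == 0]
  if (length(setdiff(zero, "carbon_capture_land"))) {
    stop("factor table: yield_factor of 0 is only valid for ",
         "carbon_capture_land", call. = FALSE)
  }
  invisible(df)
}

#' Packaged default factor table
#'
#' Equivalence and yield factors for the six land types as used in the
#' provincial-hectare accounts for the Chengdu urban agglomeration
#' (croplands 3.39/1.74, forests 1.1/0.86, grazing lands 0.56/0.51,
#' fishing grounds 0.44/0.74, carbon-capture land 1.1/0, built-up land
#' 3.39/1.74).
#'
#' @return A data.frame as returned by [read_factor_table()].
#' @export
default_factor_table <- function() {
  read_factor_table(pkg_extdata("factors.csv"))
}

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "footprint3d")
  if (p == "") stop("packaged file not found: ", file, call. = FALSE)
  p
}

#' Read a consumption-item yield table
#'
#' Reads the item metadata used to convert per-capita consumption into
#' bioproductive area.  Biological items carry an average yield in kg/hm2
#' (provincial-hectare basis); energy items carry an energy footprint
#' density in GJ/hm2 and a conversion coefficient in GJ per declared
#' consumption unit (low calorific value).  The two field sets are
#' mutually exclusive per item.
#'
#' @param path Path to a CSV file with columns `item`, `land_type`,
#'   `account` (`biological` or `energy`), `average_yield`,
#'   `energy_footprint_density`, `convert_coefficient`, and optionally
#'   `label` and `unit`.
#' @return A validated data.frame of consumption items; empty input yields
#'   an empty table with a warning.
#' @seealso [default_yield_table()]
#' @export
read_yield_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("item", "land_type", "account", "average_yield",
                        "energy_footprint_density", "convert_coefficient"),
                  "yield table")
  if (nrow(df) == 0) {
    warning("yield table is empty", call. = FALSE)
    return(df)
  }
  df$land_type <- normalize_land_type(df$land_type)
  if (anyDuplicated(df$item)) {
    stop("yield table: duplicated item", call. = FALSE)
  }
  validate_yield_table(df)
  df
}

validate_yield_table <- function(df) {
  if (!all(df$account %in% c("biological", "energy"))) {
    stop("yield table: account must be 'biological' or 'energy'",
         call. = FALSE)
  }
  bio <- df$account == "biological"
  has_yield <- is.finite(df$average_yield) & !is.na(df$average_yield)
  has_energy <- (is.finite(df$energy_footprint_density) &
                   !is.na(df$energy_footprint_density)) |
    (is.finite(df$convert_coefficient) & !is.na(df$convert_coefficient))
  if (any(has_yield & has_energy)) {
    stop("yield table: item declares both average_yield and energy fields",
         call. = FALSE)
  }
  if (any(bio & (!has_yield | df$average_yield <= 0))) {
    stop("yield table: biological items need average_yield > 0",
         call. = FALSE)
  }
  en <- !bio
  ok_energy <- is.finite(df$energy_footprint_density) &
    df$energy_footprint_density > 0 &
    is.finite(df$convert_coefficient) & df$convert_coefficient > 0
  if (any(en & !ok_energy)) {
    stop("yield table: energy items need energy_footprint_density > 0 ",
         "and convert_coefficient > 0", call. = FALSE)
  }
  invisible(df)
}

#' Packaged default yield table
#'
#' Provincial-hectare average yields for the biological consumption items
#' (grain, oil, vegetables, sugarcane, tobacco, tea, garden fruit,
#' cocoons, meat, milk, eggs, aquatic products) and energy conversion
#' coefficients for the energy items (raw coal, natural gas, gasoline,
#' diesel, coke, electricity).  Fossil fuels are declared in tons per
#' capita; electricity is declared in units of 1e4 kWh per capita (see the
#' methods vignette for the dimensional reading of its 11.84 GJ/unit
#' coefficient).
#'
#' @return A data.frame as returned by [read_yield_table()].
#' @export
default_yield_table <- function() {
  read_yield_table(pkg_extdata("yields.csv"))
}

#' Read a city-year panel
#'
#' Reads a long-format panel keyed by (city, year).  Consumption columns
#' are named `cons_<item>` and must match items in the yield table;
#' per-capita bioproductive areas are named `area_<land_type>`; the nine
#' socioeconomic/environmental indicators are `X1` ... `X9`.
#'
#' @param path Path to the panel CSV.
#' @param yields Yield table the consumption columns are validated
#'   against; defaults to [default_yield_table()].
#' @param per_capita If `FALSE`, consumption and area columns hold city
#'   totals and are divided by population on ingest.
#' @return A validated data.frame of class `city_panel`, consumptions and
#'   areas per capita.
#' @export
read_city_panel <- function(path, yields = default_yield_table(),
                            per_capita = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_city_panel(df, yields = yields, per_capita = per_capita)
}

#' Validate a data.frame as a city-year panel
#'
#' @param df A data.frame with the schema described in
#'   [read_city_panel()].
#' @inheritParams read_city_panel
#' @return The validated `city_panel` data.frame.
#' @export
as_city_panel <- function(df, yields = default_yield_table(),
                          per_capita = TRUE) {
  require_columns(df, c("city", "year", "population", indicator_names()),
                  "city panel")
  if (anyDuplicated(df[, c("city", "year")])) {
    stop("city panel: duplicate (city, year) key", call. = FALSE)
  }
  if (any(!is.finite(df$population)) || any(df$population <= 0)) {
    stop("city panel: population must be > 0", call. = FALSE)
  }
  cons_cols <- grep("^cons_", names(df), value = TRUE)
  area_cols <- grep("^area_", names(df), value = TRUE)
  unknown <- setdiff(sub("^cons_", "", cons_cols), yields$item)
  if (length(unknown)) {
    stop("city panel: consumption column(s) not in yield table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  normalize_land_type(sub("^area_", "", area_cols))  # errors if unknown
  num_cols <- c(cons_cols, area_cols)
  for (cl in num_cols) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("city panel: negative or non-finite values in ", cl,
           call. = FALSE)
    }
  }
  if (!per_capita) {
    df[num_cols] <- df[num_cols] / df$population
  }
  class(df) <- c("city_panel", "data.frame")
  df
}

indicator_names <- function() paste0("X", 1:9)

#' Indicator categories
#'
#' The mapping of the nine explanatory indicators to their perspective:
#' economic (X1 economic development, X2 industrial structure), social
#' (X3 population size, X4 urbanization, X5 government intervention) and
#' environment (X6 industrial wastewater discharge, X7 industrial exhaust
#' emissions, X8 industrial smoke/dust emission, X9 greenery coverage of
#' the urban area).
#'
#' @return Named character vector mapping indicator name to category.
#' @export
default_indicator_categories <- function() {
  stats::setNames(
    c("economic", "economic", "social", "social", "social",
      "environment", "environment", "environment", "environment"),
    indicator_names()
  )
}

# split a panel data.frame into record lists (city, year, population,
# consumption, land_area, indicators)
panel_records <- function(panel) {
  cons_cols <- grep("^cons_", names(panel), value = TRUE)
  area_cols <- grep("^area_", names(panel), value = TRUE)
  lapply(seq_len(nrow(panel)), function(i) {
    list(
      city = panel$city[i],
      year = panel$year[i],
      population = panel$population[i],
      consumption = stats::setNames(
        as.numeric(panel[i, cons_cols]), sub("^cons_", "", cons_cols)),
      land_area = stats::setNames(
        as.numeric(panel[i, area_cols]), sub("^area_", "", area_cols)),
      indicators = stats::setNames(
        as.numeric(panel[i, indicator_names()]), indicator_names())
    )
  })
}

#' Write a result table to CSV
#'
#' Writes any of the package's result data.frames with a stable column
#' order and full double precision, so that a write/read round trip is the
#' identity up to floating-point representation.
#'
#' @param x Non-empty data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path) {
  if (!is.data.frame(x) || nrow(x) == 0) {
    stop("write_results: nothing to write", call. = FALSE)
  }
  utils::write.csv(format_full_precision(x), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

format_full_precision <- function(x) {
  for (cl in names(x)) {
    if (is.double(x[[cl]])) {
      x[[cl]] <- formatC(x[[cl]], digits = 17, format = "g")
    }
  }
  x
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the biodiversity
#' retention fraction applied to biocapacity (default 0.88, i.e. a 12%
#' set-aside for biodiversity), the random-forest parameters, and the
#' clustering parameters of the typology stage.
#'
#' @param retention Fraction of biocapacity counted as available after
#'   the biodiversity set-aside; in (0, 1].
#' @param n_trees Number of trees per forest.
#' @param mtry Variables tried per split; default `max(1, floor(p/3))`
#'   with p = 9 indicators.
#' @param min_node Minimum terminal-node size of the regression trees.
#' @param vi_negative How negative permutation importances are treated
#'   before normalization: `"truncate"` to zero (default) or
#'   `"absolute"` value.
#' @param k Number of clusters (the typology requires 4).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(retention = 0.88, n_trees = 500, mtry = 3,
                            min_node = 5,
                            vi_negative = c("truncate", "absolute"),
                            k = 4, linkage = "ward.D2", seed = 1L) {
  vi_negative <- match.arg(vi_negative)
  stopifnot(retention > 0, retention <= 1, n_trees >= 1, mtry >= 1,
            min_node >= 1, k >= 2)
  structure(
    list(retention = retention, n_trees = as.integer(n_trees),
         mtry = as.integer(mtry), min_node = as.integer(min_node),
         vi_negative = vi_negative, k = as.integer(k), linkage = linkage,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [analysis_config()].
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}

#' Published reference tables for the Chengdu urban agglomeration
#'
#' Accessors for the published 2000-2019 assessment results of the eight
#' cities of the Chengdu urban agglomeration, shipped as plain-text data:
#' per-land-type footprint depths for 2000 and 2019 (`cua_land_depth`),
#' per-capita three-dimensional footprints for 2000/2010/2015/2019
#' (`cua_ef3d`), and the out-of-bag importance ratios (in percent) with
#' model R-squared for both responses and all time slices
#' (`cua_importance`).  These tables are reference outputs, not inputs:
#' the underlying yearbook consumption data are not public.
#'
#' @return A data.frame.
#' @name cua_reference
NULL

#' @rdname cua_reference
#' @export
cua_land_depth <- function() {
  utils::read.csv(pkg_extdata("cua_land_depth.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname cua_reference
#' @export
cua_ef3d <- function() {
  utils::read.csv(pkg_extdata("cua_ef3d.csv"), stringsAsFactors = FALSE)
}

#' @rdname cua_reference
#' @export
cua_importance <- function() {
  utils::read.csv(pkg_extdata("cua_importance.csv"),
                  stringsAsFactors = FALSE)
}
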