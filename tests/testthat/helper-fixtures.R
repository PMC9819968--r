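# shared fixtures: tiny records and accounts built in code

make_record <- function(consumption = c(grain = 545.3472),
                        land_area = c(croplands = 0.1),
                        city = "a", year = 2000, population = 100) {
  list(city = city, year = year, population = population,
       consumption = consumption, land_area = land_area,
       indicators = stats::setNames(rep(1, 9), paste0("X", 1:9)))
}

make_account <- function(ef, ec, population = 1) {
  structure(list(city = "a", year = 2000, population = population,
                 ef = ef, ec = ec),
            class = "footprint_account")
}

# direct loop transcription of the accounting formulas, used as the
# brute-force oracle against the package implementation
oracle_ef <- function(consumption, yields, factors) {
  out <- stats::setNames(rep(0, length(land_types())), land_types())
  for (nm in names(consumption)) {
    it <- yields[yields$item == nm, ]
    r <- factors$equivalence_factor[factors$land_type == it$land_type]
    contrib <- if (it$account == "biological") {
      r * consumption[[nm]] / it$average_yield
    } else {
      consumption[[nm]] * it$convert_coefficient /
        it$energy_footprint_density * r
    }
    out[it$land_type] <- out[it$land_type] + contrib
  }
  out
}

# direct transcription of the size/depth/3D definitions
oracle_size <- function(ef, ec) sum(pmin(ef, ec))
oracle_depth <- function(ef, ec) {
  1 + sum(pmax(ef - ec, 0)) / sum(ec)
}
oracle_ef3d <- function(ef, ec) oracle_size(ef, ec) * oracle_depth(ef, ec)

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
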