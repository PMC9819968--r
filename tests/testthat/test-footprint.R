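test_that("biological footprint matches hand arithmetic", {
  # grain: r * C / Y = 3.39 * 545.3472 / 5453.472 = 0.339
  ef <- ef_biological(c(grain = 545.3472))
  expect_equal(ef[["croplands"]], 0.339, tolerance = 1e-12)
  expect_true(all(ef[setdiff(land_types(), "croplands")] == 0))

  # two cropland items with individual footprints 0.2 and 0.1 sum to 0.3
  yt <- default_yield_table()
  c_grain <- 0.2 * yt$average_yield[yt$item == "grain"] / 3.39
  c_veg <- 0.1 * yt$average_yield[yt$item == "vegetables"] / 3.39
  ef2 <- ef_biological(c(grain = c_grain, vegetables = c_veg))
  expect_equal(ef2[["croplands"]], 0.3, tolerance = 1e-12)

  # zero consumption everywhere
  ef0 <- ef_biological(c(grain = 0, meat = 0))
  expect_true(all(ef0 == 0))
})

test_that("energy footprint converts through calorific value", {
  # raw coal 1 t/cap: 20.934 GJ / 55 GJ/hm2 * 1.1
  ef <- ef_energy(c(raw_coal = 1))
  expect_equal(ef[["carbon_capture_land"]], 20.934 / 55 * 1.1,
               tolerance = 1e-12)

  # electricity maps to built-up land with cropland-row factors
  efe <- ef_energy(c(electricity = 1))
  expect_equal(efe[["built_up"]], 11.84 / 1000 * 3.39, tolerance = 1e-12)
  expect_equal(efe[["carbon_capture_land"]], 0)

  # zero consumption and linearity
  expect_true(all(ef_energy(c(raw_coal = 0)) == 0))
  mix <- c(raw_coal = 0.7, natural_gas = 0.2, electricity = 0.4)
  expect_equal(ef_energy(2 * mix), 2 * ef_energy(mix), tolerance = 1e-12)
})

test_that("unknown consumption items are a configuration error", {
  expect_error(ef_biological(c(stardust = 1)), "not in the yield table")
  expect_error(ef_energy(c(stardust = 1)), "not in the yield table")
})

test_that("carrying capacity applies factors and biodiversity retention", {
  ec <- ec_per_capita(c(croplands = 0.1))
  expect_equal(ec[["croplands"]], 0.1 * 3.39 * 1.74 * 0.88,
               tolerance = 1e-12)

  # carbon-capture land never contributes biocapacity
  ec2 <- ec_per_capita(c(carbon_capture_land = 5))
  expect_equal(ec2[["carbon_capture_land"]], 0)

  # retention enters as a pure scale factor
  area <- c(croplands = 0.2, forests = 0.4, grazing_lands = 0.1)
  full <- ec_per_capita(area, retention = 1)
  part <- ec_per_capita(area, retention = 0.88)
  expect_equal(part, 0.88 * full, tolerance = 1e-12)

  expect_error(ec_per_capita(c(atlantis = 1)), "unknown land type")
  expect_error(ec_per_capita(c(croplands = 1), retention = 0))
})

test_that("ecological balance is (ef - ec) * N", {
  acc <- make_account(ef = c(croplands = 0.6), ec = c(croplands = 0.4),
                      population = 100)
  expect_equal(ecological_balance(acc), 20)
  acc0 <- make_account(ef = c(croplands = 0.5), ec = c(croplands = 0.5),
                       population = 10)
  expect_equal(ecological_balance(acc0), 0)
  expect_equal(ecological_balance(make_account(numeric(0), numeric(0))), 0)
})

test_that("build_account merges the two accounts per land type", {
  rec <- make_record(
    consumption = c(grain = 500, raw_coal = 0.5, electricity = 0.2),
    land_area = c(croplands = 0.1, forests = 0.05)
  )
  acc <- build_account(rec)
  # no energy item maps to croplands: croplands ef is biological only
  expect_equal(acc$ef[["croplands"]],
               ef_biological(rec)[["croplands"]])
  expect_equal(acc$ef[["carbon_capture_land"]],
               ef_energy(rec)[["carbon_capture_land"]])
  expect_equal(sum(acc$ec), sum(ec_per_capita(rec)))
  # totals derive from per-capita entries
  expect_equal(ecological_balance(acc),
               (sum(acc$ef) - sum(acc$ec)) * rec$population)
})

test_that("an all-surplus record has an ecological surplus", {
  rec <- make_record(consumption = c(grain = 100),
                     land_area = c(croplands = 1))
  acc <- build_account(rec)
  expect_true(all(acc$ef <= acc$ec))
  expect_lt(ecological_balance(acc), 0)
})

test_that("footprint matches a direct loop oracle on random records", {
  yt <- default_yield_table()
  ft <- default_factor_table()
  set.seed(11)
  for (rep in 1:25) {
    n_items <- sample(1:5, 1)
    items <- sample(yt$item, n_items)
    cons <- stats::setNames(stats::runif(n_items, 0, 10), items)
    mine <- ef_biological(cons) + ef_energy(cons)
    want <- oracle_ef(cons, yt, ft)
    expect_equal(mine, want, tolerance = 1e-12)
  }
})

test_that("footprint is additive and degree-1 homogeneous", {
  set.seed(12)
  yt <- default_yield_table()
  items <- sample(yt$item, 6)
  cons <- stats::setNames(stats::runif(6, 0, 5), items)
  split1 <- cons[1:3]
  split2 <- cons[4:6]
  pooled <- ef_biological(cons) + ef_energy(cons)
  parts <- ef_biological(split1) + ef_energy(split1) +
    ef_biological(split2) + ef_energy(split2)
  expect_equal(pooled, parts, tolerance = 1e-12)
  expect_equal(ef_biological(3 * cons) + ef_energy(3 * cons), 3 * pooled,
               tolerance = 1e-12)

  area <- c(croplands = 0.3, forests = 0.2, fishing_grounds = 0.1)
  expect_equal(ec_per_capita(2 * area), 2 * ec_per_capita(area),
               tolerance = 1e-12)
})

test_that("panel accounts table carries per-capita entries for all types", {
  panel <- generate_panel(scenario_config(seed = 21))
  acc <- footprint_accounts(panel)
  expect_equal(nrow(acc), nrow(panel))
  expect_true(all(paste0("ef_", land_types()) %in% names(acc)))
  expect_true(all(paste0("ec_", land_types()) %in% names(acc)))
  expect_true(all(acc$ec_carbon_capture_land == 0))
  expect_true(all(as.matrix(acc[, paste0("ef_", land_types())]) >= 0))
})
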