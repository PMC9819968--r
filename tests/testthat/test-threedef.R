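test_that("size and depth match hand evaluation", {
  ef <- c(2, 5); ec <- c(3, 4)
  expect_equal(ef_size(ef, ec), 6)
  expect_equal(ef_depth(ef, ec), 1 + 1 / 7)
  expect_equal(ef3d(ef_size(ef, ec), ef_depth(ef, ec)), 48 / 7)

  # per-land-type deficits are taken before summing: the naive
  # aggregate (7 - 7)/7 would wrongly report depth 1
  expect_gt(ef_depth(ef, ec), 1 + max(sum(ef) - sum(ec), 0) / sum(ec))
})

test_that("depth is the original length 1 when every type is in surplus", {
  set.seed(31)
  for (rep in 1:20) {
    ec <- stats::runif(6, 0.1, 2)
    ef <- ec * stats::runif(6, 0, 1)
    expect_identical(ef_depth(ef, ec), 1)
  }
  expect_equal(ef_size(c(1, 2), c(3, 4)), 3)  # min degenerates to ef
})

test_that("depth is scale invariant, size is not", {
  ef <- c(2, 5, 0.5); ec <- c(3, 4, 0.1)
  expect_equal(ef_depth(10 * ef, 10 * ec), ef_depth(ef, ec))
  expect_equal(ef_size(10 * ef, 10 * ec), 10 * ef_size(ef, ec))
  expect_error(ef_depth(c(1, 1), c(0, 0)), "undefined")
  expect_equal(ef_size(c(1, 1), c(0, 0)), 0)
})

test_that("per-land-type depth handles the zero-capacity guard", {
  expect_equal(land_depth(20, 2), 10)
  expect_equal(land_depth(1, 2), 1)       # surplus floors at 1
  expect_equal(land_depth(0, 0), 1)
  expect_true(is.na(land_depth(1, 0)))    # undefined, not an error
  expect_equal(land_depth(c(20, 1), c(2, 0)), c(10, NA))
  expect_error(land_depth(-1, 1), "negative")
})

test_that("ef3d validates its domain", {
  expect_equal(ef3d(6, 1 + 1 / 7), 48 / 7)
  expect_equal(ef3d(5, 1), 5)
  expect_equal(ef3d(0, 3), 0)
  expect_error(ef3d(1, 0.5), "depth")
  expect_error(ef3d(-1, 2), "size")
})

test_that("decomposition identity holds when all capacities are positive", {
  set.seed(32)
  for (rep in 1:20) {
    ec <- stats::runif(6, 0.05, 2)
    ef <- stats::runif(6, 0, 3)
    lhs <- ef_size(ef, ec) + (ef_depth(ef, ec) - 1) * sum(ec)
    expect_equal(lhs, sum(ef), tolerance = 1e-12)
  }
})

test_that("size and depth are monotone in capacity and footprint", {
  set.seed(33)
  ec <- stats::runif(6, 0.1, 2)
  ef <- stats::runif(6, 0, 3)
  for (j in 1:6) {
    ef2 <- ef; ef2[j] <- ef2[j] + 0.5
    expect_gte(ef_depth(ef2, ec), ef_depth(ef, ec))
    ec2 <- ec; ec2[j] <- ec2[j] + 0.5
    expect_gte(ef_size(ef, ec2), ef_size(ef, ec))
  }
})

test_that("revised depth never benefits from surplus/deficit offsetting", {
  set.seed(34)
  found <- 0
  for (rep in 1:50) {
    ec <- stats::runif(4, 0.1, 2)
    ef <- ec * stats::runif(4, 0, 2.5)
    if (any(ef > ec) && any(ef < ec)) {
      found <- found + 1
      naive <- 1 + max(sum(ef) - sum(ec), 0) / sum(ec)
      expect_gt(ef_depth(ef, ec), naive)
    }
  }
  expect_gt(found, 10)
})

test_that("coefficient of variation uses the sample convention", {
  expect_equal(coefficient_of_variation(c(1, 3)), 70.71068,
               tolerance = 1e-6)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  expect_error(coefficient_of_variation(1), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("change statistics combine absolute, percent and annual rates", {
  cs <- change_stats(10.90, 18.83, years = 19)
  expect_equal(cs$absolute, 7.93)
  expect_equal(cs$percent, 100 * 7.93 / 10.90, tolerance = 1e-12)
  cs2 <- change_stats(1, 2, years = 10)
  expect_equal(cs2$annualized, 7.177346, tolerance = 1e-6)
  cs3 <- change_stats(5, 5, years = 4)
  expect_equal(unlist(cs3), c(absolute = 0, percent = 0, annualized = 0))
  cs4 <- change_stats(0, 5, years = 4)
  expect_equal(cs4$absolute, 5)
  expect_true(is.na(cs4$percent) && is.na(cs4$annualized))
  expect_error(change_stats(1, 2, years = 0), "years")
})

test_that("panel-level indicators satisfy their defining identities", {
  panel <- generate_panel(scenario_config(seed = 41))
  acc <- footprint_accounts(panel)
  td <- threedef(acc)
  expect_equal(td$ef3d_pc, td$ef_size_pc * td$ef_depth, tolerance = 1e-14)
  expect_equal(td$ef_size_total, td$ef_size_pc * td$population)
  expect_true(all(td$ef_depth >= 1))
  expect_true(all(td$ef_size_pc <= td$ec_pc + 1e-12))
  # carbon-capture land always carries the deficit here: depth undefined
  expect_true(all(is.na(td$depth_carbon_capture_land)))
  expect_true(all(td[, paste0("depth_", setdiff(
    land_types(), "carbon_capture_land"))] >= 1))
})

test_that("land-depth and change tables are internally consistent", {
  panel <- generate_panel(scenario_config(seed = 42))
  td <- threedef(footprint_accounts(panel))
  ld <- land_depth_table(td, years = c(2000, 2019))
  expect_false("carbon_capture_land" %in% names(ld))
  expect_equal(nrow(ld), 16)

  ct <- change_table(td)
  expect_equal(ct$absolute, ct$y2019 - ct$y2000, tolerance = 1e-12)
  expect_equal(ct$percent, 100 * ct$absolute / ct$y2000,
               tolerance = 1e-12)
})
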