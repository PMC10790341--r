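test_that("mural volume follows the power law and matches the printed values", {
  p <- growth_params()
  expect_equal(mural_volume(0, p), 0)
  expect_equal(signif(mural_volume(350, p), 2), 1.0e7)
  expect_equal(signif(mural_volume(100, p), 2), 2.3e5)
  d <- seq(10, 600, by = 10)
  expect_true(all(diff(mural_volume(d, p)) > 0))
  expect_error(mural_volume(-1, p), "diameter")
})

test_that("diameter and cell count convert both ways", {
  p <- growth_params()
  expect_equal(cell_count_from_diameter(0, p), 0)
  expect_equal(signif(cell_count_from_diameter(200, p), 2), 1.4e4)
  # paper rounds N(450) to 1.6e5; the exact value is ~1.68e5
  expect_equal(cell_count_from_diameter(450, p), 1.6e5, tolerance = 0.07)
  # round trip over the whole working range, relative error < 1e-9
  d <- seq(50, 600, length.out = 56)
  expect_equal(diameter_from_cell_count(cell_count_from_diameter(d, p), p),
               d, tolerance = 1e-9)
  # closed form agrees with bisection inversion
  expect_equal(diameter_from_cell_count(77900, p),
               oracle_diameter_bisect(77900), tolerance = 1e-8)
  expect_equal(round(diameter_from_cell_count(77900, p)), 350)
  expect_error(diameter_from_cell_count(-5, p), "cell_count")
})

test_that("effective LI applies the first-iteration rule, decline and clamps", {
  p <- growth_params()
  expect_equal(effective_li(0.30, 200, 200, p), 0.795 * 0.30)
  expect_equal(effective_li(0.30, 300, 200, p), 0.795 * (0.30 - 0.08))
  expect_equal(effective_li(0.05, 300, 200, p), 0)  # floored before scaling
  expect_error(effective_li(0.30, 150, 200, p), "diameter_now")
})

test_that("one growth step reproduces the hand-iterated value", {
  p <- growth_params()
  start <- follicle_state(334, 0.303, params = p)
  s1 <- grow_one_day(start, start, p)
  expect_equal(s1$diameter, 358.4909, tolerance = 1e-6)
  expect_equal(s1$day, 1L)
  # zero LI: no growth
  s0 <- follicle_state(334, 0, params = p)
  expect_equal(grow_one_day(s0, s0, p)$diameter, 334)
})

test_that("simulated trajectories match the independent brute-force oracle", {
  p <- growth_params()
  for (d0 in c(170, 250, 334, 420)) {
    for (li0 in c(0, 0.2, 0.45)) {
      tr <- simulate_growth(d0, li0, 6, p)
      or <- oracle_growth(d0, li0, 6)
      expect_equal(tr$diameter, or$diameter, tolerance = 1e-12)
      expect_equal(tr$cell_count, or$cell_count, tolerance = 1e-12)
    }
  }
  expect_equal(nrow(simulate_growth(250, 0.3, 0, p)), 1)
})

test_that("with no decline and unit adjustment growth is exactly exponential", {
  p <- growth_params(adjustment_factor = 1, li_decline_slope = 0)
  for (li0 in c(0.1, 0.33, 0.6)) {
    tr <- simulate_growth(200, li0, 8, p)
    expect_equal(tr$cell_count,
                 cell_count_from_diameter(200, p) * (1 + li0)^(0:8),
                 tolerance = 1e-9)
  }
})

test_that("trajectory invariants hold: cell count non-decreasing, applied LI non-increasing", {
  p <- growth_params()
  tr <- simulate_growth(180, 0.42, 12, p)
  expect_true(all(diff(tr$cell_count) >= 0))
  expect_true(all(diff(tr$li_applied[-1]) <= 1e-12))
})

test_that("days_to_diameter matches oracle values and is monotone", {
  p <- growth_params()
  expect_equal(days_to_diameter(170, 0.434, 350, p), 9)  # brute-force oracle
  expect_equal(days_to_diameter(250, 0.45, 350, p), 4)
  expect_equal(days_to_diameter(349.9, 0.3, 350, p), 1)
  expect_true(is.na(days_to_diameter(200, 0, 350, p)))
  # non-increasing in LI0 and in starting diameter
  for (d0 in c(200, 250, 300)) {
    days <- vapply(c(0.25, 0.35, 0.45, 0.55),
                   function(l) days_to_diameter(d0, l, 350, p), integer(1))
    expect_true(all(diff(days) <= 0))
  }
  for (li0 in c(0.3, 0.45)) {
    days <- vapply(c(200, 250, 300, 330),
                   function(d) days_to_diameter(d, li0, 350, p), integer(1))
    expect_true(all(diff(days) <= 0))
  }
})

test_that("the literal growth-equation reading is exposed and degenerates", {
  p <- growth_params()
  lit <- simulate_growth(250, 0.45, 3, p, strategy = "literal")
  std <- simulate_growth(250, 0.45, 3, p)
  # the dimensionless correction applied per cell of increase stalls the
  # first iteration almost completely ...
  expect_lt(lit$diameter[2] - 250, 0.01)
  expect_gt(std$diameter[2] - 250, 20)
  # ... and later steps alternate erratically instead of declining smoothly
  expect_false(all(diff(lit$li_applied[-1]) <= 0))
  expect_lt(lit$diameter[4], std$diameter[4])
})

test_that("table regeneration reproduces every printed cell within 7%", {
  p <- growth_params()
  tab <- generate_table1(params = p)
  expect_equal(tab$proliferation_rate, table1_printed$rate_percent / 100)
  expect_true(all(abs(tab$mural_volume_um3 /
                        table1_printed$mural_volume_um3 - 1) <= 0.07))
  expect_true(all(abs(tab$cell_count / table1_printed$cell_count - 1) <= 0.07))
  expect_true(all(abs(tab$cell_increase /
                        table1_printed$cell_increase - 1) <= 0.07))
  expect_equal(generate_table1(300, 0, p)$cell_increase, 0)
  expect_error(generate_table1(c(100, 200), 0.3, p), "length")
})

test_that("adjustment-factor calibration recovers planted values", {
  p <- growth_params()
  for (a in c(0.795, 1.0, 0.6)) {
    pa <- p
    pa$adjustment_factor <- a
    obs <- simulate_growth(280, 0.35, 4, pa)[c("day", "diameter")]
    expect_equal(calibrate_adjustment(obs, 0.35, p), a, tolerance = 0.01)
  }
  expect_error(calibrate_adjustment(data.frame(day = 0, diameter = 300), 0.3, p),
               "at least 2")
  expect_error(
    calibrate_adjustment(data.frame(day = 0:2, diameter = c(300, 290, 280)),
                         0.3, p),
    "increasing")
})

test_that("growth parameters validate their invariants and load from config", {
  expect_error(growth_params(volume_exponent = 0.9))
  expect_error(growth_params(adjustment_factor = 0))
  expect_error(growth_params(li_decline_slope = -1e-4))
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "params.yaml")
  writeLines(c("adjustment_factor: 1.0", "li_decline_slope: 0.0005"), yml)
  p <- growth_params_from_config(yml)
  expect_equal(p$adjustment_factor, 1.0)
  expect_equal(p$li_decline_slope, 5e-4)
  expect_equal(p$volume_coefficient, 0.18)  # untouched default
  writeLines("not_a_key: 3", yml)
  expect_error(growth_params_from_config(yml), "unknown")
})

test_that("median LI line passes through the printed rate column", {
  p <- growth_params()
  expect_equal(median_li(seq(100, 450, 50), p),
               c(49, 45, 41, 37, 33, 29, 25, 21) / 100)
  expect_equal(median_li(170, p), 0.434)
})
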