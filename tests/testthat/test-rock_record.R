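test_that("volume flux matches the closed-form single-unit budget", {
  # 10,000 km2 x 200 m over 10 Ma -> 2,000 km3 total, 10 km3 per 50-ka bin
  units <- validate_strat_table(tibble::tibble(
    region = "A", unit_id = "A_U1", group = "siliciclastic",
    depth = "shallow_inner_shelf", mean_thickness = 200, area = 10000,
    base_age = 580, top_age = 570
  ), "rock_units")
  g <- time_grid(580, 570)
  flux <- compute_volume_flux(units, g)
  tot <- flux_total(flux, g)
  expect_equal(sum(tot$volume_km3), 2000, tolerance = 1e-12)
  expect_equal(unique(round(tot$volume_km3, 9)), 10)
  expect_equal(nrow(tot), 200)
})

test_that("partial bin overlap allocates proportionally (integration oracle)", {
  units <- validate_strat_table(tibble::tibble(
    region = "A", unit_id = "A_U1", group = "limestone",
    depth = "shallow_inner_shelf", mean_thickness = 120, area = 5000,
    base_age = 580.000, top_age = 570.025
  ), "rock_units")
  g <- time_grid(581, 570)
  flux <- compute_volume_flux(units, g)
  tot <- flux_total(flux, g)
  # the 570.05-570.00 bin is only half covered by the unit
  half_bin <- tot$volume_km3[abs(tot$bin_older - 570.05) < 1e-9]
  full_bin <- tot$volume_km3[abs(tot$bin_older - 570.15) < 1e-9]
  expect_equal(half_bin, full_bin / 2, tolerance = 1e-9)
  # midpoint-rule oracle over a handful of bins, including the partial ones
  for (bo in c(580.05, 580.00, 575.00, 570.10, 570.05)) {
    got <- tot$volume_km3[abs(tot$bin_older - bo) < 1e-9]
    want <- oracle_bin_volume(5000, 120, 580.000, 570.025, bo, bo - 0.05)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("binned volumes conserve area x thickness and behave linearly", {
  g <- time_grid(580, 540)
  withr::with_seed(31, {
    units <- validate_strat_table(tibble::tibble(
      region = sample(c("A", "B", "C"), 30, replace = TRUE),
      unit_id = sprintf("U%02d", 1:30),
      group = sample(c("siliciclastic", "limestone", "dolostone"), 30,
                     replace = TRUE),
      depth = sample(c("shallow_inner_shelf", "lower_slope_basinal"), 30,
                     replace = TRUE),
      mean_thickness = runif(30, 10, 500),
      area = runif(30, 1e3, 1e6),
      base_age = runif(30, 560, 580),
      top_age = runif(30, 541, 559)
    ), "rock_units")
  })
  flux <- compute_volume_flux(units, g)
  # conservation per unit (units all live strictly inside the grid)
  per_region_unit <- flux |>
    dplyr::group_by(region, group, depth) |>
    dplyr::summarise(v = sum(volume_km3), .groups = "drop")
  expect_equal(sum(flux$volume_km3),
               sum(units$area * units$mean_thickness / 1000),
               tolerance = 1e-9)
  # per-lithofacies partitions sum bin-wise to the total
  tot <- flux_total(flux, g)
  by_class <- flux |>
    dplyr::group_by(bin_mid) |>
    dplyr::summarise(v = sum(volume_km3), .groups = "drop")
  cmp <- dplyr::left_join(tot, by_class, by = "bin_mid") |>
    dplyr::mutate(v = dplyr::coalesce(v, 0))
  expect_equal(cmp$volume_km3, cmp$v, tolerance = 1e-9)
  # linearity over a disjoint split of the unit set
  f1 <- flux_total(compute_volume_flux(units[1:12, ], g), g)
  f2 <- flux_total(compute_volume_flux(units[13:30, ], g), g)
  expect_equal(f1$volume_km3 + f2$volume_km3, tot$volume_km3,
               tolerance = 1e-9)
})

test_that("zero-thickness units contribute zero flux; zero duration errors", {
  units <- fixture_units()
  units$mean_thickness[] <- 0
  flux <- compute_volume_flux(units, time_grid(580, 560))
  expect_equal(sum(flux_total(flux)$volume_km3), 0)
  bad <- fixture_units()
  bad$top_age[1] <- bad$base_age[1]
  expect_error(validate_strat_table(bad, "rock_units"), "base_age")
})

test_that("lithofacies percentages normalize within the marine nonevaporitic universe", {
  units <- validate_strat_table(tibble::tibble(
    region = "A",
    unit_id = c("U1", "U2", "U3", "U4"),
    group = c("siliciclastic", "limestone", "siliciclastic",
              "evaporitic_semirestricted"),
    depth = c("shallow_inner_shelf", "shallow_inner_shelf",
              "lower_slope_basinal", "not_applicable"),
    mean_thickness = c(30, 50, 20, 10),
    area = 1000, base_age = 575, top_age = 570
  ), "rock_units")
  g <- time_grid(575, 570)
  pct <- lithofacies_percentages(compute_volume_flux(units, g), g)
  one_bin <- dplyr::filter(pct, abs(bin_mid - 572.025) < 1e-9)
  expect_equal(sum(one_bin$pct), 100, tolerance = 1e-9)
  got <- setNames(one_bin$pct, paste(one_bin$group, one_bin$depth, sep = "."))
  expect_equal(unname(got["siliciclastic.shallow_inner_shelf"]), 30)
  expect_equal(unname(got["limestone.shallow_inner_shelf"]), 50)
  expect_equal(unname(got["siliciclastic.lower_slope_basinal"]), 20)
  # evaporite excluded from numerator and denominator entirely
  expect_false(any(one_bin$group == "evaporitic_semirestricted"))
})

test_that("evaporite-only and empty bins are missing, not zero", {
  units <- validate_strat_table(tibble::tibble(
    region = "A", unit_id = c("U1", "U2"),
    group = c("evaporitic_semirestricted", "limestone"),
    depth = c("not_applicable", "shallow_inner_shelf"),
    mean_thickness = c(10, 40), area = 1000,
    base_age = c(575, 573), top_age = c(574, 572)
  ), "rock_units")
  g <- time_grid(576, 571)
  pct <- lithofacies_percentages(compute_volume_flux(units, g), g)
  evap_bin <- dplyr::filter(pct, abs(bin_mid - 574.525) < 1e-9)
  expect_true(all(is.na(evap_bin$pct)))  # only evaporite deposited there
  carb_bin <- dplyr::filter(pct, abs(bin_mid - 572.525) < 1e-9,
                            group == "limestone")
  expect_equal(carb_bin$pct, 100)
})

test_that("area series counts region cover and nondeposition fraction", {
  units <- validate_strat_table(tibble::tibble(
    region = c("A", "B"), unit_id = c("A1", "B1"),
    group = "siliciclastic", depth = "shallow_inner_shelf",
    mean_thickness = 10, area = c(100, 300),
    base_age = c(575, 574), top_age = c(573, 570)
  ), "rock_units")
  areas <- c(A = 100, B = 300)
  g <- time_grid(576, 570)
  ar <- compute_area_series(units, areas, g)
  at <- function(bo) ar[abs(ar$bin_older - bo) < 1e-9, ]
  expect_equal(at(571.00)$area_km2, 300)          # only B deposits
  expect_equal(at(571.00)$nondep_fraction, 0.25)
  expect_equal(at(573.50)$nondep_fraction, 0)     # both deposit
  expect_equal(at(576.00)$nondep_fraction, 1)     # neither deposits
  expect_true(all(ar$nondep_fraction >= 0 & ar$nondep_fraction <= 1))
  bad <- units; bad$region[1] <- "Z"
  expect_error(compute_area_series(bad, areas, g), "unknown region")
})

test_that("leave-one-region-out equals recomputation on the complement", {
  units <- fixture_units()
  g <- time_grid(580, 560)
  out <- leave_region_out(units, region = "A")
  expect_equal(nrow(out$units), 2)
  f_removed <- flux_total(compute_volume_flux(out$units, g), g)
  f_complement <- flux_total(
    compute_volume_flux(dplyr::filter(units, region != "A"), g), g)
  expect_equal(f_removed, f_complement)
})

test_that("unit-max normalization scales to 1 and rejects degenerate input", {
  expect_equal(normalize_to_unit_max(c(2, 4)), c(0.5, 1))
  expect_equal(normalize_to_unit_max(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(normalize_to_unit_max(c(2, NA, 4)), c(0.5, NA, 1))
  expect_error(normalize_to_unit_max(c(0, 0)), "positive")
  expect_error(normalize_to_unit_max(numeric()), "empty")
})
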