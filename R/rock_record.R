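# Volume/area flux budgeting: unit volume = area (km^2) x mean thickness
# (converted m -> km), spread uniformly over the unit's duration (the
# compilation assumes a continuous depositional rate), and apportioned to
# 50-ka bins by proportional overlap.

#' Compute binned sedimentary volume flux
#'
#' Each unit's volume (`area * mean_thickness / 1000`, km^3) is distributed
#' uniformly over its `base_age`-`top_age` span; every flux bin receives the
#' share proportional to its overlap with the unit. The result is returned
#' long, partitioned by region and lithofacies (group x depth), so the
#' partitions sum bin-wise to the total.
#'
#' @param units A validated rock-unit tibble (see [read_strat_table()]).
#' @param grid A [time_grid()].
#' @return A tibble of class `flux_series` with columns `bin_older`,
#'   `bin_younger`, `bin_mid`, `region`, `group`, `depth`, `volume_km3`;
#'   only non-zero contributions are materialized.
#' @export
#' @examples
#' cfg <- synth_config(master_seed = 7)
#' units <- simulate_rock_record(cfg, time_grid(580, 560))
#' flux <- compute_volume_flux(units, time_grid(580, 560))
compute_volume_flux <- function(units, grid) {
  bins <- build_flux_bins(grid)
  zero_dur <- which(units$base_age - units$top_age <= 0)
  if (length(zero_dur) > 0L) {
    abort(sprintf("zero-duration rock unit: %s",
                  paste(units$unit_id[zero_dur], collapse = ", ")))
  }
  parts <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    base <- units$base_age[i]; top <- units$top_age[i]
    ov <- pmax(0, pmin(base, bins$bin_older) - pmax(top, bins$bin_younger))
    sel <- which(ov > 0)
    if (length(sel) == 0L) return(tibble::tibble())
    vol <- units$area[i] * units$mean_thickness[i] / 1000
    tibble::tibble(
      bin_older = bins$bin_older[sel],
      bin_younger = bins$bin_younger[sel],
      bin_mid = bins$bin_mid[sel],
      region = units$region[i],
      group = units$group[i],
      depth = units$depth[i],
      volume_km3 = vol * ov[sel] / (base - top)
    )
  })
  if (nrow(parts) == 0L) {
    parts <- tibble::tibble(
      bin_older = numeric(), bin_younger = numeric(), bin_mid = numeric(),
      region = character(), group = character(), depth = character(),
      volume_km3 = numeric()
    )
  } else {
    parts <- parts |>
      dplyr::group_by(.data$bin_older, .data$bin_younger, .data$bin_mid,
                      .data$region, .data$group, .data$depth) |>
      dplyr::summarise(volume_km3 = sum(.data$volume_km3), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$bin_mid))
  }
  attr(parts, "grid") <- grid
  class(parts) <- c("flux_series", class(parts))
  parts
}

#' Total flux per bin
#'
#' Collapses a partitioned flux series to one row per bin, optionally after
#' restricting to a lithofacies subset. Bins with no contribution are
#' reported with zero volume (rock absent, not unknown).
#'
#' @param flux A `flux_series` from [compute_volume_flux()].
#' @param grid The grid used to build `flux` (defaults to its attribute).
#' @param groups,depths Optional lithofacies filters (character vectors).
#' @param regions Optional region filter.
#' @return A tibble with `bin_older`, `bin_younger`, `bin_mid`,
#'   `volume_km3`, old to young, one row per bin of the grid.
#' @export
flux_total <- function(flux, grid = attr(flux, "grid"), groups = NULL,
                       depths = NULL, regions = NULL) {
  bins <- build_flux_bins(grid)
  x <- flux
  if (!is.null(groups)) x <- dplyr::filter(x, .data$group %in% groups)
  if (!is.null(depths)) x <- dplyr::filter(x, .data$depth %in% depths)
  if (!is.null(regions)) x <- dplyr::filter(x, .data$region %in% regions)
  tot <- x |>
    dplyr::group_by(.data$bin_mid) |>
    dplyr::summarise(volume_km3 = sum(.data$volume_km3), .groups = "drop")
  bins |>
    dplyr::left_join(tot, by = "bin_mid") |>
    dplyr::mutate(volume_km3 = dplyr::coalesce(.data$volume_km3, 0))
}

#' Lithofacies percentages of the marine nonevaporitic record
#'
#' Per-bin percentage of total marine nonevaporitic volume contributed by
#' each lithofacies (group x depth). Evaporitic and nonmarine classes are
#' excluded from numerator and denominator; bins whose denominator is zero
#' are missing, not zero.
#'
#' @inheritParams flux_total
#' @param universe Character vector of groups forming the denominator
#'   (default [marine_nonevaporitic_groups()]).
#' @return A tibble with `bin_mid`, `group`, `depth`, `volume_km3`, `pct`.
#' @export
lithofacies_percentages <- function(flux, grid = attr(flux, "grid"),
                                    universe = marine_nonevaporitic_groups()) {
  bins <- build_flux_bins(grid)
  x <- dplyr::filter(flux, .data$group %in% universe)
  cls <- x |>
    dplyr::group_by(.data$bin_mid, .data$group, .data$depth) |>
    dplyr::summarise(volume_km3 = sum(.data$volume_km3), .groups = "drop")
  tot <- cls |>
    dplyr::group_by(.data$bin_mid) |>
    dplyr::summarise(total = sum(.data$volume_km3), .groups = "drop")
  classes <- dplyr::distinct(cls, .data$group, .data$depth)
  tidyr::crossing(bins["bin_mid"], classes) |>
    dplyr::left_join(cls, by = c("bin_mid", "group", "depth")) |>
    dplyr::left_join(tot, by = "bin_mid") |>
    dplyr::mutate(
      volume_km3 = dplyr::coalesce(.data$volume_km3, 0),
      pct = dplyr::if_else(is.na(.data$total) | .data$total <= 0,
                           NA_real_, 100 * .data$volume_km3 / .data$total)
    ) |>
    dplyr::select(-"total") |>
    dplyr::arrange(dplyr::desc(.data$bin_mid), .data$group, .data$depth)
}

#' Marine depositional area and nondeposition fraction
#'
#' Per bin, the depositional area is the sum of terrane areas of regions
#' with at least one marine nonevaporitic unit overlapping the bin; the
#' nondeposition fraction is the complementary share of total terrane area
#' (hiatus or erosion).
#'
#' @param units A validated rock-unit tibble.
#' @param region_areas Named numeric vector (or tibble with `region`,
#'   `area_km2`) of constant terrane areas; every unit's region must appear.
#' @param grid A [time_grid()].
#' @param universe Marine groups counted as depositional cover.
#' @param depths Optional depth-class filter applied before counting cover
#'   (used for per-lithofacies area series).
#' @return A tibble of class `area_series` with `bin_older`, `bin_younger`,
#'   `bin_mid`, `area_km2`, `nondep_fraction`.
#' @export
compute_area_series <- function(units, region_areas, grid,
                                universe = marine_nonevaporitic_groups(),
                                depths = NULL) {
  if (is.data.frame(region_areas)) {
    region_areas <- setNames(region_areas$area_km2, region_areas$region)
  }
  unknown <- setdiff(unique(units$region), names(region_areas))
  if (length(unknown) > 0L) {
    abort(sprintf("unit references unknown region: %s",
                  paste(unknown, collapse = ", ")))
  }
  bins <- build_flux_bins(grid)
  marine <- dplyr::filter(units, .data$group %in% universe)
  if (!is.null(depths)) {
    marine <- dplyr::filter(marine, .data$depth %in% .env$depths)
  }
  total_area <- sum(region_areas)
  area <- purrr::map_dbl(seq_len(nrow(bins)), function(i) {
    ov <- pmin(marine$base_age, bins$bin_older[i]) -
      pmax(marine$top_age, bins$bin_younger[i])
    sum(region_areas[unique(marine$region[ov > 0])])
  })
  out <- bins |>
    dplyr::mutate(area_km2 = area,
                  nondep_fraction = (total_area - area) / total_area)
  attr(out, "grid") <- grid
  class(out) <- c("area_series", class(out))
  out
}

#' Scale a series to unit maximum
#'
#' Divides by the series maximum (ignoring missing values), as used to
#' overlay normalized volume flux and genus density. Missing values stay
#' missing.
#'
#' @param x A numeric vector with a positive maximum.
#' @return `x / max(x)`.
#' @export
#' @examples
#' normalize_to_unit_max(c(2, 4, NA))
normalize_to_unit_max <- function(x) {
  if (length(x) == 0L || all(is.na(x))) {
    abort("cannot normalize an empty or all-missing series")
  }
  m <- max(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    abort("series maximum must be positive to normalize")
  }
  x / m
}

#' Window-aggregated rock series for correlation
#'
#' Helper mapping the standard Table-1 predictors onto the moving-window
#' grid: total volume, deep siliciclastic volume, shallow/mid siliciclastic
#' volume, shallow/mid carbonate volume, and the corresponding areas.
#'
#' @param flux A `flux_series`.
#' @param units,region_areas When supplied, per-lithofacies and total area
#'   predictors are added via [compute_area_series()].
#' @param grid A [time_grid()].
#' @return A named list of window tibbles (`label`, `value`), one per
#'   predictor: `vol_all`, `vol_deep_silic`, `vol_shallow_mid_silic`,
#'   `vol_shallow_mid_carb`, and `area_*` counterparts when areas are
#'   available.
#' @export
window_rock_predictors <- function(flux, units = NULL, region_areas = NULL,
                                   grid = attr(flux, "grid")) {
  shallow_mid <- c("shallow_inner_shelf", "mid_outer_shelf_upper_slope")
  vol <- list(
    vol_all = flux_total(flux, grid, groups = marine_nonevaporitic_groups()),
    vol_deep_silic = flux_total(flux, grid, groups = "siliciclastic",
                                depths = "lower_slope_basinal"),
    vol_shallow_mid_silic = flux_total(flux, grid, groups = "siliciclastic",
                                       depths = shallow_mid),
    vol_shallow_mid_carb = flux_total(flux, grid,
                                      groups = c("limestone", "dolostone"),
                                      depths = shallow_mid)
  )
  out <- purrr::map(vol, aggregate_to_windows, grid = grid,
                    value = "volume_km3")
  if (!is.null(units) && !is.null(region_areas)) {
    ar <- list(
      area_all = compute_area_series(units, region_areas, grid),
      area_deep_silic = compute_area_series(
        units, region_areas, grid, universe = "siliciclastic",
        depths = "lower_slope_basinal"),
      area_shallow_mid_silic = compute_area_series(
        units, region_areas, grid, universe = "siliciclastic",
        depths = shallow_mid),
      area_shallow_mid_carb = compute_area_series(
        units, region_areas, grid, universe = c("limestone", "dolostone"),
        depths = shallow_mid)
    )
    out <- c(out, purrr::map(ar, aggregate_to_windows, grid = grid,
                             value = "area_km2"))
  }
  out
}
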