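#' Run the full analysis pipeline
#'
#' End-to-end convenience wrapper: rock volume/area flux on the fine grid,
#' replicate diversity under age-uncertainty resampling, sampling
#' intensity, genus density, and the correlation report, all on one shared
#' time grid.
#'
#' @param occurrences,units,surfaces Validated input tibbles (see
#'   [read_strat_table()]).
#' @param region_areas Named numeric vector or tibble (`region`,
#'   `area_km2`) of terrane areas.
#' @param geochem Optional validated geochem tibble; when supplied the
#'   carbon/uranium correlations are added.
#' @param grid A [time_grid()].
#' @param n_replicates Number of Monte Carlo range-resampling replicates.
#' @param master_seed Integer master seed for all resampling.
#' @param cutoff Pre/post partition age (Ma) for the correlation subsets.
#' @param k Smoothing window (samples) for the isotope pairing.
#' @return A list with `flux`, `area`, `diversity`, `intensity`,
#'   `genus_density`, `correlations`, and (with geochem) `geochem_cors`.
#' @export
run_pipeline <- function(occurrences, units, surfaces, region_areas,
                         geochem = NULL, grid = time_grid(),
                         n_replicates = 100L, master_seed = 1L,
                         cutoff = 535, k = 10L) {
  flux <- compute_volume_flux(units, grid)
  area <- compute_area_series(units, region_areas, grid)
  diversity <- replicate_diversity(occurrences, grid,
                                   n_replicates = n_replicates,
                                   master_seed = master_seed)
  intensity <- intensity_series(surfaces, grid)
  predictors <- window_rock_predictors(flux, units = units,
                                       region_areas = region_areas,
                                       grid = grid)
  correlations <- correlation_report(diversity, predictors,
                                     intensity = intensity, cutoff = cutoff)
  density <- genus_density(diversity, predictors$vol_all)
  out <- list(flux = flux, area = area, diversity = diversity,
              intensity = intensity, genus_density = density,
              correlations = correlations, grid = grid)
  if (!is.null(geochem)) {
    out$geochem_cors <- purrr::map_dfr(
      c("raw_paired", "moving_mean_vs_mean", "moving_mean_vs_min"),
      function(m) {
        res <- tryCatch({
          p <- pair_geochem(geochem, m, k = k)
          sc <- spearman_cor(p$x, p$y, mode = "raw", subset = m)
          fd <- spearman_cor(first_differences(p$x),
                             first_differences(p$y),
                             mode = "first_difference", subset = m)
          dplyr::bind_rows(tidy(sc), tidy(fd))
        }, error = function(e) tibble::tibble())
        res
      })
  }
  out
}
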