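# Sampling intensity: moving counts of fossiliferous beds / bedding-plane
# surfaces (or sites/sections where surfaces are unavailable). A surface is
# counted in every window intersecting its permitted age interval, so for
# poorly constrained surfaces the series is the total maximum possible
# sampling intensity across the host unit's duration.

#' Moving-window sampling-intensity series
#'
#' Counts, per moving window, the surfaces whose closed age interval
#' `(max_age, min_age)` intersects the window; point-aged surfaces count in
#' every window containing that age. Totals are broken down by age
#' constraint quality.
#'
#' @param surfaces A validated surfaces tibble.
#' @param grid A [time_grid()] (or window tibble).
#' @return A tibble of class `intensity_series` with `label`, `n_total`,
#'   `n_well_constrained`, `n_uncertain`.
#' @export
intensity_series <- function(surfaces, grid) {
  windows <- if (inherits(grid, "time_grid")) build_windows(grid) else grid
  well <- surfaces$constraint_quality == "well_constrained"
  count_in <- function(sel, i) {
    sum(surfaces$max_age[sel] >= windows$younger[i] &
          surfaces$min_age[sel] <= windows$older[i])
  }
  out <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    tibble::tibble(
      label = windows$label[i],
      n_well_constrained = count_in(well, i),
      n_uncertain = count_in(!well, i)
    )
  }) |>
    dplyr::mutate(n_total = .data$n_well_constrained + .data$n_uncertain,
                  .after = "label")
  class(out) <- c("intensity_series", class(out))
  out
}

#' Derive a surfaces table from occurrence records
#'
#' Builds one sampling surface per occurrence record, using the sampling
#' filter set: trace-fossil-only records are excluded, but body-fossil
#' records removed from diversity estimation on taxonomic grounds
#' (holdfast-only, flagged taxa, lagerstatten) are retained. Records with
#' uncertainty category 1-2 are labelled well constrained.
#'
#' @param occurrences A validated occurrence tibble.
#' @return A validated surfaces tibble.
#' @export
surfaces_from_occurrences <- function(occurrences) {
  x <- dplyr::filter(occurrences, .data$record_class != "trace")
  validate_strat_table(tibble::tibble(
    surface_id = sprintf("occ_surf_%05d", seq_len(nrow(x))),
    region = x$region,
    max_age = x$max_age,
    min_age = x$min_age,
    constraint_quality = ifelse(x$uncertainty_category <= 2L,
                                "well_constrained", "uncertain")
  ), "surfaces")
}
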