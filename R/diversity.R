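# Moving-window diversity dynamics from realized range sets: range-through
# richness, Foote boundary-crosser bookkeeping (N_bt/N_bL/N_Ft/N_FL), and
# per-capita origination/extinction rates
#   p = ln((N_bt + N_Ft)/N_bt)/dt,  q = ln((N_bt + N_bL)/N_bt)/dt,
# undefined (missing) when no taxon ranges through the window.
#
# Edge rules, used consistently by richness and counts: a range [lad, fad]
# intersects a window (older o, younger y) iff fad >= y and lad <= o; it
# crosses the older edge iff fad >= o and lad < o, and the younger edge iff
# lad <= y and fad > y.

#' Range-through richness per moving window
#'
#' Counts, in every window, the taxa whose closed realized range
#' `[lad, fad]` intersects the window.
#'
#' @param ranges A tibble with `fad` and `lad` columns (one row per taxon),
#'   e.g. from [realize_ranges()].
#' @param windows A window tibble from [build_windows()].
#' @return A tibble with `label` and `richness`.
#' @export
richness_per_window <- function(ranges, windows) {
  hit <- outer(ranges$fad, windows$younger, ">=") &
    outer(ranges$lad, windows$older, "<=")
  tibble::tibble(label = windows$label, richness = as.integer(colSums(hit)))
}

#' Boundary-crosser counts for one window
#'
#' Classifies every taxon intersecting the window into the four
#' boundary-crosser categories underlying per-capita turnover rates:
#' `N_bt` (crosses both edges), `N_bL` (bottom/older edge only), `N_Ft`
#' (top/younger edge only), `N_FL` (confined to the window).
#'
#' @inheritParams richness_per_window
#' @param window A one-row window (list or tibble row) with `older` and
#'   `younger` edges, `older > younger`.
#' @return A named list with `N_bt`, `N_bL`, `N_Ft`, `N_FL`; their sum is
#'   the window richness.
#' @export
boundary_crossers <- function(ranges, window) {
  o <- window$older; y <- window$younger
  cross_b <- ranges$fad >= o & ranges$lad < o
  cross_t <- ranges$lad <= y & ranges$fad > y
  inter <- ranges$fad >= y & ranges$lad <= o
  list(
    N_bt = sum(cross_b & cross_t),
    N_bL = sum(cross_b & !cross_t),
    N_Ft = sum(!cross_b & cross_t),
    N_FL = sum(inter & !cross_b & !cross_t)
  )
}

# vectorized over windows: taxa x windows comparison matrices
bin_counts_series <- function(ranges, windows) {
  o <- windows$older; y <- windows$younger
  fad <- ranges$fad; lad <- ranges$lad
  cb <- outer(fad, o, ">=") & outer(lad, o, "<")
  ct <- outer(lad, y, "<=") & outer(fad, y, ">")
  inter <- outer(fad, y, ">=") & outer(lad, o, "<=")
  tibble::tibble(
    label = windows$label,
    N_bt = as.integer(colSums(cb & ct)),
    N_bL = as.integer(colSums(cb & !ct)),
    N_Ft = as.integer(colSums(!cb & ct)),
    N_FL = as.integer(colSums(inter & !cb & !ct))
  )
}

#' Foote per-capita origination and extinction rates
#'
#' `p = ln((N_bt + N_Ft)/N_bt)/dt` and `q = ln((N_bt + N_bL)/N_bt)/dt`,
#' in per-Ma units. Both rates are missing (not zero, not an error) when no
#' taxon ranges completely through the window (`N_bt = 0`).
#'
#' @param counts Boundary-crosser counts: a list or data frame with
#'   `N_bt`, `N_bL`, `N_Ft` (vectors allowed).
#' @param dt Window span in Ma.
#' @return A list with numeric `p` and `q`.
#' @export
#' @examples
#' foote_rates(list(N_bt = 4, N_bL = 1, N_Ft = 0), dt = 1)  # q = log(1.25)
foote_rates <- function(counts, dt) {
  if (any(dt <= 0)) abort("dt must be positive")
  nbt <- counts$N_bt
  p <- ifelse(nbt > 0, log((nbt + counts$N_Ft) / nbt) / dt, NA_real_)
  q <- ifelse(nbt > 0, log((nbt + counts$N_bL) / nbt) / dt, NA_real_)
  list(p = as.numeric(p), q = as.numeric(q))
}

#' Full diversity series for one realized range set
#'
#' Richness, boundary-crosser counts, and Foote rates on every moving
#' window, with the young-end truncations applied: extinction rates are not
#' reported younger than `extinction_truncation` and richness not younger
#' than `richness_truncation` (the compilation cannot constrain last
#' appearances near its young edge).
#'
#' @inheritParams richness_per_window
#' @param grid A [time_grid()] (or prebuilt window tibble).
#' @param richness_truncation,extinction_truncation Youngest window labels
#'   (Ma) for which richness / extinction are reported; defaults 522 / 530.
#' @return A tibble with `label`, `richness`, `N_bt`, `N_bL`, `N_Ft`,
#'   `N_FL`, `p`, `q`, ordered old to young.
#' @export
diversity_series <- function(ranges, grid, richness_truncation = 522,
                             extinction_truncation = 530) {
  windows <- if (inherits(grid, "time_grid")) build_windows(grid) else grid
  dt <- windows$older - windows$younger
  counts <- bin_counts_series(ranges, windows)
  rates <- foote_rates(counts, dt)
  out <- counts |>
    dplyr::mutate(
      richness = .data$N_bt + .data$N_bL + .data$N_Ft + .data$N_FL,
      p = rates$p, q = rates$q
    ) |>
    dplyr::mutate(
      q = dplyr::if_else(.data$label < extinction_truncation, NA_real_,
                         .data$q),
      richness = dplyr::if_else(.data$label < richness_truncation,
                                NA_real_, as.numeric(.data$richness))
    ) |>
    dplyr::select("label", "richness", "N_bt", "N_bL", "N_Ft", "N_FL",
                  "p", "q")
  out
}

na_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
na_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
na_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

#' Aggregate diversity series across replicates
#'
#' Element-wise mean, minimum and maximum of richness and turnover rates
#' across replicate datasets. Missing values are ignored pairwise; a window
#' missing in every replicate stays missing.
#'
#' @param series_list A list of diversity series (from [diversity_series()])
#'   on identical window grids.
#' @return A tibble of class `replicate_summary` with `label` and
#'   `<stat>_mean`, `<stat>_min`, `<stat>_max` for `richness`, `p`, `q`.
#' @export
aggregate_replicates <- function(series_list) {
  if (length(series_list) < 1L) abort("need at least one replicate")
  labs <- series_list[[1L]]$label
  ok <- purrr::every(series_list, function(s) identical(s$label, labs))
  if (!ok) abort("replicates are on mismatched window grids")
  long <- dplyr::bind_rows(series_list)
  out <- long |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(
      c("richness", "p", "q"),
      list(mean = na_mean, min = na_min, max = na_max)
    ), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$label))
  class(out) <- c("replicate_summary", class(out))
  out
}

#' Replicate diversity pipeline
#'
#' Convenience wrapper: filter occurrences, generate replicate range sets,
#' compute each diversity series, and aggregate. This is the per-dataset
#' path used by the study-scale analysis with 10,000 replicates; tests and
#' examples use on the order of 100.
#'
#' @inheritParams generate_replicates
#' @inheritParams diversity_series
#' @param filter Logical; apply [filter_occurrences()] first (default TRUE).
#' @return A `replicate_summary` tibble (see [aggregate_replicates()]).
#' @export
replicate_diversity <- function(occurrences, grid, n_replicates = 100L,
                                master_seed = 1L, filter = TRUE,
                                richness_truncation = 522,
                                extinction_truncation = 530) {
  if (filter) occurrences <- filter_occurrences(occurrences)
  windows <- build_windows(grid)
  reps <- generate_replicates(occurrences, n_replicates, master_seed)
  series <- purrr::map(reps, diversity_series, grid = windows,
                       richness_truncation = richness_truncation,
                       extinction_truncation = extinction_truncation)
  aggregate_replicates(series)
}

#' Genus density relative to rock quantity
#'
#' Divides per-window richness by a window-aggregated rock quantity (volume
#' flux or area), the normalization used to compare biodiversity against
#' the record of its hosting lithology. Windows with zero or missing rock
#' quantity are missing and are excluded from the unit-max normalization.
#'
#' @param richness A tibble with `label` and a richness column (e.g.
#'   `richness` or `richness_mean`).
#' @param rock A window tibble with `label` and `value` (from
#'   [aggregate_to_windows()]).
#' @param richness_col Name of the richness column (default picks
#'   `richness_mean` if present, else `richness`).
#' @param normalize Rescale the density to unit maximum (default TRUE, as
#'   plotted).
#' @return A tibble with `label` and `density`.
#' @export
genus_density <- function(richness, rock, richness_col = NULL,
                          normalize = TRUE) {
  richness_col <- richness_col %||%
    (if ("richness_mean" %in% names(richness)) "richness_mean" else "richness")
  if (!identical(sort(richness$label), sort(rock$label))) {
    abort("richness and rock series are on different window grids")
  }
  x <- dplyr::inner_join(richness[, c("label", richness_col)], rock,
                         by = "label")
  dens <- ifelse(!is.na(x$value) & x$value > 0,
                 x[[richness_col]] / x$value, NA_real_)
  if (normalize) dens <- normalize_to_unit_max(dens)
  tibble::tibble(label = x$label, density = dens)
}
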