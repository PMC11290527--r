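# ggplot2 figures for the main result types. Age axes are reversed so time
# runs left (old) to right (young).

age_axis <- function() ggplot2::scale_x_reverse(name = "Age (Ma)")

#' Plot a volume-flux series
#'
#' Stacked per-bin volume flux coloured by lithofacies group.
#'
#' @param flux A `flux_series` from [compute_volume_flux()].
#' @return A ggplot object.
#' @export
plot_flux <- function(flux) {
  x <- flux |>
    dplyr::group_by(.data$bin_mid, .data$group) |>
    dplyr::summarise(volume_km3 = sum(.data$volume_km3), .groups = "drop")
  ggplot2::ggplot(x, ggplot2::aes(.data$bin_mid, .data$volume_km3,
                                  fill = .data$group)) +
    ggplot2::geom_col(width = attr(flux, "grid")$flux_bin) +
    age_axis() +
    ggplot2::labs(y = expression(Volume~flux~(km^3/bin)), fill = "Lithofacies") +
    ggplot2::theme_minimal()
}

#' @rdname plot_flux
#' @param object,... Passed from the autoplot generic.
#' @export
autoplot.flux_series <- function(object, ...) plot_flux(object)

#' Plot depositional area and nondeposition fraction
#'
#' @param area An `area_series` from [compute_area_series()].
#' @return A ggplot object (nondeposition fraction through time).
#' @export
plot_area <- function(area) {
  ggplot2::ggplot(area, ggplot2::aes(.data$bin_mid, .data$nondep_fraction)) +
    ggplot2::geom_line(colour = "grey30") +
    age_axis() +
    ggplot2::scale_y_continuous("Nondeposition fraction", limits = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_area
#' @param object,... Passed from the autoplot generic.
#' @export
autoplot.area_series <- function(object, ...) plot_area(object)

#' Plot a replicate diversity summary
#'
#' Mean richness with the across-replicate min-max envelope.
#'
#' @param summary A `replicate_summary` from [aggregate_replicates()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$richness_min,
                                      ymax = .data$richness_max),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$richness_mean),
                       colour = "steelblue4") +
    age_axis() +
    ggplot2::labs(y = "Genus richness") +
    ggplot2::theme_minimal()
}

#' @rdname plot_diversity
#' @param object,... Passed from the autoplot generic.
#' @export
autoplot.replicate_summary <- function(object, ...) plot_diversity(object)

#' Plot a sampling-intensity series
#'
#' @param intensity An `intensity_series`.
#' @return A ggplot object, stacked by constraint quality.
#' @export
plot_intensity <- function(intensity) {
  x <- intensity |>
    tidyr::pivot_longer(c("n_well_constrained", "n_uncertain"),
                        names_to = "quality", values_to = "n")
  ggplot2::ggplot(x, ggplot2::aes(.data$label, .data$n,
                                  fill = .data$quality)) +
    ggplot2::geom_area(position = "stack") +
    age_axis() +
    ggplot2::labs(y = "Surfaces per window", fill = "Age constraint") +
    ggplot2::theme_minimal()
}

#' @rdname plot_intensity
#' @param object,... Passed from the autoplot generic.
#' @export
autoplot.intensity_series <- function(object, ...) plot_intensity(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
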