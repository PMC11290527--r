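# Shared binning conventions: 1-Ma moving windows stepped every 100 ka for
# diversity/sampling/correlation, and 50-ka bins for rock flux. All edge
# arithmetic is done in integer deci-Ma (windows) or centi-Ma (flux bins) and
# divided once, so printed labels and edges are bit-exact.

#' Define the shared time grid
#'
#' A `time_grid` fixes the study span and both binning conventions used by
#' the pipeline: moving windows stepped every `step` Ma for diversity,
#' sampling-intensity and correlation series, and fine `flux_bin` bins for
#' rock volume/area flux.
#'
#' A window labelled `L` spans `L + 0.4` to `L - 0.5` Ma under the default
#' `"printed_example"` convention (so label 570.5 covers 570.9-570.0 Ma and
#' label 570.4 covers 570.8-569.9 Ma). The alternative `"symmetric_1ma"`
#' convention spans `L + 0.5` to `L - 0.5`.
#'
#' @param oldest,youngest Grid span in Ma (`oldest > youngest`).
#' @param window_convention `"printed_example"` (default, 0.9-Ma span) or
#'   `"symmetric_1ma"` (1.0-Ma span).
#' @param step Window label step in Ma (default 0.1).
#' @param flux_bin Flux bin width in Ma (default 0.05, i.e. 50 ka).
#' @return An object of class `time_grid`.
#' @export
#' @examples
#' g <- time_grid(580, 522)
#' head(build_windows(g))
time_grid <- function(oldest = 580, youngest = 522,
                      window_convention = c("printed_example", "symmetric_1ma"),
                      step = 0.1, flux_bin = 0.05) {
  window_convention <- match.arg(window_convention)
  if (!(oldest > youngest)) abort("oldest must exceed youngest")
  if (step <= 0 || flux_bin <= 0) abort("step and flux_bin must be positive")
  structure(
    list(oldest = oldest, youngest = youngest,
         window_convention = window_convention,
         step = step, flux_bin = flux_bin),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %g-%g Ma, %s windows every %g Ma, %g-Ma flux bins\n",
              x$oldest, x$youngest, x$window_convention, x$step, x$flux_bin))
  invisible(x)
}

#' Build the ordered moving-window list
#'
#' Windows are ordered old to young and labelled in Ma. Under the
#' `"printed_example"` convention the window labelled `L` spans
#' `(L + 0.4, L - 0.5)`; consecutive windows overlap by the span minus the
#' label step. Only windows fully inside the grid span are returned.
#'
#' @param grid A [time_grid()].
#' @return A tibble with columns `label`, `older`, `younger` (Ma), ordered
#'   old to young.
#' @export
build_windows <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  # integer deci-Ma to keep labels/edges exact
  od <- round(grid$oldest * 10)
  yd <- round(grid$youngest * 10)
  sd_ <- round(grid$step * 10)
  if (grid$window_convention == "printed_example") {
    up <- 4L; dn <- 5L
  } else {
    up <- 5L; dn <- 5L
  }
  first <- od - up          # oldest admissible label (deci-Ma)
  last <- yd + dn
  if (first < last) abort("grid span shorter than one window")
  labs <- seq(first, last, by = -sd_)
  tibble::tibble(
    label = labs / 10,
    older = (labs + up) / 10,
    younger = (labs - dn) / 10
  )
}

#' Build the fine flux-bin table
#'
#' Contiguous `flux_bin`-wide bins (default 50 ka) covering the grid span,
#' ordered old to young, as half-open intervals `[older, younger)`: a unit
#' boundary falling exactly on a bin edge contributes only to the older bin.
#'
#' @inheritParams build_windows
#' @return A tibble with columns `bin_older`, `bin_younger`, `bin_mid` (Ma).
#' @export
build_flux_bins <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  oc <- round(grid$oldest * 1000)
  yc <- round(grid$youngest * 1000)
  w <- round(grid$flux_bin * 1000)
  edges <- seq(oc, yc, by = -w)
  if (length(edges) < 2L) abort("grid span shorter than one flux bin")
  tibble::tibble(
    bin_older = edges[-length(edges)] / 1000,
    bin_younger = edges[-1L] / 1000,
    bin_mid = (edges[-length(edges)] + edges[-1L]) / 2000
  )
}

#' Aggregate a fine-binned series onto the moving windows
#'
#' Each moving window receives the mean (by default) of the fine-bin values
#' whose bin midpoints fall inside the window, mirroring how the
#' lithostratigraphic series are grouped and averaged across 1-Ma bins moved
#' in 100-ka increments. Windows containing no bin midpoint are missing.
#'
#' @param bins A tibble with a `bin_mid` column (from [build_flux_bins()] or
#'   a flux/area series) and the value column named by `value`.
#' @param grid A [time_grid()] (or a window tibble from [build_windows()]).
#' @param value Name of the value column to aggregate.
#' @param fun Aggregation function (default `mean`); missing bin values are
#'   removed before aggregation.
#' @return A tibble with columns `label` and `value`, ordered old to young.
#' @export
aggregate_to_windows <- function(bins, grid, value = "value", fun = mean) {
  windows <- if (inherits(grid, "time_grid")) build_windows(grid) else grid
  if (!value %in% names(bins)) abort(sprintf("column '%s' not found", value))
  v <- bins[[value]]
  mid <- bins$bin_mid
  out <- purrr::map_dbl(seq_len(nrow(windows)), function(i) {
    sel <- mid < windows$older[i] & mid > windows$younger[i]
    vv <- v[sel & !is.na(v)]
    if (length(vv) == 0L) NA_real_ else fun(vv)
  })
  tibble::tibble(label = windows$label, value = out)
}
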