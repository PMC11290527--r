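# Correlation suite: moving-window smoothing, first differences, Spearman
# rank correlation (average ranks, t-approximation p-values), window
# alignment, and the carbon/uranium isotope pairing conventions.

#' Moving-window statistic of an age-ordered series
#'
#' For every run of `k` consecutive samples (old to young), reports the
#' statistic of the values at the mean age of the run. The moving mean (and
#' moving minimum, used for the uranium series) smooths over the large
#' sampling gaps of sparse isotope records.
#'
#' @param values Numeric values, ordered old to young.
#' @param ages Sample ages (Ma), same order; defaults to the sample index.
#' @param k Window size in samples (`>= 1`).
#' @param stat `"mean"` or `"min"`.
#' @return A tibble with `age` (mean age of the run) and `value`; empty when
#'   fewer than `k` samples are supplied.
#' @export
#' @examples
#' moving_stat(c(3, 1, 2), k = 3, stat = "min")
moving_stat <- function(values, ages = seq_along(values), k,
                        stat = c("mean", "min")) {
  stat <- match.arg(stat)
  if (k < 1) abort("k must be >= 1")
  n <- length(values)
  if (n < k) return(tibble::tibble(age = numeric(), value = numeric()))
  f <- if (stat == "mean") mean else min
  tibble::tibble(
    age = zoo::rollapply(ages, k, mean, align = "left"),
    value = zoo::rollapply(values, k, f, align = "left")
  )
}

#' First differences of a window series
#'
#' `d_i = x_{i+1} - x_i` with the series ordered old to young; missing
#' values propagate into both adjacent differences. Used to suppress the
#' autocorrelation that moving-mean series inherit.
#'
#' @param x Numeric series of length `>= 2` on a uniform window grid.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
#' @examples
#' first_differences(c(1, 4, 9))
first_differences <- function(x) {
  if (length(x) < 2L) abort("need at least 2 values to difference")
  diff(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of average ranks (ties share
#' their mean rank) after pairwise deletion of incomplete pairs, with the
#' two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom -- the standard test for monotonic association between the
#' pipeline's series.
#'
#' @param x,y Paired numeric series.
#' @param mode Label stored in the result (`"raw"` or
#'   `"first_difference"`).
#' @param subset Free-text label of the data subset (e.g. `"pre-BACE
#'   (>535 Ma)"`).
#' @return An object of class `spearman_cor`: list with `rho`, `p_value`,
#'   `n`, `mode`, `subset`.
#' @export
#' @examples
#' spearman_cor(c(1, 2, 2, 3), c(1, 3, 2, 4))
spearman_cor <- function(x, y, mode = "raw", subset = "all") {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  sdx <- sd(rx); sdy <- sd(ry)
  if (sdx == 0 || sdy == 0) {
    abort("a series is constant after ranking; rho undefined")
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n, mode = mode,
                 subset = subset),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (%s, %s)\n", x$mode, x$subset))
  cat(sprintf("  rho = %.4f, p = %.4g, n = %d\n", x$rho, x$p_value, x$n))
  invisible(x)
}

#' @rdname spearman_cor
#' @param x A `spearman_cor` object.
#' @param ... Unused.
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(estimate = x$rho, p.value = x$p_value, n = x$n,
                 method = "spearman", mode = x$mode, subset = x$subset)
}

#' @rdname spearman_cor
#' @export
glance.spearman_cor <- function(x, ...) tidy(x)

#' Align two series on the shared moving-window grid
#'
#' Pairs two series by window label; a fine-binned rock series (with
#' `bin_mid`) is first averaged onto the windows via
#' [aggregate_to_windows()]. Unmatched labels are dropped.
#'
#' @param a,b Window tibbles with `label` and `value` columns, or (for `b`)
#'   a fine-binned series with `bin_mid` and the column named by
#'   `value_b`.
#' @param grid A [time_grid()], required when `b` must be aggregated.
#' @param value_a,value_b Value column names (default `"value"`).
#' @return A tibble with `label`, `x` (from `a`), `y` (from `b`).
#' @export
align_windows <- function(a, b, grid = NULL, value_a = "value",
                          value_b = "value") {
  if ("bin_mid" %in% names(b) && !"label" %in% names(b)) {
    if (is.null(grid)) abort("grid required to aggregate a binned series")
    b <- aggregate_to_windows(b, grid, value = value_b)
    value_b <- "value"
  }
  key_a <- round(a$label, 6)
  key_b <- round(b$label, 6)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0L) abort("series share no window labels")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  tibble::tibble(label = a$label[ia],
                 x = a[[value_a]][ia],
                 y = b[[value_b]][ib]) |>
    dplyr::arrange(dplyr::desc(.data$label))
}

#' Pair the carbon and uranium isotope series
#'
#' Three pairing conventions: `raw_paired` pairs the two isotopes measured
#' on the same samples; the moving modes smooth each isotope's own
#' age-ordered series over `k` samples (moving mean for carbon; moving mean
#' or moving minimum for uranium) and pair smoothed points by nearest
#' smoothed age within `max_gap`.
#'
#' @param samples A validated geochem tibble.
#' @param mode `"raw_paired"`, `"moving_mean_vs_mean"`, or
#'   `"moving_mean_vs_min"`.
#' @param k Smoothing window in samples (default 10).
#' @param max_gap Maximum age gap (Ma) for nearest-age pairing of smoothed
#'   series (default 0.5).
#' @return A tibble with `age`, `x` (carbon), `y` (uranium).
#' @export
pair_geochem <- function(samples,
                         mode = c("raw_paired", "moving_mean_vs_mean",
                                  "moving_mean_vs_min"),
                         k = 10L, max_gap = 0.5) {
  mode <- match.arg(mode)
  if (mode == "raw_paired") {
    s <- dplyr::filter(samples, .data$paired, !is.na(.data$d13C),
                       !is.na(.data$d238U))
    if (nrow(s) == 0L) abort("no paired samples available")
    return(tibble::tibble(age = s$age, x = s$d13C, y = s$d238U))
  }
  cs <- samples |>
    dplyr::filter(!is.na(.data$d13C)) |>
    dplyr::arrange(dplyr::desc(.data$age))
  us <- samples |>
    dplyr::filter(!is.na(.data$d238U)) |>
    dplyr::arrange(dplyr::desc(.data$age))
  if (nrow(cs) < k || nrow(us) < k) {
    abort("smoothing window k exceeds the length of an isotope series")
  }
  sm_c <- moving_stat(cs$d13C, cs$age, k, "mean")
  sm_u <- moving_stat(us$d238U, us$age, k,
                      if (mode == "moving_mean_vs_min") "min" else "mean")
  idx <- purrr::map_int(sm_c$age, function(a) which.min(abs(sm_u$age - a)))
  gap <- abs(sm_u$age[idx] - sm_c$age)
  keep <- gap <= max_gap
  if (!any(keep)) abort("no smoothed pairs within max_gap")
  tibble::tibble(age = sm_c$age[keep], x = sm_c$value[keep],
                 y = sm_u$value[idx][keep])
}

#' Table-style correlation report
#'
#' Runs the Spearman test of mean richness against each rock-record
#' predictor (and optionally sampling intensity), on raw series and first
#' differences, over the full span and the pre/post age-cutoff partitions.
#' One row per (predictor, subset, mode), mirroring the shape of the
#' published correlation table.
#'
#' @param richness A window tibble with `label` and a richness column
#'   (`richness_mean` preferred).
#' @param predictors Named list of window tibbles (`label`, `value`), e.g.
#'   from [window_rock_predictors()].
#' @param intensity Optional [intensity_series()] tibble; tested raw only
#'   (first differences of maximum-possible counts are uninformative).
#' @param cutoff Age cutoff (Ma) splitting pre/post subsets; the window
#'   whose label equals the cutoff falls on the older side. Use `NULL` to
#'   skip the partitions.
#' @param subset_label Label prefix recorded for the full-span rows.
#' @return A tibble with `predictor`, `subset`, `mode`, `rho`, `p_value`,
#'   `n`.
#' @export
correlation_report <- function(richness, predictors, intensity = NULL,
                               cutoff = 535, subset_label = "all") {
  rcol <- if ("richness_mean" %in% names(richness)) "richness_mean" else
    "richness"
  rich <- tibble::tibble(label = richness$label,
                         value = richness[[rcol]])
  subsets <- list()
  subsets[[subset_label]] <- function(x) x
  if (!is.null(cutoff)) {
    subsets[[sprintf("pre (>%g Ma)", cutoff)]] <- function(x) {
      partition_by_age(x, cutoff, "label")$older
    }
    subsets[[sprintf("post (<%g Ma)", cutoff)]] <- function(x) {
      partition_by_age(x, cutoff, "label")$younger
    }
  }
  test_pair <- function(paired, mode, pred_name, sub_name) {
    res <- tryCatch({
      if (mode == "first_difference") {
        sc <- spearman_cor(first_differences(paired$x),
                           first_differences(paired$y),
                           mode = mode, subset = sub_name)
      } else {
        sc <- spearman_cor(paired$x, paired$y, mode = mode,
                           subset = sub_name)
      }
      tibble::tibble(predictor = pred_name, subset = sub_name,
                     mode = mode, rho = sc$rho, p_value = sc$p_value,
                     n = sc$n)
    }, error = function(e) {
      tibble::tibble(predictor = pred_name, subset = sub_name,
                     mode = mode, rho = NA_real_, p_value = NA_real_,
                     n = NA_integer_)
    })
    res
  }
  rows <- purrr::map_dfr(names(predictors), function(pn) {
    purrr::map_dfr(names(subsets), function(sn) {
      paired <- align_windows(rich, predictors[[pn]]) |>
        subsets[[sn]]()
      dplyr::bind_rows(
        test_pair(paired, "raw", pn, sn),
        test_pair(paired, "first_difference", pn, sn)
      )
    })
  })
  if (!is.null(intensity)) {
    ints <- tibble::tibble(label = intensity$label,
                           value = as.numeric(intensity$n_total))
    rows <- dplyr::bind_rows(
      purrr::map_dfr(names(subsets), function(sn) {
        paired <- align_windows(rich, ints) |> subsets[[sn]]()
        test_pair(paired, "raw", "sampling_intensity", sn)
      }),
      rows
    )
  }
  rows
}
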