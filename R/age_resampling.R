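# Monte Carlo realization of taxon ranges under the four-category
# age-uncertainty scheme. Category-1 records enter with their full calibrated
# range; categories 2-4 each contribute one age drawn uniformly from the
# permitted interval, and a taxon's realized range is the envelope of its
# records' contributions.

#' Filter occurrences for diversity estimation
#'
#' Applies the exclusions used before range resampling: trace fossils,
#' records identified solely as holdfasts, taxa flagged as excluded on
#' taxonomic grounds, and lagerstatte records. Each exclusion is a separate
#' toggle because the sampling-intensity series uses a different filter set
#' (see [surfaces_from_occurrences()]).
#'
#' @param occurrences A validated occurrence tibble.
#' @param exclude_trace,exclude_holdfasts,exclude_flagged,exclude_lagerstatten
#'   Logical toggles, all `TRUE` by default.
#' @return The filtered occurrence tibble.
#' @export
filter_occurrences <- function(occurrences, exclude_trace = TRUE,
                               exclude_holdfasts = TRUE,
                               exclude_flagged = TRUE,
                               exclude_lagerstatten = TRUE) {
  x <- occurrences
  if (exclude_trace) x <- dplyr::filter(x, .data$record_class != "trace")
  if (exclude_holdfasts) {
    x <- dplyr::filter(x, .data$record_class != "holdfast_only")
  }
  if (exclude_flagged) {
    x <- dplyr::filter(x, .data$record_class != "excluded_taxon")
  }
  if (exclude_lagerstatten) x <- dplyr::filter(x, !.data$lagerstatte)
  x
}

#' Realize one set of taxon ranges under age uncertainty
#'
#' Category-1 records contribute both their bounds (the full calibrated
#' range); records in categories 2-4 contribute a single age drawn uniformly
#' from their permitted `(min_age, max_age)` interval. Each taxon's realized
#' first/last appearance is the envelope (oldest, youngest) of its records'
#' contributions. Deterministic under `seed`.
#'
#' @param occurrences A filtered occurrence tibble (see
#'   [filter_occurrences()]).
#' @param seed Integer seed for the draws.
#' @param replicate_id Integer identifier stored in the result.
#' @return A tibble with `replicate_id`, `genus`, `fad`, `lad`
#'   (`fad >= lad`), one row per taxon.
#' @export
realize_ranges <- function(occurrences, seed, replicate_id = 1L) {
  if (nrow(occurrences) == 0L) {
    return(tibble::tibble(replicate_id = integer(), genus = character(),
                          fad = numeric(), lad = numeric()))
  }
  withr::with_seed(as.integer(seed), {
    certain <- occurrences$uncertainty_category == 1L
    drawn_age <- numeric(nrow(occurrences))
    drawn_age[!certain] <- runif(sum(!certain),
                                 occurrences$min_age[!certain],
                                 occurrences$max_age[!certain])
    contrib <- dplyr::bind_rows(
      tibble::tibble(genus = occurrences$genus[certain],
                     age = occurrences$max_age[certain]),
      tibble::tibble(genus = occurrences$genus[certain],
                     age = occurrences$min_age[certain]),
      tibble::tibble(genus = occurrences$genus[!certain],
                     age = drawn_age[!certain])
    )
    contrib |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(fad = max(.data$age), lad = min(.data$age),
                       .groups = "drop") |>
      dplyr::mutate(replicate_id = as.integer(replicate_id),
                    .before = 1L)
  })
}

#' Generate replicate range sets
#'
#' Draws `n_replicates` independent realizations of the taxon ranges; each
#' replicate uses its own seed derived from `master_seed` by an explicit
#' stream split, so the whole sequence is reproducible and replicates are
#' mutually independent.
#'
#' @inheritParams realize_ranges
#' @param n_replicates Number of replicate datasets (the study-scale run
#'   uses 10,000; tests and examples use far fewer).
#' @param master_seed Integer master seed.
#' @return A list of realized-range tibbles with `replicate_id` 1..n.
#' @export
generate_replicates <- function(occurrences, n_replicates, master_seed) {
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("n_replicates must be >= 1")
  }
  n_replicates <- as.integer(n_replicates)
  seeds <- derive_seeds(master_seed, n_replicates)
  purrr::map(seq_len(n_replicates),
             function(i) realize_ranges(occurrences, seeds[i], i))
}

#' Randomly subsample taxa
#'
#' Draws datasets each containing a fixed fraction of all taxa, without
#' replacement within a dataset, to probe the robustness of diversity
#' trends to incomplete sampling (default: three datasets of one third of
#' the taxa each).
#'
#' @inheritParams realize_ranges
#' @param fraction Fraction of taxa per dataset, in `(0, 1]`.
#' @param n_datasets Number of subsampled datasets.
#' @param seed Integer seed.
#' @return A list of occurrence tibbles, each restricted to
#'   `round(fraction * n_taxa)` distinct taxa.
#' @export
subsample_taxa <- function(occurrences, fraction = 1 / 3, n_datasets = 3L,
                           seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]")
  }
  taxa <- unique(occurrences$genus)
  size <- round(fraction * length(taxa))
  seeds <- derive_seeds(seed, n_datasets)
  purrr::map(seq_len(n_datasets), function(i) {
    keep <- withr::with_seed(seeds[i], sample(taxa, size))
    dplyr::filter(occurrences, .data$genus %in% keep)
  })
}
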