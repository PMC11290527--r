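# Controlled vocabularies for the four input schemas -------------------------

#' Controlled vocabularies used by the input schemas
#'
#' Token sets accepted by [read_strat_table()] and produced by the synthetic
#' generator: lithological affinities of fossil occurrences, assemblage
#' (paleocommunity) labels, occurrence record classes, lithofacies groups and
#' depth classes of rock units.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
lithology_affinities <- c(
  "shallow_mid_siliciclastic", "deep_siliciclastic",
  "shallow_mid_limestone", "shallow_mid_dolostone"
)

#' @rdname vocabularies
#' @export
assemblage_labels <- c("Avalon", "WhiteSea", "Nama", "Cambrian")

#' @rdname vocabularies
#' @export
record_classes <- c("body", "trace", "holdfast_only", "excluded_taxon")

#' @rdname vocabularies
#' @export
lithofacies_groups <- c(
  "siliciclastic", "limestone", "dolostone", "phosphorite", "diamictite",
  "evaporitic_semirestricted", "fluvial_subaerial", "volcanic"
)

#' @rdname vocabularies
#' @export
depth_classes <- c(
  "shallow_inner_shelf", "mid_outer_shelf_upper_slope",
  "lower_slope_basinal", "not_applicable"
)

# groups counted as marine; evaporitic/semirestricted settings are kept
# separate because the flux percentage universe is "nonevaporitic marine"
marine_groups <- c(
  "siliciclastic", "limestone", "dolostone", "phosphorite", "diamictite"
)

# groups that carry a meaningful depth class
depth_bearing_groups <- c("siliciclastic", "limestone", "dolostone")

#' Is a lithofacies group marine?
#'
#' @param group Character vector of lithofacies group tokens.
#' @return Logical vector, `TRUE` for marine groups (siliciclastic,
#'   limestone, dolostone, phosphorite, diamictite).
#' @export
is_marine_group <- function(group) group %in% marine_groups

#' Default "marine nonevaporitic" lithofacies universe
#'
#' The denominator universe for lithofacies percentages and depositional-area
#' bookkeeping. Phosphorite and diamictite are included by default; pass a
#' restricted vector to the relevant functions to exclude them.
#'
#' @return Character vector of group tokens.
#' @export
marine_nonevaporitic_groups <- function() marine_groups

# Schema definitions ----------------------------------------------------------

schema_defs <- list(
  occurrences = list(
    required = c("genus", "region", "max_age", "min_age",
                 "uncertainty_category", "lithology_affinity", "assemblage",
                 "record_class", "lagerstatte"),
    numeric = c("max_age", "min_age"),
    integer = "uncertainty_category",
    logical = "lagerstatte"
  ),
  rock_units = list(
    required = c("region", "unit_id", "group", "depth", "mean_thickness",
                 "area", "base_age", "top_age"),
    numeric = c("mean_thickness", "area", "base_age", "top_age"),
    integer = character(), logical = character()
  ),
  surfaces = list(
    required = c("surface_id", "region", "max_age", "min_age",
                 "constraint_quality"),
    numeric = c("max_age", "min_age"),
    integer = character(), logical = character()
  ),
  geochem = list(
    required = c("age", "d13C", "d238U", "provenance", "paired"),
    numeric = c("age", "d13C", "d238U"),
    integer = character(), logical = "paired"
  )
)

strat_schemas <- function() names(schema_defs)

fail_rows <- function(what, idx) {
  abort(sprintf("%s (rows: %s)", what,
                paste(head(idx, 5L), collapse = ", ")),
        class = "stratodyn_validation_error")
}

check_tokens <- function(x, col, allowed, allow_na = FALSE) {
  bad <- which(!(x %in% allowed | (allow_na & is.na(x))))
  if (length(bad) > 0L) {
    fail_rows(sprintf("unknown %s token '%s'", col, x[bad[1L]]), bad)
  }
  invisible(TRUE)
}

#' Validate a table against one of the input schemas
#'
#' Checks required columns, coerces column types, and enforces the schema's
#' invariants (age ordering, positive ages, category and vocabulary tokens).
#' Called by [read_strat_table()]; exported so that programmatically built
#' tables can be checked the same way.
#'
#' @param x A data frame.
#' @param schema One of `"occurrences"`, `"rock_units"`, `"surfaces"`,
#'   `"geochem"`.
#' @return The validated tibble (invisibly classed by schema via attribute
#'   `strat_schema`).
#' @export
validate_strat_table <- function(x, schema = strat_schemas()) {
  schema <- match.arg(schema)
  def <- schema_defs[[schema]]
  missing_cols <- setdiff(def$required, names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf("schema '%s': missing required column '%s'",
                  schema, missing_cols[1L]),
          class = "stratodyn_schema_error")
  }
  x <- tibble::as_tibble(x)
  for (col in def$numeric) x[[col]] <- as.numeric(x[[col]])
  for (col in def$integer) x[[col]] <- as.integer(x[[col]])
  for (col in def$logical) x[[col]] <- as.logical(x[[col]])

  if (schema == "occurrences") {
    bad <- which(!(x$max_age >= x$min_age) | !(x$min_age > 0))
    if (length(bad)) fail_rows("occurrence with max_age < min_age or non-positive age", bad)
    bad <- which(!(x$uncertainty_category %in% 1:4))
    if (length(bad)) fail_rows("uncertainty_category outside {1,2,3,4}", bad)
    check_tokens(x$lithology_affinity, "lithology_affinity", lithology_affinities)
    check_tokens(x$assemblage, "assemblage", assemblage_labels)
    check_tokens(x$record_class, "record_class", record_classes)
  } else if (schema == "rock_units") {
    bad <- which(!(x$base_age > x$top_age))
    if (length(bad)) fail_rows("rock unit with base_age <= top_age", bad)
    bad <- which(!(x$mean_thickness >= 0) | !(x$area > 0))
    if (length(bad)) fail_rows("rock unit with negative thickness or non-positive area", bad)
    check_tokens(x$group, "group", lithofacies_groups)
    check_tokens(x$depth, "depth", depth_classes)
    bad <- which(!(x$group %in% depth_bearing_groups) &
                   x$depth != "not_applicable")
    if (length(bad)) fail_rows("depth class given for a group that takes none", bad)
  } else if (schema == "surfaces") {
    bad <- which(!(x$max_age >= x$min_age))
    if (length(bad)) fail_rows("surface with max_age < min_age", bad)
    check_tokens(x$constraint_quality, "constraint_quality",
                 c("well_constrained", "uncertain"))
  } else if (schema == "geochem") {
    bad <- which(is.na(x$d13C) & is.na(x$d238U))
    if (length(bad)) fail_rows("geochem sample with neither d13C nor d238U", bad)
  }
  attr(x, "strat_schema") <- schema
  x
}

#' Read a delimiter-separated input table
#'
#' Reads one of the four tidy input schemas (occurrences, rock units,
#' fossiliferous surfaces, geochemical samples) from a UTF-8 text file with a
#' header row. The delimiter (comma or tab) is auto-detected from the header
#' line; empty fields become missing values. All schema invariants are
#' enforced on read.
#'
#' @param path Path to the file.
#' @inheritParams validate_strat_table
#' @return A validated tibble, one row per record.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_strat_table(synthetic_dataset(synth_config(master_seed = 1))$geochem, f)
#' g <- read_strat_table(f, "geochem")
read_strat_table <- function(path, schema = strat_schemas()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                         show_col_types = FALSE, progress = FALSE)
  validate_strat_table(x, schema)
}

#' Write a table in the package's delimiter-separated exchange format
#'
#' @param x A data frame (typically one of the schema tables or a derived
#'   series).
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `x`, invisibly.
#' @export
write_strat_table <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(x)
}

# Age partition ---------------------------------------------------------------

#' Partition records or a series at an age cutoff
#'
#' Splits a table into an older and a younger part at `cutoff` (Ma). An
#' element whose age equals the cutoff goes to the older side, matching the
#' ">535 Ma" convention for pre-excursion subsets. For interval-valued
#' records, supply the label or midpoint column via `age_col`.
#'
#' @param x A data frame with an age (or window label) column.
#' @param cutoff Age cutoff in Ma.
#' @param age_col Name of the column holding the age or label used for
#'   assignment (default `"age"`; use `"label"` for window series).
#' @return A named list with tibbles `older` (age >= cutoff) and `younger`
#'   (age < cutoff); their union is the input and they are disjoint. Empty
#'   input yields two empty tibbles.
#' @export
#' @examples
#' partition_by_age(tibble::tibble(label = c(540, 535.1, 534.9)),
#'                  cutoff = 535, age_col = "label")
partition_by_age <- function(x, cutoff, age_col = "age") {
  if (!age_col %in% names(x)) {
    abort(sprintf("column '%s' not found", age_col))
  }
  a <- x[[age_col]]
  list(
    older = dplyr::filter(x, .data[[age_col]] >= cutoff),
    younger = dplyr::filter(x, .data[[age_col]] < cutoff)
  )
}

#' Remove one region from the compilation
#'
#' Leave-one-region-out sensitivity filter: drops every record belonging to
#' `region` from each supplied table and returns the rest unchanged, ready to
#' be fed back through the flux/diversity/correlation pipeline.
#'
#' @param units Rock-unit table (required; used to check the region exists).
#' @param occurrences,surfaces Optional occurrence / surface tables filtered
#'   the same way.
#' @param region Region identifier to remove.
#' @return A list with elements `units` and, when supplied, `occurrences` and
#'   `surfaces`.
#' @export
leave_region_out <- function(units, occurrences = NULL, surfaces = NULL,
                             region) {
  present <- unique(c(units$region, occurrences$region, surfaces$region))
  if (!region %in% present) {
    abort(sprintf("region '%s' not present in the data", region))
  }
  out <- list(units = dplyr::filter(units, .data$region != .env$region))
  if (!is.null(occurrences)) {
    out$occurrences <- dplyr::filter(occurrences, .data$region != .env$region)
  }
  if (!is.null(surfaces)) {
    out$surfaces <- dplyr::filter(surfaces, .data$region != .env$region)
  }
  out
}
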