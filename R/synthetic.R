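# Synthetic Ediacaran-Cambrian study system: taxon ranges in four successive
# assemblages with age-framework uncertainty, a regional rock record with
# hiatuses, fossiliferous surfaces, and anticorrelated d13C/d238U series.
# Every generator is deterministic under config$master_seed via an explicit
# stream-splitting scheme (see derive_seeds).

#' Configuration for the synthetic study system
#'
#' Collects every tunable of the generator with defaults that emulate the
#' statistical structure the pipeline assumes: four successive assemblages
#' (Avalon 575-559, White Sea 560-550, Nama 550.5-538, Cambrian 535-522 Ma),
#' a mixture of the four age-uncertainty categories with symmetric
#' half-widths (0, 0.5, 1.5, 3 Ma), regional rock stacks with hiatuses, and
#' smooth anticorrelated carbon/uranium isotope curves. All distributional
#' choices are stand-ins and deliberately configurable.
#'
#' @param n_taxa Named integer vector: body-fossil taxa per assemblage.
#' @param assemblage_windows Tibble with `assemblage`, `older`, `younger`.
#' @param category_mix Probabilities over uncertainty categories 1-4
#'   (must sum to 1).
#' @param category_halfwidth Half-widths (Ma) by which reported bounds widen
#'   the true range, per category; category 1 must be 0.
#' @param records_per_taxon_extra Mean of the Poisson number of extra
#'   occurrence records per taxon beyond the two endpoint-defining ones
#'   (each taxon has 2 + Poisson(this) records).
#' @param mean_duration Mean of the exponential true range duration (Ma),
#'   truncated to the assemblage window.
#' @param extra_taxon_fraction Fraction of additional non-body taxa (trace /
#'   holdfast-only / flagged-excluded records) generated per assemblage;
#'   these are outside the recovery truth set.
#' @param lagerstatte_fraction Fraction of extra Cambrian taxa flagged as
#'   lagerstatte records.
#' @param regions Tibble with `region` and `area_km2` (constant terrane
#'   area per region).
#' @param unit_duration_mean,hiatus_duration_mean Means (Ma) of exponential
#'   unit and hiatus durations in the regional stack walk.
#' @param hiatus_prob Probability that any step of the stack walk is a
#'   hiatus rather than a unit.
#' @param thickness_meanlog,thickness_sdlog Lognormal parameters of unit
#'   mean thickness (m).
#' @param facies_weights Named numeric vector of lithofacies draw weights;
#'   names are `"group.depth"` tokens.
#' @param n_geochem Number of geochemical samples.
#' @param geochem_span Older/younger bounds (Ma) of geochem sampling.
#' @param rho_target Target anticorrelation between the latent d13C and
#'   d238U curves, in `[-1, 0]`.
#' @param noise_sd_d13C,noise_sd_d238U Additive measurement noise SD (permil).
#' @param paired_fraction Fraction of samples carrying both isotopes.
#' @param n_surfaces Number of fossiliferous surfaces.
#' @param well_constrained_fraction Fraction of surfaces with narrow age
#'   brackets.
#' @param master_seed Integer master seed for all generator streams.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(
    n_taxa = c(Avalon = 40L, WhiteSea = 60L, Nama = 40L, Cambrian = 60L),
    assemblage_windows = tibble::tibble(
      assemblage = c("Avalon", "WhiteSea", "Nama", "Cambrian"),
      older = c(575, 560, 550.5, 535),
      younger = c(559, 550, 538, 522)
    ),
    category_mix = c(0.25, 0.35, 0.25, 0.15),
    category_halfwidth = c(0, 0.5, 1.5, 3.0),
    records_per_taxon_extra = 0,
    mean_duration = 3,
    extra_taxon_fraction = 0.15,
    lagerstatte_fraction = 0.3,
    regions = tibble::tibble(
      region = c("Avalonia", "Baltica", "Siberia", "SouthChina",
                 "Laurentia", "Australia", "Namibia", "Oman"),
      area_km2 = c(5e5, 4e5, 8e5, 6e5, 7e5, 5e5, 1.5e5, 1e5)
    ),
    unit_duration_mean = 2,
    hiatus_duration_mean = 1.5,
    hiatus_prob = 0.25,
    thickness_meanlog = log(150),
    thickness_sdlog = 0.5,
    facies_weights = c(
      "siliciclastic.shallow_inner_shelf" = 0.25,
      "siliciclastic.mid_outer_shelf_upper_slope" = 0.15,
      "siliciclastic.lower_slope_basinal" = 0.10,
      "limestone.shallow_inner_shelf" = 0.20,
      "limestone.mid_outer_shelf_upper_slope" = 0.05,
      "dolostone.shallow_inner_shelf" = 0.10,
      "phosphorite.not_applicable" = 0.03,
      "diamictite.not_applicable" = 0.02,
      "evaporitic_semirestricted.not_applicable" = 0.05,
      "fluvial_subaerial.not_applicable" = 0.04,
      "volcanic.not_applicable" = 0.01
    ),
    n_geochem = 400L,
    geochem_span = c(580, 510),
    rho_target = -0.7,
    noise_sd_d13C = 0.4,
    noise_sd_d238U = 0.04,
    paired_fraction = 0.5,
    n_surfaces = 300L,
    well_constrained_fraction = 0.6,
    master_seed = 1L) {
  cfg <- list(
    n_taxa = n_taxa, assemblage_windows = assemblage_windows,
    category_mix = category_mix, category_halfwidth = category_halfwidth,
    records_per_taxon_extra = records_per_taxon_extra,
    mean_duration = mean_duration,
    extra_taxon_fraction = extra_taxon_fraction,
    lagerstatte_fraction = lagerstatte_fraction,
    regions = regions,
    unit_duration_mean = unit_duration_mean,
    hiatus_duration_mean = hiatus_duration_mean,
    hiatus_prob = hiatus_prob,
    thickness_meanlog = thickness_meanlog,
    thickness_sdlog = thickness_sdlog,
    facies_weights = facies_weights,
    n_geochem = as.integer(n_geochem), geochem_span = geochem_span,
    rho_target = rho_target,
    noise_sd_d13C = noise_sd_d13C, noise_sd_d238U = noise_sd_d238U,
    paired_fraction = paired_fraction,
    n_surfaces = as.integer(n_surfaces),
    well_constrained_fraction = well_constrained_fraction,
    master_seed = as.integer(master_seed)
  )
  if (abs(sum(cfg$category_mix) - 1) > 1e-8) {
    abort("category_mix must sum to 1", class = "stratodyn_config_error")
  }
  if (any(cfg$category_halfwidth < 0) || cfg$category_halfwidth[1] != 0) {
    abort("category half-widths must be >= 0 with category 1 exact",
          class = "stratodyn_config_error")
  }
  if (cfg$rho_target < -1 || cfg$rho_target > 0) {
    abort("rho_target must lie in [-1, 0]", class = "stratodyn_config_error")
  }
  if (cfg$hiatus_prob < 0 || cfg$hiatus_prob > 1) {
    abort("hiatus_prob must lie in [0, 1]", class = "stratodyn_config_error")
  }
  if (!setequal(names(cfg$n_taxa), cfg$assemblage_windows$assemblage)) {
    abort("n_taxa names must match assemblage_windows",
          class = "stratodyn_config_error")
  }
  structure(cfg, class = "synth_config")
}

# Stream splitting: one substream seed per generator component, drawn from a
# generator keyed on the master seed alone, so each simulate_* is
# reproducible independently of call order.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

synth_streams <- function(cfg) {
  s <- derive_seeds(cfg$master_seed, 4L)
  list(occurrences = s[1L], rock = s[2L], geochem = s[3L], surfaces = s[4L])
}

# lithology affinity preferences per assemblage (deep-water Avalon, shallow
# siliciclastic White Sea, carbonate-dominated Nama and Cambrian)
affinity_weights <- list(
  Avalon = c(shallow_mid_siliciclastic = 0.25, deep_siliciclastic = 0.70,
             shallow_mid_limestone = 0.04, shallow_mid_dolostone = 0.01),
  WhiteSea = c(shallow_mid_siliciclastic = 0.85, deep_siliciclastic = 0.05,
               shallow_mid_limestone = 0.07, shallow_mid_dolostone = 0.03),
  Nama = c(shallow_mid_siliciclastic = 0.35, deep_siliciclastic = 0.02,
           shallow_mid_limestone = 0.43, shallow_mid_dolostone = 0.20),
  Cambrian = c(shallow_mid_siliciclastic = 0.30, deep_siliciclastic = 0.02,
               shallow_mid_limestone = 0.48, shallow_mid_dolostone = 0.20)
)

#' Simulate genus-level occurrence records with known truth
#'
#' Draws a true range for every body-fossil taxon (origin uniform in its
#' assemblage window; duration exponential, truncated to the window) and
#' emits several occurrence records per taxon, anchored at true occurrence
#' ages: the oldest and youngest occurrences sit at the range endpoints (as
#' the FAD/LAD-defining surfaces do in real compilations) and any extras
#' fall uniformly inside the range. Each record carries an uncertainty
#' category from the configured mixture. Category-1 records report the
#' exact calibrated range `(fad, lad)`; category 2-4 records report their
#' anchor age widened symmetrically by the category half-width, emulating
#' the age-framework uncertainty of the hosting surface. Additional taxa
#' with non-body record classes (trace, holdfast-only, flagged-excluded,
#' Cambrian lagerstatte) are generated outside the truth set to exercise
#' the diversity filters.
#'
#' @param config A [synth_config()].
#' @return A list with `occurrences` (validated occurrence tibble) and
#'   `truth` (list with `ranges` tibble of true `genus`, `assemblage`,
#'   `fad`, `lad`, plus the seeds used).
#' @export
simulate_occurrences <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seed <- synth_streams(config)$occurrences
  withr::with_seed(seed, {
    aw <- config$assemblage_windows
    taxa <- purrr::map_dfr(seq_len(nrow(aw)), function(i) {
      n <- config$n_taxa[[aw$assemblage[i]]]
      if (n == 0L) return(tibble::tibble())
      origin <- runif(n, aw$younger[i], aw$older[i])
      dur_cap <- origin - aw$younger[i]
      duration <- pmin(rexp(n, 1 / config$mean_duration), dur_cap)
      tibble::tibble(
        genus = sprintf("%s_g%03d", aw$assemblage[i], seq_len(n)),
        assemblage = aw$assemblage[i],
        fad = origin, lad = origin - duration
      )
    })
    truth <- list(ranges = taxa, seed = seed,
                  master_seed = config$master_seed)
    if (nrow(taxa) == 0L) {
      occ <- tibble::tibble(
        genus = character(), region = character(), max_age = numeric(),
        min_age = numeric(), uncertainty_category = integer(),
        lithology_affinity = character(), assemblage = character(),
        record_class = character(), lagerstatte = logical()
      )
      return(list(occurrences = validate_strat_table(occ, "occurrences"),
                  truth = truth))
    }
    regions <- config$regions$region
    hw <- config$category_halfwidth
    occ_body <- purrr::map_dfr(seq_len(nrow(taxa)), function(j) {
      k <- 2L + rpois(1L, config$records_per_taxon_extra)
      # oldest and youngest occurrences define the range endpoints
      anchor <- c(taxa$fad[j], taxa$lad[j],
                  if (k > 2L) runif(k - 2L, taxa$lad[j], taxa$fad[j]))
      cat_j <- sample(1:4, k, replace = TRUE, prob = config$category_mix)
      certain <- cat_j == 1L
      aff <- sample(names(affinity_weights[[taxa$assemblage[j]]]), 1L,
                    prob = affinity_weights[[taxa$assemblage[j]]])
      tibble::tibble(
        genus = taxa$genus[j],
        region = sample(regions, k, replace = TRUE),
        max_age = ifelse(certain, taxa$fad[j], anchor + hw[cat_j]),
        min_age = pmax(ifelse(certain, taxa$lad[j], anchor - hw[cat_j]),
                       1e-6),
        uncertainty_category = as.integer(cat_j),
        lithology_affinity = aff,
        assemblage = taxa$assemblage[j],
        record_class = "body",
        lagerstatte = FALSE
      )
    })
    # extra non-body taxa, outside the truth set
    occ_extra <- purrr::map_dfr(seq_len(nrow(aw)), function(i) {
      n <- max(0L, round(config$extra_taxon_fraction *
                           config$n_taxa[[aw$assemblage[i]]]))
      if (n == 0L) return(tibble::tibble())
      origin <- runif(n, aw$younger[i], aw$older[i])
      duration <- pmin(rexp(n, 1 / config$mean_duration),
                       origin - aw$younger[i])
      cls <- sample(c("trace", "holdfast_only", "excluded_taxon"), n,
                    replace = TRUE, prob = c(0.4, 0.35, 0.25))
      lag <- aw$assemblage[i] == "Cambrian" &
        runif(n) < config$lagerstatte_fraction
      cat_i <- sample(1:4, n, replace = TRUE, prob = config$category_mix)
      tibble::tibble(
        genus = sprintf("%s_x%03d", aw$assemblage[i], seq_len(n)),
        region = sample(regions, n, replace = TRUE),
        max_age = origin + hw[cat_i],
        min_age = pmax(origin - duration - hw[cat_i], 1e-6),
        uncertainty_category = as.integer(cat_i),
        lithology_affinity = sample(lithology_affinities, n, replace = TRUE),
        assemblage = aw$assemblage[i],
        record_class = cls,
        lagerstatte = lag
      )
    })
    occ <- dplyr::bind_rows(occ_body, occ_extra)
    list(occurrences = validate_strat_table(occ, "occurrences"),
         truth = truth)
  })
}

#' True per-window richness from a synthetic truth record
#'
#' Range-through richness of the true (generating) taxon ranges on the
#' moving-window grid; the target curve for parameter-recovery checks.
#'
#' @param truth The `truth` element returned by [simulate_occurrences()].
#' @param grid A [time_grid()].
#' @return A tibble with `label` and `richness`.
#' @export
true_richness <- function(truth, grid) {
  richness_per_window(truth$ranges, build_windows(grid))
}

#' Simulate the regional rock record
#'
#' Walks each region from the old end of the grid to the young end,
#' alternating between depositional units (lithofacies drawn from the
#' configured weights, thickness lognormal, duration exponential) and
#' hiatuses inserted with probability `hiatus_prob`. Unit areas equal the
#' region's constant terrane area.
#'
#' @inheritParams simulate_occurrences
#' @param grid A [time_grid()] giving the span to fill.
#' @return A validated rock-unit tibble.
#' @export
simulate_rock_record <- function(config, grid = time_grid()) {
  stopifnot(inherits(config, "synth_config"))
  seed <- synth_streams(config)$rock
  withr::with_seed(seed, {
    units <- purrr::map_dfr(seq_len(nrow(config$regions)), function(i) {
      region <- config$regions$region[i]
      area <- config$regions$area_km2[i]
      base <- grid$oldest
      rows <- list()
      u <- 0L
      while (base > grid$youngest + 1e-9) {
        dur <- if (runif(1) < config$hiatus_prob) {
          base <- base - rexp(1, 1 / config$hiatus_duration_mean)
          next
        } else {
          rexp(1, 1 / config$unit_duration_mean)
        }
        top <- max(base - dur, grid$youngest)
        if (base - top < 1e-6) break
        u <- u + 1L
        fac <- sample(names(config$facies_weights), 1L,
                      prob = config$facies_weights)
        gd <- strsplit(fac, ".", fixed = TRUE)[[1L]]
        rows[[u]] <- tibble::tibble(
          region = region,
          unit_id = sprintf("%s_U%03d", region, u),
          group = gd[1L], depth = gd[2L],
          mean_thickness = rlnorm(1, config$thickness_meanlog,
                                  config$thickness_sdlog),
          area = area, base_age = base, top_age = top
        )
        base <- top
      }
      dplyr::bind_rows(rows)
    })
    if (nrow(units) == 0L) {
      units <- tibble::tibble(
        region = character(), unit_id = character(), group = character(),
        depth = character(), mean_thickness = numeric(), area = numeric(),
        base_age = numeric(), top_age = numeric()
      )
    }
    validate_strat_table(units, "rock_units")
  })
}

#' Simulate carbonate carbon and uranium isotope series
#'
#' Builds a smooth latent carbon-isotope curve (sum of incommensurate
#' sinusoids), an antithetic latent uranium curve whose correlation with it
#' is `rho_target` (mixed with an independent smooth component), and draws
#' irregularly spaced samples with additive measurement noise. A configured
#' fraction of samples carries both isotopes (`paired = TRUE`); the rest
#' report one isotope only.
#'
#' @inheritParams simulate_occurrences
#' @return A list with `samples` (validated geochem tibble, ordered old to
#'   young) and `latent` (tibble of the noise-free curves at sample ages).
#' @export
simulate_geochem <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seed <- synth_streams(config)$geochem
  withr::with_seed(seed, {
    n <- config$n_geochem
    span <- config$geochem_span
    age <- sort(runif(n, span[2], span[1]), decreasing = TRUE)
    phases <- runif(8, 0, 2 * pi)
    periods <- c(25, 12, 6, 3)
    amps <- c(2.5, 1.5, 0.8, 0.4)
    curve <- function(t, ph) {
      out <- numeric(length(t))
      for (j in seq_along(periods)) {
        out <- out + amps[j] * sin(2 * pi * t / periods[j] + ph[j])
      }
      out
    }
    c_lat <- curve(age, phases[1:4])
    g_lat <- curve(age, phases[5:8])
    std <- function(x) (x - mean(x)) / sd(x)
    rho <- abs(config$rho_target)
    u_std <- rho * (-std(c_lat)) + sqrt(1 - rho^2) * std(g_lat)
    u_lat <- -0.45 + 0.12 * u_std
    d13C <- c_lat + rnorm(n, 0, config$noise_sd_d13C)
    d238U <- u_lat + rnorm(n, 0, config$noise_sd_d238U)
    paired <- runif(n) < config$paired_fraction
    only_c <- !paired & runif(n) < 0.5
    d238U[only_c] <- NA_real_
    d13C[!paired & !only_c] <- NA_real_
    samples <- tibble::tibble(
      age = age, d13C = d13C, d238U = d238U,
      provenance = sprintf("synth_s%04d", seq_len(n)),
      paired = paired
    )
    list(samples = validate_strat_table(samples, "geochem"),
         latent = tibble::tibble(age = age, d13C = c_lat, d238U = u_lat))
  })
}

#' Simulate fossiliferous surfaces
#'
#' Surfaces cluster in time with the configured assemblages (weights
#' proportional to `n_taxa`). Well-constrained surfaces get narrow age
#' brackets (<= 0.3 Ma); uncertain ones are constrained only to a 1-4 Ma
#' span, emulating surfaces dated by the duration of their host unit.
#'
#' @inheritParams simulate_occurrences
#' @return A validated surfaces tibble.
#' @export
simulate_surfaces <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seed <- synth_streams(config)$surfaces
  withr::with_seed(seed, {
    n <- config$n_surfaces
    aw <- config$assemblage_windows
    if (n == 0L) {
      return(validate_strat_table(tibble::tibble(
        surface_id = character(), region = character(),
        max_age = numeric(), min_age = numeric(),
        constraint_quality = character()
      ), "surfaces"))
    }
    wts <- as.numeric(config$n_taxa[aw$assemblage])
    idx <- sample(seq_len(nrow(aw)), n, replace = TRUE, prob = wts)
    mid <- runif(n, aw$younger[idx], aw$older[idx])
    quality <- ifelse(runif(n) < config$well_constrained_fraction,
                      "well_constrained", "uncertain")
    width <- ifelse(quality == "well_constrained",
                    runif(n, 0, 0.3), runif(n, 1, 4))
    validate_strat_table(tibble::tibble(
      surface_id = sprintf("surf_%04d", seq_len(n)),
      region = sample(config$regions$region, n, replace = TRUE),
      max_age = mid + width / 2,
      min_age = pmax(mid - width / 2, 1e-6),
      constraint_quality = quality
    ), "surfaces")
  })
}

#' Simulate the full synthetic study system
#'
#' Convenience wrapper running all four generators under one master seed.
#'
#' @inheritParams simulate_rock_record
#' @return A list with `occurrences`, `units`, `surfaces`, `geochem`,
#'   `geochem_latent`, and `truth`.
#' @export
synthetic_dataset <- function(config = synth_config(), grid = time_grid()) {
  occ <- simulate_occurrences(config)
  gc <- simulate_geochem(config)
  list(
    occurrences = occ$occurrences,
    units = simulate_rock_record(config, grid),
    surfaces = simulate_surfaces(config),
    geochem = gc$samples,
    geochem_latent = gc$latent,
    truth = occ$truth
  )
}
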