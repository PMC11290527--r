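# Independent oracles, deliberately written with explicit loops and counting
# so they share no code path with the package implementations.

# Spearman rho on average ranks, from first principles: ranks by counting,
# correlation by explicit sums.
oracle_spearman <- function(x, y) {
  n <- length(x)
  rk <- function(v) {
    r <- numeric(n)
    for (i in seq_len(n)) {
      below <- 0; tied <- 0
      for (j in seq_len(n)) {
        if (v[j] < v[i]) below <- below + 1
        if (v[j] == v[i]) tied <- tied + 1
      }
      r[i] <- below + (tied + 1) / 2
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Per-taxon, per-window enumeration of richness and boundary-crosser classes.
oracle_window_counts <- function(fad, lad, older, younger) {
  N_bt <- 0L; N_bL <- 0L; N_Ft <- 0L; N_FL <- 0L; rich <- 0L
  for (i in seq_along(fad)) {
    cb <- fad[i] >= older && lad[i] < older
    ct <- lad[i] <= younger && fad[i] > younger
    inter <- fad[i] >= younger && lad[i] <= older
    if (inter) rich <- rich + 1L
    if (cb && ct) N_bt <- N_bt + 1L
    else if (cb) N_bL <- N_bL + 1L
    else if (ct) N_Ft <- N_Ft + 1L
    else if (inter) N_FL <- N_FL + 1L
  }
  list(richness = rich, N_bt = N_bt, N_bL = N_bL, N_Ft = N_Ft, N_FL = N_FL)
}

# Midpoint-rule integration of a unit's uniform deposition rate over one bin.
oracle_bin_volume <- function(area_km2, thickness_m, base, top,
                              bin_older, bin_younger, n_steps = 20000) {
  vol <- area_km2 * thickness_m / 1000
  rate <- vol / (base - top)
  ages <- bin_younger + (seq_len(n_steps) - 0.5) *
    (bin_older - bin_younger) / n_steps
  inside <- ages < base & ages > top
  rate * (bin_older - bin_younger) * mean(inside)
}

# Small deterministic fixtures -----------------------------------------------

fixture_units <- function() {
  validate_strat_table(tibble::tibble(
    region = c("A", "A", "B", "B"),
    unit_id = c("A_U1", "A_U2", "B_U1", "B_U2"),
    group = c("siliciclastic", "limestone", "siliciclastic", "evaporitic_semirestricted"),
    depth = c("lower_slope_basinal", "shallow_inner_shelf",
              "shallow_inner_shelf", "not_applicable"),
    mean_thickness = c(200, 100, 50, 80),
    area = c(10000, 10000, 300, 300),
    base_age = c(580, 570, 575, 565),
    top_age = c(570, 560, 565, 560)
  ), "rock_units")
}

fixture_occurrences <- function() {
  validate_strat_table(tibble::tibble(
    genus = c("Alpha", "Alpha", "Beta", "Gamma", "Tracer", "Holdy", "Bad", "Lager"),
    region = "A",
    max_age = c(560, 556, 571, 559, 566, 563, 561, 531),
    min_age = c(558, 554, 569, 549, 562, 561, 557, 529),
    uncertainty_category = c(1L, 1L, 3L, 2L, 2L, 3L, 4L, 1L),
    lithology_affinity = "shallow_mid_siliciclastic",
    assemblage = c("WhiteSea", "WhiteSea", "Avalon", "WhiteSea",
                   "WhiteSea", "WhiteSea", "WhiteSea", "Cambrian"),
    record_class = c("body", "body", "body", "body", "trace",
                     "holdfast_only", "excluded_taxon", "body"),
    lagerstatte = c(rep(FALSE, 7), TRUE)
  ), "occurrences")
}

random_range_set <- function(n, oldest = 580, youngest = 522) {
  fad <- runif(n, youngest, oldest)
  lad <- fad - rexp(n, 1 / 3)
  lad <- pmax(lad, youngest - 5)
  tibble::tibble(genus = sprintf("g%03d", seq_len(n)), fad = fad, lad = lad)
}
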