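test_that("window construction reproduces the labelling convention bit-exactly", {
  w <- build_windows(time_grid(580, 522))
  w5705 <- w[w$label == 570.5, ]
  expect_identical(w5705$older, 570.9)
  expect_identical(w5705$younger, 570.0)
  w5704 <- w[w$label == 570.4, ]
  expect_identical(w5704$older, 570.8)
  expect_identical(w5704$younger, 569.9)
  # consecutive windows overlap by span - 0.1 Ma
  expect_equal(w$older[-1] - w$younger[-nrow(w)],
               rep(0.9 - 0.1, nrow(w) - 1), tolerance = 1e-12)
  # symmetric alternative spans a full 1 Ma
  ws <- build_windows(time_grid(580, 522, window_convention = "symmetric_1ma"))
  expect_equal(unique(round(ws$older - ws$younger, 9)), 1)
  expect_error(build_windows(time_grid(522, 580)), "oldest")
})

test_that("range-through richness counts closed-interval intersections", {
  ranges <- tibble::tibble(genus = c("A", "B", "C"),
                           fad = c(572, 571, 568), lad = c(570.5, 569, 567))
  w <- tibble::tibble(label = 570.5, older = 570.9, younger = 570.0)
  expect_equal(richness_per_window(ranges, w)$richness, 2)
  # empty set and grid-spanning taxon
  w_all <- build_windows(time_grid(575, 560))
  expect_true(all(richness_per_window(ranges[0, ], w_all)$richness == 0))
  wide <- tibble::tibble(genus = "W", fad = 580, lad = 550)
  expect_true(all(richness_per_window(wide, w_all)$richness == 1))
})

test_that("boundary crossers classify the worked four-taxon example", {
  ranges <- tibble::tibble(
    genus = c("bt", "bL", "Ft", "FL"),
    fad = c(573, 572, 570.8, 570.7),
    lad = c(569, 570.5, 568, 570.2)
  )
  bc <- boundary_crossers(ranges, list(older = 571, younger = 570))
  expect_equal(bc, list(N_bt = 1L, N_bL = 1L, N_Ft = 1L, N_FL = 1L))
  # all range-through
  thru <- tibble::tibble(genus = letters[1:5], fad = 580, lad = 560)
  bc2 <- boundary_crossers(thru, list(older = 571, younger = 570))
  expect_equal(bc2$N_bt, 5L)
  expect_equal(bc2$N_bL + bc2$N_Ft + bc2$N_FL, 0L)
  # empty
  bc3 <- boundary_crossers(thru[0, ], list(older = 571, younger = 570))
  expect_equal(unlist(bc3), c(N_bt = 0L, N_bL = 0L, N_Ft = 0L, N_FL = 0L))
})

test_that("richness and counts match per-taxon enumeration on random sets", {
  windows <- build_windows(time_grid(580, 522))
  withr::with_seed(607, {
    for (i in 1:25) {
      ranges <- random_range_set(sample(1:50, 1))
      rich <- richness_per_window(ranges, windows)
      counts <- stratodyn:::bin_counts_series(ranges, windows)
      idx <- sample(nrow(windows), 12)
      for (j in idx) {
        want <- oracle_window_counts(ranges$fad, ranges$lad,
                                     windows$older[j], windows$younger[j])
        expect_identical(rich$richness[j], want$richness)
        expect_identical(counts$N_bt[j], want$N_bt)
        expect_identical(counts$N_bL[j], want$N_bL)
        expect_identical(counts$N_Ft[j], want$N_Ft)
        expect_identical(counts$N_FL[j], want$N_FL)
      }
    }
  })
})

test_that("the four crosser classes partition window richness; monotone in taxa", {
  windows <- build_windows(time_grid(580, 522))
  withr::with_seed(913, {
    for (i in 1:10) {
      ranges <- random_range_set(40)
      counts <- stratodyn:::bin_counts_series(ranges, windows)
      rich <- richness_per_window(ranges, windows)
      expect_equal(counts$N_bt + counts$N_bL + counts$N_Ft + counts$N_FL,
                   rich$richness)
      # adding one taxon never decreases richness anywhere
      more <- dplyr::bind_rows(ranges, random_range_set(1))
      rich2 <- richness_per_window(more, windows)
      expect_true(all(rich2$richness >= rich$richness))
    }
  })
})

test_that("Foote per-capita rates evaluate their closed forms", {
  r1 <- foote_rates(list(N_bt = 4, N_bL = 1, N_Ft = 0), dt = 1)
  expect_equal(r1$p, 0, tolerance = 1e-12)
  expect_equal(r1$q, log(1.25), tolerance = 1e-12)
  r2 <- foote_rates(list(N_bt = 2, N_bL = 0, N_Ft = 2), dt = 1)
  expect_equal(r2$p, log(2), tolerance = 1e-12)
  expect_equal(r2$q, 0, tolerance = 1e-12)
  # no turnover, and the per-Ma scaling by dt
  r3 <- foote_rates(list(N_bt = 7, N_bL = 0, N_Ft = 0), dt = 0.9)
  expect_equal(c(r3$p, r3$q), c(0, 0))
  r4 <- foote_rates(list(N_bt = 2, N_bL = 3, N_Ft = 1), dt = 0.9)
  expect_equal(r4$q, log(2.5) / 0.9, tolerance = 1e-12)
  # no boundary crossers -> missing, not zero, not an error
  r5 <- foote_rates(list(N_bt = 0, N_bL = 3, N_Ft = 1), dt = 1)
  expect_true(is.na(r5$p) && is.na(r5$q))
  expect_error(foote_rates(list(N_bt = 1, N_bL = 0, N_Ft = 0), dt = 0), "dt")
})

test_that("young-end truncations leave extinction and richness missing", {
  ranges <- tibble::tibble(genus = "A", fad = 580, lad = 510)
  g <- time_grid(580, 510)
  ds <- diversity_series(ranges, g)
  expect_true(all(is.na(ds$q[ds$label < 530])))
  expect_true(all(!is.na(ds$q[ds$label >= 530])))
  expect_true(all(is.na(ds$richness[ds$label < 522])))
  expect_true(all(!is.na(ds$p)))  # origination reported over the full grid
})

test_that("replicate aggregation reports pairwise mean/min/max", {
  mk <- function(vals) tibble::tibble(
    label = c(570.5, 570.4, 570.3), richness = vals,
    N_bt = 0L, N_bL = 0L, N_Ft = 0L, N_FL = 0L,
    p = c(NA, 0.2, NA), q = NA_real_
  )
  agg <- aggregate_replicates(list(mk(c(4, NA, 1)), mk(c(6, NA, 2)),
                                   mk(c(5, NA, 3))))
  expect_equal(agg$richness_mean[agg$label == 570.5], 5)
  expect_equal(agg$richness_min[agg$label == 570.5], 4)
  expect_equal(agg$richness_max[agg$label == 570.5], 6)
  expect_true(is.na(agg$richness_mean[agg$label == 570.4]))
  expect_equal(agg$p_mean, c(NA, 0.2, NA))
  single <- aggregate_replicates(list(mk(c(4, NA, 1))))
  expect_equal(single$richness_mean, single$richness_min)
  expect_equal(single$richness_mean, single$richness_max)
  bad <- mk(c(1, 2, 3)); bad$label <- bad$label + 1
  expect_error(aggregate_replicates(list(mk(c(1, 2, 3)), bad)), "mismatched")
})

test_that("category-1-only data collapse the replicate summary onto one series", {
  occ <- filter_occurrences(fixture_occurrences()) |>
    dplyr::filter(uncertainty_category == 1L)
  g <- time_grid(565, 550)
  summ <- replicate_diversity(occ, g, n_replicates = 5L, master_seed = 4L)
  one <- diversity_series(realize_ranges(occ, seed = 1L), g)
  expect_equal(summ$richness_mean, as.numeric(one$richness))
  expect_equal(summ$richness_min, as.numeric(one$richness))
  expect_equal(summ$richness_max, as.numeric(one$richness))
})

test_that("genus density divides richness by rock quantity and normalizes", {
  rich <- tibble::tibble(label = c(570.5, 570.4, 570.3),
                         richness = c(10, 8, 4))
  rock <- tibble::tibble(label = c(570.5, 570.4, 570.3),
                         value = c(5, 0, 2))
  d <- genus_density(rich, rock, normalize = FALSE)
  expect_equal(d$density, c(2, NA, 2))
  dn <- genus_density(rich, rock)
  expect_equal(dn$density, c(1, NA, 1))  # zero-flux window excluded from max
  expect_equal(genus_density(rich, dplyr::mutate(rock, value = c(5, 2, 2)),
                             normalize = TRUE)$density, c(0.5, 1, 0.5))
  expect_error(genus_density(rich, rock[1:2, ]), "different window grids")
})
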