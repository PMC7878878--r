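sim_records <- function(seed = 1, n = 15, spans = list(c(6000, 500),
                                                       c(6000, 500))) {
  curve <- make_synthetic_curve("wiggly", 0, 8000, sigma = 10, seed = 99)
  scens <- lapply(seq_along(spans), function(k)
    taxon_scenario(LETTERS[k], spans[[k]], 1))
  sim <- simulate_assemblage(scens, n, curve, seed = seed)
  calibrate_specimens(sim$specimens, curve)
}

test_that("SPD equals the elementwise summation oracle", {
  rec <- sim_records(seed = 3, n = 8)
  dens <- rec$density[rec$status == "calibrated"]
  names(dens) <- rec$specimen_id[rec$status == "calibrated"]
  s <- compute_spd(dens)
  # direct per-density placement oracle
  expected <- numeric(length(s$grid))
  for (d in dens) {
    idx <- match(d$grid, s$grid)
    expected[idx] <- expected[idx] + d$prob / sum(d$prob)
  }
  expect_lt(max(abs(s$density - expected)), 1e-12)
  expect_equal(sum(s$density), length(dens), tolerance = 1e-6)
})

test_that("single date SPD reproduces its density; binning averages members", {
  rec <- sim_records(seed = 4, n = 5)
  d1 <- rec$density[[1]]
  s1 <- compute_spd(list(x = d1))
  expect_equal(sum(s1$density), 1, tolerance = 1e-9)
  expect_equal(s1$density[match(d1$grid, s1$grid)], unname(d1$prob))

  # two copies of one date in one bin contribute exactly one date's mass
  dens <- list(a = d1, b = d1)
  bins <- structure(list(h = 0, bins = list(c("a", "b")), taxon = "T",
                         site = "S", n_bins = 1L), class = "bin_set")
  sb <- compute_spd(dens, bins = bins)
  expect_equal(sum(sb$density), 1, tolerance = 1e-9)
  expect_equal(sb$density[match(d1$grid, sb$grid)], unname(d1$prob))

  # k singleton bins carry mass k
  bins2 <- structure(list(h = 0, bins = list("a", "b"), taxon = c("T", "T"),
                          site = c("S", "S"), n_bins = 2L),
                     class = "bin_set")
  expect_equal(sum(compute_spd(dens, bins = bins2)$density), 2,
               tolerance = 1e-9)
})

test_that("permutation test is reproducible and validates its inputs", {
  rec <- sim_records(seed = 5)
  p1 <- mark_permutation_test(rec, "A", n_sim = 49, seed = 11)
  p2 <- mark_permutation_test(rec, "A", n_sim = 49, seed = 11)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$deviation_intervals, p2$deviation_intervals)
  expect_identical(p1$upper, p2$upper)
  p3 <- mark_permutation_test(rec, "A", n_sim = 49, seed = 12)
  expect_false(identical(p1$upper, p3$upper))

  expect_gte(p1$global_p, 1 / 50)
  expect_lte(p1$global_p, 1)

  one <- rec[rec$taxon == "A", ]
  expect_error(mark_permutation_test(one, "A", n_sim = 9, seed = 1),
               ">= 2 taxa")
  expect_warning(mark_permutation_test(rec, "A", n_sim = 10, seed = 1),
                 "envelope")
})

test_that("clustered focal dates are detected against a spread background", {
  curve <- make_synthetic_curve("wiggly", 0, 8000, sigma = 10, seed = 99)
  scF <- taxon_scenario("F", c(2000, 1500), 1)   # narrow 500-yr window
  scB <- taxon_scenario("B", c(7500, 500), 1)    # broad background
  sim <- simulate_assemblage(list(scF, scB), 20, curve, seed = 21)
  rec <- calibrate_specimens(sim$specimens, curve)
  pt <- mark_permutation_test(rec, "F", n_sim = 199, seed = 22)
  expect_lt(pt$global_p, 0.05)
  dev <- pt$deviation_intervals
  pos <- dev[dev$sign > 0, ]
  expect_gt(nrow(pos), 0)
  # the positive departure sits on the focal window
  expect_true(any(pos$old >= 1500 & pos$young <= 2000))
})

test_that("deviation intervals are maximal runs with a length filter", {
  grid <- 100:200
  obs <- rep(0.5, length(grid))
  upper <- rep(1, length(grid))
  lower <- rep(0.1, length(grid))
  obs[21:40] <- 1.5        # 20-yr excursion above (grid 120..139)
  obs[61] <- 0.05          # single-year dip below
  fake <- structure(list(grid = grid, observed = obs, lower = lower,
                         upper = upper, eps = 0), class = "perm_test")
  dv <- deviation_intervals(fake)
  expect_equal(nrow(dv), 2L)
  expect_equal(dv$old[dv$sign == 1], 139)
  expect_equal(dv$young[dv$sign == 1], 120)
  expect_equal(dv$old[dv$sign == -1], 160)
  dv5 <- deviation_intervals(fake, min_run = 5)
  expect_equal(nrow(dv5), 1L)
  expect_equal(dv5$sign, 1L)

  none <- fake; none$observed <- rep(0.5, length(grid))
  expect_equal(nrow(deviation_intervals(none)), 0L)
})

test_that("disjoint focal and background spans give an extreme global p", {
  # a focal taxon far outside the background's span: near-minimal p; the
  # floor 1/(n_sim+1) is only reachable, never undercut
  curve <- make_synthetic_curve("wiggly", 0, 9000, sigma = 10, seed = 99)
  scF <- taxon_scenario("F", c(1200, 800), 1)
  scB <- taxon_scenario("B", c(8500, 5000), 1)
  sim <- simulate_assemblage(list(scF, scB), 15, curve, seed = 33)
  rec <- calibrate_specimens(sim$specimens, curve)
  pt <- mark_permutation_test(rec, "F", n_sim = 99, seed = 34)
  expect_gte(pt$global_p, 1 / 100)
  expect_lte(pt$global_p, 0.05)
})
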