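make_records <- function(...) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("specimen_id", "site_id", "taxon", "c14_age", "c14_error",
                 "fraction")
  df$c14_age <- as.numeric(df$c14_age)
  df$c14_error <- as.numeric(df$c14_error)
  df
}

test_that("specimen tables load with schema and uniqueness checks", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- make_records(
    c("A1", "S1", "Hyaena hyaena", 1000, 25, "collagen"),
    c("A2", "S1", "Hyaena hyaena", 2000, 25, "scat"),
    c("A3", "S2", "Panthera pardus", 3000, 25, "bioapatite"))
  write.csv(df, f, row.names = FALSE)
  got <- load_specimens(f)
  expect_equal(nrow(got), 3L)
  expect_equal(got$specimen_id, c("A1", "A2", "A3"))

  df2 <- df; df2$specimen_id <- c("A1", "A1", "A3")
  write.csv(df2, f, row.names = FALSE)
  expect_error(load_specimens(f), "A1")

  df3 <- df; df3$c14_error[2] <- 0
  write.csv(df3, f, row.names = FALSE)
  expect_error(load_specimens(f), "c14_error")

  df4 <- df[, -3]
  write.csv(df4, f, row.names = FALSE)
  expect_error(load_specimens(f), "taxon")
})

test_that("MNI merges same-site chronologically equivalent specimens only", {
  cv <- make_synthetic_curve("identity", 0, 10000, sigma = 0)
  rec <- calibrate_specimens(make_records(
    c("X1", "S1", "T", 5000, 30, "collagen"),
    c("X2", "S1", "T", 5000, 30, "collagen"),   # same site, same age
    c("X3", "S2", "T", 5000, 30, "collagen"),   # same age, other site
    c("X4", "S1", "T", 8000, 30, "collagen")),  # same site, far in time
    cv)
  m <- assign_mni_clusters(rec, "T")
  expect_equal(m$nisp, 4L)
  expect_equal(m$mni, 3L)
  sizes <- sort(lengths(m$clusters))
  expect_equal(sizes, c(1L, 1L, 2L))
  expect_setequal(unlist(m$clusters), rec$specimen_id)

  expect_equal(assign_mni_clusters(rec, "absent")$mni, 0L)
})

test_that("MNI counts modern and beyond-range specimens as singletons", {
  cv <- make_synthetic_curve("wiggly", 0, 50000, sigma = 10, seed = 1)
  rec <- calibrate_specimens(make_records(
    c("Y1", "S1", "T", 5000, 30, "collagen"),
    c("Y2", "S1", "T", 5005, 30, "collagen"),   # merges with Y1
    c("Y3", "S1", "T", -300, 30, "collagen"),   # modern
    c("Y4", "S1", "T", 60000, 400, "collagen")),# beyond range
    cv)
  m <- assign_mni_clusters(rec, "T")
  expect_equal(m$mni, 3L)
})

test_that("cluster assignment is invariant to row order", {
  cv <- make_synthetic_curve("wiggly", 0, 20000, sigma = 10, seed = 2)
  set.seed(42)
  base <- make_records(
    c("Z1", "S1", "T", 4000, 25, "collagen"),
    c("Z2", "S1", "T", 4010, 25, "collagen"),
    c("Z3", "S1", "T", 9000, 25, "collagen"),
    c("Z4", "S2", "T", 4000, 25, "collagen"),
    c("Z5", "S2", "T", 12000, 30, "collagen"),
    c("Z6", "S2", "T", 12040, 30, "collagen"))
  ref <- assign_mni_clusters(calibrate_specimens(base, cv), "T")
  canon <- function(m) lapply(m$clusters, sort)[order(vapply(
    lapply(m$clusters, sort), `[[`, character(1), 1))]
  for (i in 1:3) {
    perm <- base[sample(nrow(base)), ]
    got <- assign_mni_clusters(calibrate_specimens(perm, cv), "T")
    expect_equal(got$mni, ref$mni)
    expect_equal(canon(got), canon(ref))
  }
})

test_that("binning is single linkage within site at cutoff h", {
  df <- make_records(
    c("B1", "S1", "T", 1000, 20, "collagen"),
    c("B2", "S1", "T", 1050, 20, "collagen"),
    c("B3", "S1", "T", 1200, 20, "collagen"))
  bs <- make_bins(df, h = 100)
  expect_equal(bs$n_bins, 2L)
  expect_setequal(lapply(bs$bins, sort),
                  list(c("B1", "B2"), "B3"))
  # matches exhaustive chaining oracle
  o <- oracle_single_linkage(df$c14_age, 100)
  expect_equal(bs$n_bins, length(o))

  expect_equal(make_bins(df, h = 0)$n_bins, 3L)

  # equal ages merge at h = 0
  df2 <- make_records(
    c("C1", "S1", "T", 900, 20, "collagen"),
    c("C2", "S1", "T", 900, 20, "collagen"))
  expect_equal(make_bins(df2, h = 0)$n_bins, 1L)

  # order invariance and partition property
  perm <- df[c(3, 1, 2), ]
  expect_equal(make_bins(perm, h = 100)$n_bins, 2L)
  expect_setequal(unlist(bs$bins), df$specimen_id)
})

test_that("bins never span sites and random cases match the oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 12
    df <- data.frame(
      specimen_id = sprintf("R%02d", 1:n),
      site_id = sample(c("S1", "S2"), n, replace = TRUE),
      taxon = "T",
      c14_age = round(runif(n, 1000, 2500)),
      c14_error = 20, fraction = "collagen",
      stringsAsFactors = FALSE)
    h <- sample(c(0, 50, 150, 400), 1)
    bs <- make_bins(df, h = h)
    for (b in seq_along(bs$bins)) {
      sites <- df$site_id[match(bs$bins[[b]], df$specimen_id)]
      expect_length(unique(sites), 1L)
    }
    n_oracle <- sum(vapply(c("S1", "S2"), function(s) {
      ages <- df$c14_age[df$site_id == s]
      if (!length(ages)) 0L else length(oracle_single_linkage(ages, h))
    }, integer(1)))
    expect_equal(bs$n_bins, n_oracle)
  }
})

test_that("FAD/LAD come from calibrated medians with explicit undefined case", {
  cv <- make_synthetic_curve("wiggly", 0, 50000, sigma = 10, seed = 1)
  rec <- calibrate_specimens(make_records(
    c("F1", "S1", "T", 7200, 25, "collagen"),
    c("F2", "S2", "T", 3400, 25, "collagen"),
    c("F3", "S3", "T", -250, 25, "collagen"),
    c("F4", "S1", "U", 60000, 300, "collagen")),
    cv)
  fl <- fad_lad(rec, "T")
  expect_true(fl$defined)
  expect_equal(fl$fad, max(rec$median_calbp[rec$taxon == "T"], na.rm = TRUE))
  expect_equal(fl$lad, min(rec$median_calbp[rec$taxon == "T" &
                                            rec$status == "calibrated"]))
  expect_gte(fl$fad, fl$lad)
  expect_equal(fl$n_modern, 1L)
  expect_equal(fl$n_calibrated + fl$n_modern + fl$n_beyond,
               sum(rec$taxon == "T"))

  # single calibrated date: fad == lad
  one <- fad_lad(rec[rec$specimen_id == "F1", ], "T")
  expect_equal(one$fad, one$lad)

  # no calibrated record -> undefined, not silent zeros
  und <- fad_lad(rec, "U")
  expect_false(und$defined)
  expect_true(is.na(und$fad) && is.na(und$lad))
  expect_equal(und$n_beyond, 1L)

  # bound mode widens both ends
  fb <- fad_lad(rec, "T", mode = "bound")
  expect_gte(fb$fad, fl$fad)
  expect_lte(fb$lad, fl$lad)
})

test_that("fraction_after uses a strict threshold on calibrated medians", {
  cv <- make_synthetic_curve("identity", 0, 10000, sigma = 0)
  rec <- calibrate_specimens(make_records(
    c("G1", "S1", "T", 5000, 30, "collagen"),
    c("G2", "S2", "T", 3000, 30, "collagen"),
    c("G3", "S3", "T", 1000, 30, "collagen")),
    cv)
  expect_equal(fraction_after(rec, "T", 4000)$fraction, 2 / 3)
  expect_equal(fraction_after(rec, "T", 9000)$fraction, 1)
  # a record whose median equals the threshold is excluded
  expect_equal(fraction_after(rec, "T", 3000)$k, 1L)
  expect_error(fraction_after(rec, "absent", 4000), "no calibrated")
})

test_that("cave composition yields unit-sum proportions per site", {
  df <- make_records(
    c("H1", "S1", "Hyaena hyaena", 100, 20, "scat"),
    c("H2", "S1", "Hyaena hyaena", 200, 20, "collagen"),
    c("H3", "S1", "Panthera pardus", 300, 20, "collagen"),
    c("H4", "S1", "Panthera pardus", 400, 20, "collagen"),
    c("H5", "S2", "Vulpes cana", 500, 20, "collagen"),
    c("H6", "S3", "Vulpes rueppellii", 600, 20, "collagen"),
    c("H7", "S3", "Canis lupus", 700, 20, "collagen"))  # outside the groups
  comp <- cave_composition(df)
  s1 <- comp[comp$site_id == "S1", ]
  expect_equal(c(s1$leopard, s1$hyena, s1$fox), c(0.5, 0.5, 0))
  s2 <- comp[comp$site_id == "S2", ]
  expect_equal(c(s2$leopard, s2$hyena, s2$fox), c(0, 0, 1))
  expect_true(all(abs(comp$leopard + comp$hyena + comp$fox - 1) < 1e-12))
})
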