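# Independent oracles used across the suite. These re-derive expected
# values by direct enumeration or closed form and never call the code paths
# they check.

# Brute-force calibration oracle: evaluate the unnormalised posterior at
# every integer year of the curve support with scalar arithmetic, normalise,
# then apply the documented tail rule (drop years below `trunc_rel` of the
# maximum, renormalise).
oracle_calibrate <- function(c14_age, c14_error, curve, trunc_rel = 1e-6) {
  years <- seq(ceiling(min(curve$calbp)), floor(max(curve$calbp)))
  dens <- vapply(years, function(y) {
    mu <- approx(curve$calbp, curve$c14age, xout = y)$y
    sc <- approx(curve$calbp, curve$error, xout = y)$y
    v <- c14_error^2 + sc^2
    exp(-(c14_age - mu)^2 / (2 * v)) / sqrt(v)
  }, numeric(1))
  p <- dens / sum(dens)
  if (trunc_rel > 0) {
    keep <- p >= trunc_rel * max(p)
    years <- years[keep]
    p <- p[keep] / sum(p[keep])
  }
  list(grid = years, prob = p)
}

# Threshold-scan HPD oracle: the HPD set at `level` is {years: prob >= c}
# for the largest threshold c whose mass reaches `level`. Scans every
# distinct probability value as a candidate threshold.
oracle_hpd_set <- function(grid, prob, level) {
  cands <- sort(unique(prob), decreasing = TRUE)
  for (c in cands) {
    sel <- prob >= c
    if (sum(prob[sel]) >= level - 1e-12) return(sort(grid[sel]))
  }
  sort(grid)
}

# O(n^3) convex-hull oracle: a point is a hull vertex iff it is not a strict
# convex combination of the others; test via the all-pairs half-plane rule
# (for every directed pair (i, j), points strictly left of every edge of the
# hull). Returns the set of extreme points.
oracle_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  extreme <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # is every other point strictly on one side of line (i, j)?
    d <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
         (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    d <- d[-c(i, j)]
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      extreme[i] <- TRUE
      extreme[j] <- TRUE
    }
  }
  pts[extreme, , drop = FALSE]
}

# Fan-triangulation polygon area (m^2) from an ordered vertex matrix.
oracle_fan_area <- function(v) {
  if (nrow(v) < 3) return(0)
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    p1 <- as.numeric(v[1, ]); p2 <- as.numeric(v[i, ])
    p3 <- as.numeric(v[i + 1, ])
    a <- a + abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                 (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
  }
  a
}

# Single-linkage 1-D clustering by exhaustive chaining: two ages join when
# some chain of pairwise gaps <= h connects them.
oracle_single_linkage <- function(ages, h) {
  n <- length(ages)
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        gap <- min(abs(outer(ages[groups[[a]]], ages[groups[[b]]], `-`)))
        if (gap <= h) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups <- groups[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups
}

total_variation <- function(p, q, grid_p, grid_q) {
  grid <- sort(union(grid_p, grid_q))
  pv <- numeric(length(grid)); qv <- numeric(length(grid))
  pv[match(grid_p, grid)] <- p
  qv[match(grid_q, grid)] <- q
  sum(abs(pv - qv)) / 2
}
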