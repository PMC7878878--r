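#' Construct an uncalibrated radiocarbon measurement
#'
#' @param lab_id laboratory code for the measurement.
#' @param c14_age conventional 14C age BP; modern (post-bomb) measurements may
#'   be small or negative.
#' @param c14_error 1-sigma measurement error (14C yr), > 0.
#' @param fraction dated fraction: `"collagen"`, `"bioapatite"`, `"scat"` or
#'   `"unknown"`.
#' @return An object of class `uncal_date`.
#' @export
uncal_date <- function(lab_id, c14_age, c14_error, fraction = "unknown") {
  fraction <- match.arg(fraction, c("collagen", "bioapatite", "scat", "unknown"))
  if (!is.finite(c14_age)) stop("c14_age must be finite", call. = FALSE)
  if (!is.finite(c14_error) || c14_error <= 0)
    stop("c14_error must be > 0", call. = FALSE)
  structure(list(lab_id = as.character(lab_id)[1L],
                 c14_age = as.numeric(c14_age),
                 c14_error = as.numeric(c14_error),
                 fraction = fraction),
            class = "uncal_date")
}

#' Screen a measurement against the limits of a calibration curve
#'
#' A measurement whose 14C age lies more than `k_sigma` errors beyond the
#' oldest tabulated 14C age cannot be calibrated and is flagged
#' `"beyond_range"`; one more than `k_sigma` errors younger than the youngest
#' tabulated age is flagged `"modern"` (post-bomb). Everything else is
#' `"calibrated"`.
#'
#' @param date an [uncal_date].
#' @param curve a [cal_curve].
#' @param k_sigma exceedance multiple (default 2).
#' @return `"calibrated"`, `"modern"` or `"beyond_range"`.
#' @export
classify_range_status <- function(date, curve, k_sigma = 2) {
  stopifnot(inherits(date, "uncal_date"), inherits(curve, "cal_curve"))
  if (k_sigma <= 0) stop("k_sigma must be > 0", call. = FALSE)
  if (date$c14_age - k_sigma * date$c14_error > max(curve$c14age))
    return("beyond_range")
  if (date$c14_age + k_sigma * date$c14_error < min(curve$c14age))
    return("modern")
  "calibrated"
}

#' Calibrate a radiocarbon date
#'
#' Intercept-free probabilistic calibration: the posterior mass assigned to
#' calendar year theta is proportional to
#' \deqn{\exp\{-(m - \mu(\theta))^2 / 2(\sigma_m^2 + \sigma_c(\theta)^2)\} /
#'   \sqrt{\sigma_m^2 + \sigma_c(\theta)^2}}
#' where \eqn{m, \sigma_m} are the measurement and its error and
#' \eqn{\mu, \sigma_c} the curve mean and error, linearly interpolated onto a
#' 1-calendar-year grid and normalised over the curve support. Grid years
#' whose normalised mass falls below `trunc_rel` of the maximum are dropped
#' and the density renormalised, keeping densities compact without affecting
#' intervals at conventional levels. Dates that fail range screening come
#' back with status `"modern"` or `"beyond_range"` and an empty density.
#'
#' @param date an [uncal_date] (or a single numeric 14C age, in which case
#'   `c14_error` must be given).
#' @param curve a [cal_curve].
#' @param level probability level for the reported HPD intervals
#'   (default 0.954, the conventional 2-sigma level).
#' @param k_sigma range-screening multiple passed to
#'   [classify_range_status()].
#' @param trunc_rel relative tail-truncation threshold (0 disables).
#' @param c14_error used only when `date` is numeric.
#' @return An object of class `cal_density`: list with `lab_id`, `status`,
#'   `grid` (cal BP, ascending), `prob`, `median` (cal BP), `hpd`
#'   (data.frame `old`, `young`, `mass`, oldest interval first), `level`.
#' @export
calibrate_date <- function(date, curve, level = 0.954, k_sigma = 2,
                           trunc_rel = 1e-6, c14_error = NULL) {
  if (is.numeric(date)) {
    if (is.null(c14_error))
      stop("supply c14_error when calibrating a bare 14C age", call. = FALSE)
    date <- uncal_date("unnamed", date, c14_error)
  }
  stopifnot(inherits(date, "uncal_date"))
  if (!inherits(curve, "cal_curve") || length(curve$calbp) < 2L)
    stop("invalid calibration curve", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)

  status <- classify_range_status(date, curve, k_sigma = k_sigma)
  if (status != "calibrated") {
    return(structure(list(lab_id = date$lab_id, status = status,
                          grid = integer(0), prob = numeric(0),
                          median = NA_real_,
                          hpd = data.frame(old = numeric(0),
                                           young = numeric(0),
                                           mass = numeric(0)),
                          level = level),
                     class = "cal_density"))
  }

  cg <- curve_year_grid(curve)
  s2 <- date$c14_error^2 + cg$sigma^2
  dens <- exp(-(date$c14_age - cg$mu)^2 / (2 * s2)) / sqrt(s2)
  tot <- sum(dens)
  if (tot <= 0 || !is.finite(tot))
    stop("calibration produced no probability mass; check curve and date",
         call. = FALSE)
  prob <- dens / tot
  if (trunc_rel > 0) {
    keep <- prob >= trunc_rel * max(prob)
    prob <- prob[keep] / sum(prob[keep])
    grid <- cg$grid[keep]
  } else {
    grid <- cg$grid
  }

  med <- density_median(grid, prob)
  hpd <- hpd_from_probs(grid, prob, level)
  structure(list(lab_id = date$lab_id, status = "calibrated",
                 grid = grid, prob = prob, median = med,
                 hpd = hpd, level = level),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  if (x$status != "calibrated") {
    cat(sprintf("<cal_density %s: %s>\n", x$lab_id, x$status))
  } else {
    iv <- paste(sprintf("%d-%d", round(x$hpd$old), round(x$hpd$young)),
                collapse = "; ")
    cat(sprintf("<cal_density %s: median %d cal BP, %.1f%% HPD %s>\n",
                x$lab_id, round(x$median), 100 * x$level, iv))
  }
  invisible(x)
}

# Median of a discrete density on an ascending cal BP grid: the first grid
# year at which cumulative mass reaches 0.5. When it hits 0.5 exactly the
# quantile sits between two years; the older one is reported (fixed rule).
density_median <- function(grid, prob) {
  cum <- cumsum(prob)
  i <- which(cum >= 0.5)[1L]
  if (abs(cum[i] - 0.5) < 1e-12 && i < length(grid)) i <- i + 1L
  grid[i]
}

# Greedy highest-density set: take grid years in decreasing probability until
# the accumulated mass reaches `level`, then merge contiguous years. Ties in
# probability are broken towards the older year.
hpd_from_probs <- function(grid, prob, level) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]", call. = FALSE)
  ord <- order(prob, grid, decreasing = TRUE)
  cum <- cumsum(prob[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(ord)
  sel <- sort(grid[ord[seq_len(k)]])
  # merge runs of consecutive years
  breaks <- which(diff(sel) > 1)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(sel))
  mass <- vapply(seq_along(starts), function(j) {
    sum(prob[grid >= sel[starts[j]] & grid <= sel[ends[j]]])
  }, numeric(1))
  out <- data.frame(old = sel[ends], young = sel[starts], mass = mass)
  out[order(out$old, decreasing = TRUE), , drop = FALSE]
}

#' Highest-posterior-density intervals of a calibrated date
#'
#' Smallest set of calendar years containing at least `level` of the
#' posterior mass, reported as disjoint intervals, oldest first. Each
#' interval is `(old, young, mass)` with `old >= young` in cal BP.
#'
#' @param density a `cal_density` with status `"calibrated"`.
#' @param level probability level; defaults to the level the density was
#'   calibrated at.
#' @return data.frame with columns `old`, `young`, `mass`.
#' @export
hpd_intervals <- function(density, level = density$level) {
  stopifnot(inherits(density, "cal_density"))
  if (density$status != "calibrated")
    stop("cannot compute HPD intervals for a ", density$status, " date",
         call. = FALSE)
  out <- hpd_from_probs(density$grid, density$prob, level)
  rownames(out) <- NULL
  out
}
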