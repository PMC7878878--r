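#' Construct a calibration curve
#'
#' A calibration curve tabulates, for a grid of calendar ages (cal BP,
#' 0 = 1950 CE, larger = older), the corresponding radiocarbon age (14C yr BP)
#' and the 1-sigma curve error. Rows are stored sorted by increasing cal BP
#' and must cover a contiguous calendar interval.
#'
#' @param calbp numeric vector of calendar ages (cal BP), strictly increasing
#'   after sorting; duplicates are an error.
#' @param c14age numeric vector of 14C ages (BP) at each knot.
#' @param error numeric vector of 1-sigma curve errors (14C yr), all >= 0.
#' @param name text label for the curve.
#' @return An object of class `cal_curve`: a list with elements `name`,
#'   `calbp`, `c14age`, `error`.
#' @export
cal_curve <- function(calbp, c14age, error, name = "curve") {
  if (length(calbp) < 2L)
    stop("a calibration curve needs at least two knots", call. = FALSE)
  if (length(c14age) != length(calbp) || length(error) != length(calbp))
    stop("calbp, c14age and error must have equal length", call. = FALSE)
  if (anyNA(calbp) || anyNA(c14age) || anyNA(error))
    stop("calibration curve contains missing values", call. = FALSE)
  if (any(!is.finite(calbp)) || any(!is.finite(c14age)) || any(!is.finite(error)))
    stop("calibration curve contains non-finite values", call. = FALSE)
  ord <- order(calbp)
  calbp <- calbp[ord]; c14age <- c14age[ord]; error <- error[ord]
  if (anyDuplicated(calbp))
    stop("duplicated cal BP values in calibration curve", call. = FALSE)
  if (any(diff(calbp) <= 0))
    stop("calibration curve grid is not strictly increasing", call. = FALSE)
  if (any(error < 0))
    stop("negative curve error", call. = FALSE)
  structure(
    list(name = as.character(name)[1L],
         calbp = as.numeric(calbp),
         c14age = as.numeric(c14age),
         error = as.numeric(error)),
    class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve '%s': %d knots, %s-%s cal BP>\n",
              x$name, length(x$calbp),
              format(min(x$calbp)), format(max(x$calbp))))
  invisible(x)
}

#' Read a calibration curve from a text file
#'
#' Parses the standard three-column curve layout: cal BP, 14C age BP,
#' 1-sigma error. Lines starting with `#` are comments; fields may be
#' separated by commas and/or whitespace; extra columns beyond the third are
#' ignored. Files tabulated in descending cal BP (the common convention) are
#' re-sorted ascending.
#'
#' @param path path to the curve file.
#' @param dialect `"c14_standard"` (comma/whitespace separated `.14c` layout)
#'   or `"csv"` (strict comma separation). Both accept `#` comments.
#' @param name label for the curve; defaults to the file name.
#' @return A [cal_curve] object.
#' @export
read_cal_curve <- function(path, dialect = c("c14_standard", "csv"),
                           name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("curve file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    stop("curve file has no data rows: ", path, call. = FALSE)
  split_re <- if (dialect == "csv") "," else "[,[:space:]]+"
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), split_re)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("line %d of %s: expected 3 numeric columns", i, path),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals))
      stop(sprintf("line %d of %s: non-numeric field", i, path),
           call. = FALSE)
    vals
  })
  m <- do.call(rbind, rows)
  cal_curve(m[, 1L], m[, 2L], m[, 3L], name = name)
}

#' Generate a synthetic calibration curve
#'
#' Test and simulation fixture standing in for a real atmospheric curve.
#' `"identity"` maps calendar age to the same 14C age; `"wiggly"` adds a
#' smooth bounded perturbation (sum of incommensurate sinusoids with random
#' phases) so that `|mu(theta) - theta| <= amplitude` everywhere, emulating
#' the wiggles of a real curve while staying analytically tractable.
#'
#' @param kind `"identity"` or `"wiggly"`.
#' @param t_min,t_max calendar span (cal BP), `t_min < t_max`.
#' @param sigma constant 1-sigma curve error (14C yr), >= 0.
#' @param seed integer seed controlling the wiggle phases (ignored for
#'   `"identity"`).
#' @param amplitude maximum absolute deviation of the wiggly mean from the
#'   identity line (14C yr).
#' @param knot_step knot spacing in calendar years.
#' @return A [cal_curve] object.
#' @export
make_synthetic_curve <- function(kind = c("identity", "wiggly"),
                                 t_min = 0, t_max = 10000,
                                 sigma = 10, seed = 1L,
                                 amplitude = 25, knot_step = 5) {
  kind <- match.arg(kind)
  if (t_min >= t_max) stop("t_min must be < t_max", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  calbp <- seq(t_min, t_max, by = knot_step)
  if (calbp[length(calbp)] < t_max) calbp <- c(calbp, t_max)
  mu <- calbp
  if (kind == "wiggly") {
    # three incommensurate wavelengths; weights sum to 1 so the perturbation
    # is bounded by `amplitude` exactly
    ph <- with_seed(seed, stats::runif(3L, 0, 2 * pi))
    w <- c(0.5, 0.3, 0.2)
    wav <- c(731, 211, 67)
    pert <- amplitude * (
      w[1] * sin(2 * pi * calbp / wav[1] + ph[1]) +
      w[2] * sin(2 * pi * calbp / wav[2] + ph[2]) +
      w[3] * sin(2 * pi * calbp / wav[3] + ph[3]))
    mu <- calbp + pert
  }
  cal_curve(calbp, mu, rep(sigma, length(calbp)),
            name = sprintf("synthetic-%s", kind))
}

# Interpolate curve mean and error onto the integer-year calendar grid
# spanning its support (or a sub-interval of it).
curve_year_grid <- function(curve, t_min = NULL, t_max = NULL) {
  lo <- max(min(curve$calbp), if (is.null(t_min)) -Inf else t_min)
  hi <- min(max(curve$calbp), if (is.null(t_max)) Inf else t_max)
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  list(grid = grid,
       mu = stats::approx(curve$calbp, curve$c14age, xout = grid)$y,
       sigma = stats::approx(curve$calbp, curve$error, xout = grid)$y)
}

# Curve mean / error at arbitrary calendar ages (linear interpolation).
curve_mu_at <- function(curve, calbp) {
  if (any(calbp < min(curve$calbp)) || any(calbp > max(curve$calbp)))
    stop("calendar age outside curve support", call. = FALSE)
  stats::approx(curve$calbp, curve$c14age, xout = calbp)$y
}

curve_sigma_at <- function(curve, calbp) {
  stats::approx(curve$calbp, curve$error, xout = calbp)$y
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
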