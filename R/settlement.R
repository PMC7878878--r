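#' Convex hull of a point set
#'
#' Returns hull vertices in counter-clockwise order, collinear interior
#' points excluded. One- and two-point inputs (and fully collinear sets)
#' come back as degenerate hulls with zero area. The hull is pure planar
#' geometry; metric-CRS screening happens where files enter the pipeline
#' (see [read_sites_geojson()]).
#'
#' @param points two-column matrix or data.frame of (x, y) in meters.
#' @return matrix of hull vertices (counter-clockwise), class `"hull"`.
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (!nrow(pts)) stop("empty point set", call. = FALSE)
  if (any(!is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  pts <- unique(pts)
  if (nrow(pts) <= 2L) {
    colnames(pts) <- c("x", "y")
    return(structure(pts, class = c("hull", "matrix")))
  }
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])  # clockwise order
  hull <- pts[rev(idx), , drop = FALSE]          # counter-clockwise
  colnames(hull) <- c("x", "y")
  structure(hull, class = c("hull", "matrix"))
}

check_metric_crs <- function(pts) {
  # geographic lon/lat lives in [-180, 180] x [-90, 90]; a survey-scale site
  # footprint in meters essentially never fits that box, so refuse rather
  # than silently measure hectares in square degrees
  if (all(abs(pts[, 1L]) <= 180) && all(abs(pts[, 2L]) <= 90))
    stop(paste("coordinates look geographic (degrees);",
               "supply a projected metric CRS"), call. = FALSE)
  invisible(TRUE)
}

#' Area of a convex hull in hectares
#'
#' Shoelace (surveyor's) formula over the ordered vertices, divided by
#' 10,000 m^2/ha. Degenerate hulls (points, segments, collinear sets) have
#' area 0.
#'
#' @param hull result of [convex_hull()] (or any ordered simple polygon
#'   matrix with columns x, y, in meters).
#' @return area in hectares.
#' @export
hull_area_ha <- function(hull) {
  m <- unclass(as.matrix(hull))
  if (nrow(m) < 3L) return(0)
  x <- m[, 1L]; y <- m[, 2L]
  j <- c(2:nrow(m), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2 / 1e4
}

#' Ordinal settlement-intensity class from occupation area
#'
#' Classifies the convex-hull occupation area of a period into the ordinal
#' scale: `low` below 0.5 ha, `medium` from 0.5 to 1.0 ha (closed range,
#' both bounds inclusive), `high` above 1.0 ha; unoccupied periods are
#' `no_occupation` irrespective of area.
#'
#' @param area_ha occupation area in hectares (vectorised), >= 0.
#' @param occupied logical (recycled); FALSE forces `no_occupation`.
#' @return factor with levels `no_occupation < low < medium < high`.
#' @export
classify_intensity <- function(area_ha, occupied = TRUE) {
  if (any(area_ha < 0, na.rm = TRUE))
    stop("area_ha must be >= 0", call. = FALSE)
  occupied <- rep_len(occupied, length(area_ha))
  cls <- ifelse(!occupied, "no_occupation",
         ifelse(area_ha < 0.5, "low",
         ifelse(area_ha <= 1.0, "medium", "high")))
  factor(cls, levels = c("no_occupation", "low", "medium", "high"),
         ordered = TRUE)
}

#' Construct a site geometry
#'
#' @param period period label the site is attributed to.
#' @param site_id site identifier.
#' @param vertices two-column matrix/data.frame of (x, y) in meters.
#' @return list of class `site_geometry`.
#' @export
site_geometry <- function(period, site_id, vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (!nrow(v)) stop("site geometry needs >= 1 vertex", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite vertex", call. = FALSE)
  colnames(v) <- c("x", "y")
  structure(list(period = as.character(period)[1L],
                 site_id = as.character(site_id)[1L],
                 vertices = v),
            class = "site_geometry")
}

#' Period-by-period settlement occupation table
#'
#' For each defined period, pools the vertices of all that period's site
#' geometries, takes the convex hull (`method = "pooled"`, the default,
#' treating the settlement cluster as one occupation footprint) or sums
#' per-site hull areas (`method = "per_site"`), converts to hectares and
#' assigns the ordinal intensity class. Periods with no geometry get
#' `no_occupation` and area 0. The output has exactly one row per defined
#' period, in the order given.
#'
#' @param geometries list of [site_geometry] objects.
#' @param period_defs data.frame with columns `period`, `age_bp_lower`,
#'   `age_bp_upper` (lower >= upper, cal/years BP).
#' @param method `"pooled"` or `"per_site"`.
#' @return data.frame with columns `period`, `age_bp_lower`, `age_bp_upper`,
#'   `n_sites`, `area_ha`, `intensity`.
#' @export
tabulate_periods <- function(geometries, period_defs,
                             method = c("pooled", "per_site")) {
  method <- match.arg(method)
  stopifnot(all(c("period", "age_bp_lower", "age_bp_upper") %in%
                  names(period_defs)))
  if (any(period_defs$age_bp_lower < period_defs$age_bp_upper))
    stop("age_bp_lower must be >= age_bp_upper (cal BP, older first)",
         call. = FALSE)
  geo_periods <- vapply(geometries, `[[`, character(1), "period")
  unknown <- setdiff(geo_periods, period_defs$period)
  if (length(unknown))
    stop("geometry with unknown period label: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  out <- period_defs[, c("period", "age_bp_lower", "age_bp_upper")]
  out$n_sites <- 0L; out$area_ha <- 0
  for (i in seq_len(nrow(out))) {
    sel <- geometries[geo_periods == out$period[i]]
    out$n_sites[i] <- length(sel)
    if (!length(sel)) next
    if (method == "pooled") {
      verts <- do.call(rbind, lapply(sel, `[[`, "vertices"))
      out$area_ha[i] <- hull_area_ha(convex_hull(verts))
    } else {
      out$area_ha[i] <- sum(vapply(sel, function(s)
        hull_area_ha(convex_hull(s$vertices)), numeric(1)))
    }
  }
  out$intensity <- classify_intensity(out$area_ha, occupied = out$n_sites > 0)
  out
}

#' Ein Gedi oasis settlement chronology
#'
#' Reference period table for the Ein Gedi case study: thirteen historical
#' periods spanning the Late Neolithic to the Ottoman era, with age ranges
#' (years BP), published convex-hull occupation areas (ha) where occupied,
#' the separate maximum-extent areas reported for the Roman and Byzantine
#' peaks, and the ordinal intensity classes. The Ottoman row is flagged
#' `consistent = FALSE`: its printed area and class disagree with the
#' stated thresholds, so it is carried for completeness but excluded from
#' numerical checks.
#'
#' @return data.frame with columns `period`, `age_bp_lower`, `age_bp_upper`,
#'   `area_ha`, `max_area_ha`, `intensity`, `consistent`.
#' @export
ein_gedi_periods <- function() {
  df <- data.frame(
    period = c("Late Neolithic", "Chalcolithic", "Bronze Age",
               "Iron Age I-IIB", "Iron Age IIC", "Persian", "Hellenistic",
               "Roman", "Byzantine", "Early Islamic", "Crusader", "Mamluk",
               "Ottoman"),
    age_bp_lower = c(8350, 6450, 5750, 3100, 2651, 2536, 2283,
                     1887, 1626, 1322, 851, 659, 433),
    age_bp_upper = c(6450, 5750, 3100, 2651, 2536, 2283, 1887,
                     1626, 1322, 851, 659, 433, 33),
    area_ha = c(NA, 0.04, NA, NA, 0.53, 0.88, 0.17,
                1.58, 2.60, NA, NA, 0.54, 3),
    max_area_ha = c(NA, NA, NA, NA, NA, NA, NA, 27.75, 5.91, NA, NA, NA, NA),
    intensity = c("no_occupation", "low", "no_occupation", "no_occupation",
                  "medium", "medium", "low", "high", "high",
                  "no_occupation", "no_occupation", "medium", "low"),
    consistent = c(rep(TRUE, 12), FALSE),
    stringsAsFactors = FALSE)
  df
}

#' Read site geometries from GeoJSON
#'
#' Accepts a FeatureCollection of Point, Polygon or MultiPolygon features in
#' a projected metric CRS. Each feature must carry `period` and `site_id`
#' properties. Polygon holes are ignored (only exterior rings matter for a
#' convex hull). Files whose coordinates fit inside the geographic
#' longitude/latitude box are refused: hull areas in hectares require a
#' metric CRS.
#'
#' @param path path to a GeoJSON file.
#' @return list of [site_geometry] objects.
#' @export
read_sites_geojson <- function(path) {
  if (!file.exists(path))
    stop("sites file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  out <- lapply(gj$features, function(f) {
    props <- f$properties
    if (is.null(props$period) || is.null(props$site_id))
      stop("feature missing 'period' or 'site_id' property", call. = FALSE)
    geom <- f$geometry
    drop_closing <- function(m) {
      if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ]))
        m[-nrow(m), , drop = FALSE] else m
    }
    verts <- switch(geom$type,
      Point = matrix(unlist(geom$coordinates), ncol = 2, byrow = TRUE),
      Polygon = drop_closing(do.call(rbind, lapply(geom$coordinates[[1L]],
                                      function(p) unlist(p)[1:2]))),
      MultiPolygon = do.call(rbind, unlist(lapply(geom$coordinates,
        function(poly) lapply(poly[[1L]], function(p) unlist(p)[1:2])),
        recursive = FALSE)),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    site_geometry(props$period, props$site_id, verts)
  })
  check_metric_crs(do.call(rbind, lapply(out, `[[`, "vertices")))
  out
}

#' Write site geometries to GeoJSON
#'
#' @param geometries list of [site_geometry] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_geojson <- function(geometries, path) {
  feats <- lapply(geometries, function(g) {
    v <- g$vertices
    if (nrow(v) == 1L) {
      geom <- list(type = "Point", coordinates = as.numeric(v[1L, ]))
    } else {
      ring <- lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
      ring <- c(ring, ring[1L])  # closed ring
      geom <- list(type = "Polygon", coordinates = list(ring))
    }
    list(type = "Feature",
         properties = list(period = g$period, site_id = g$site_id),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
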