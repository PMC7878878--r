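#' Load a specimen table
#'
#' Reads a CSV with one row per dated specimen. Required columns:
#' `specimen_id`, `site_id`, `taxon`, `c14_age`, `c14_error`, `fraction`.
#' Additional columns are kept.
#'
#' @param path path to the CSV file.
#' @return data.frame of specimen records.
#' @export
load_specimens <- function(path) {
  if (!file.exists(path))
    stop("specimen file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_specimens(df)
}

validate_specimens <- function(df) {
  need <- c("specimen_id", "site_id", "taxon", "c14_age", "c14_error", "fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimen table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$c14_age) | !is.finite(df$c14_error))
  if (length(bad))
    stop("non-numeric or missing age/error in specimen row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    stop("duplicated specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(df$c14_error <= 0))
    stop("c14_error must be > 0 for every specimen", call. = FALSE)
  if (any(!nzchar(df$taxon)))
    stop("empty taxon label", call. = FALSE)
  df
}

#' Calibrate every specimen in a table
#'
#' Adds per-specimen calibration results: a `status` column
#' (calibrated/modern/beyond_range), the calibrated `median_calbp`, and a
#' `density` list-column holding each specimen's [calibrate_date()] result.
#'
#' @param records specimen data.frame (see [load_specimens()]).
#' @param curve a [cal_curve].
#' @param level HPD level (default 0.954).
#' @param ... further arguments passed to [calibrate_date()].
#' @return the input data.frame with `status`, `median_calbp` and `density`
#'   columns.
#' @export
calibrate_specimens <- function(records, curve, level = 0.954, ...) {
  records <- validate_specimens(records)
  dens <- lapply(seq_len(nrow(records)), function(i) {
    d <- uncal_date(records$specimen_id[i], records$c14_age[i],
                    records$c14_error[i],
                    fraction_or_unknown(records$fraction[i]))
    calibrate_date(d, curve, level = level, ...)
  })
  names(dens) <- records$specimen_id
  records$status <- vapply(dens, `[[`, character(1), "status")
  records$median_calbp <- vapply(dens, `[[`, numeric(1), "median")
  records$density <- I(dens)
  records
}

fraction_or_unknown <- function(x) {
  if (x %in% c("collagen", "bioapatite", "scat")) x else "unknown"
}

# HPD intervals of a specimen's density as a two-column matrix (old, young).
specimen_hpd <- function(density) {
  as.matrix(density$hpd[, c("old", "young"), drop = FALSE])
}

intervals_overlap <- function(a, b) {
  # a, b: matrices of (old, young) closed intervals; any pairwise overlap?
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a[i, "young"] <= b[j, "old"] && b[j, "young"] <= a[i, "old"])
        return(TRUE)
  FALSE
}

#' Minimum number of individuals from chronological clustering
#'
#' Specimens of one taxon recovered at the same site and dated to equivalent
#' calibrated 2-sigma intervals are taken to represent a single individual.
#' "Equivalent" is operationalised as overlapping HPD intervals (the
#' `"overlap"` rule, default): within each site, two calibrated specimens are
#' linked when any of their HPD intervals intersect, and clusters are the
#' transitive closure (single linkage). The stricter `"containment"` rule
#' links two specimens only when each one's calibrated median falls inside
#' the other's HPD set. Modern and beyond-range specimens demonstrably
#' differ in age from all calibrated ones and count as singleton clusters.
#'
#' @param records calibrated specimen table (see [calibrate_specimens()]).
#' @param taxon taxon label to summarise.
#' @param level HPD level used for the clustering intervals.
#' @param rule `"overlap"` (default) or `"containment"`.
#' @return list with `taxon`, `nisp`, `mni`, and `clusters` (list of
#'   specimen-id character vectors partitioning the taxon's specimens).
#' @export
assign_mni_clusters <- function(records, taxon, level = 0.954,
                                rule = c("overlap", "containment")) {
  rule <- match.arg(rule)
  stopifnot(!is.null(records$density))
  rows <- records[records$taxon == taxon, , drop = FALSE]
  if (!nrow(rows))
    return(list(taxon = taxon, nisp = 0L, mni = 0L, clusters = list()))

  clusters <- list()
  uncal <- rows$status != "calibrated"
  for (id in rows$specimen_id[uncal]) clusters <- c(clusters, list(id))

  cal <- rows[!uncal, , drop = FALSE]
  for (site in unique(cal$site_id)) {
    sub <- cal[cal$site_id == site, , drop = FALSE]
    n <- nrow(sub)
    hp <- lapply(sub$density, function(d) {
      h <- hpd_from_probs(d$grid, d$prob, level)
      as.matrix(h[, c("old", "young"), drop = FALSE])
    })
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        linked <- if (rule == "overlap") {
          intervals_overlap(hp[[i]], hp[[j]])
        } else {
          median_in(sub$density[[i]]$median, hp[[j]]) &&
            median_in(sub$density[[j]]$median, hp[[i]])
        }
        if (linked) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots))
      clusters <- c(clusters, list(sub$specimen_id[roots == r]))
  }
  list(taxon = taxon, nisp = nrow(rows), mni = length(clusters),
       clusters = clusters)
}

median_in <- function(m, intervals) {
  any(intervals[, "young"] <= m & m <= intervals[, "old"])
}

#' Group dates into site-wise bins
#'
#' Single-linkage agglomerative clustering of uncalibrated 14C ages within
#' each site (and taxon: bins never mix taxa, since they are the units whose
#' taxon marks get reshuffled in the permutation test), with cutoff `h`:
#' dates at one site belong to the same bin when they can be chained through
#' gaps of at most `h` 14C yr. `h = 0` merges only exactly equal ages.
#' Only calibrated specimens are binned when a `status` column is present.
#'
#' @param records specimen table.
#' @param h clustering cutoff in 14C yr (>= 0).
#' @return An object of class `bin_set`: list with `h`, `bins` (list of
#'   specimen-id vectors), `taxon` and `site` (per-bin labels), `n_bins`.
#' @export
make_bins <- function(records, h = 100) {
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  if (!is.null(records$status))
    records <- records[records$status == "calibrated", , drop = FALSE]
  bins <- list(); btax <- character(0); bsite <- character(0)
  if (nrow(records)) {
    key <- interaction(records$site_id, records$taxon, drop = TRUE)
    for (g in levels(key)) {
      sub <- records[key == g, , drop = FALSE]
      ord <- order(sub$c14_age)
      ages <- sub$c14_age[ord]; ids <- sub$specimen_id[ord]
      cut <- if (length(ages) > 1L) which(diff(ages) > h) else integer(0)
      starts <- c(1L, cut + 1L); ends <- c(cut, length(ages))
      for (b in seq_along(starts)) {
        bins <- c(bins, list(ids[starts[b]:ends[b]]))
        btax <- c(btax, sub$taxon[1L]); bsite <- c(bsite, sub$site_id[1L])
      }
    }
  }
  structure(list(h = h, bins = bins, taxon = btax, site = bsite,
                 n_bins = length(bins)),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set: %d bins from %d dates, h = %g 14C yr>\n",
              x$n_bins, sum(lengths(x$bins)), x$h))
  invisible(x)
}

#' First and last appearance of a taxon
#'
#' FAD is the oldest and LAD the youngest calibrated point estimate of the
#' taxon's dated specimens. With `mode = "median"` (default) the point
#' estimate is the calibrated median; with `mode = "bound"` the FAD uses the
#' old edge of the oldest specimen's outermost HPD interval and the LAD the
#' young edge of the youngest one's. Modern and beyond-range specimens are
#' counted but never enter FAD/LAD.
#'
#' @param records calibrated specimen table.
#' @param taxon taxon label.
#' @param mode `"median"` or `"bound"`.
#' @return list with `taxon`, `fad`, `lad` (cal BP; `NA` with
#'   `defined = FALSE` when no specimen is calibrated), `n_calibrated`,
#'   `n_modern`, `n_beyond`, `defined`.
#' @export
fad_lad <- function(records, taxon, mode = c("median", "bound")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(records$status))
  rows <- records[records$taxon == taxon, , drop = FALSE]
  n_mod <- sum(rows$status == "modern")
  n_bey <- sum(rows$status == "beyond_range")
  cal <- rows[rows$status == "calibrated", , drop = FALSE]
  if (!nrow(cal)) {
    return(list(taxon = taxon, fad = NA_real_, lad = NA_real_,
                n_calibrated = 0L, n_modern = n_mod, n_beyond = n_bey,
                defined = FALSE))
  }
  meds <- cal$median_calbp
  if (mode == "median") {
    fad <- max(meds); lad <- min(meds)
  } else {
    oldest <- cal$density[[which.max(meds)]]
    youngest <- cal$density[[which.min(meds)]]
    fad <- max(oldest$hpd$old); lad <- min(youngest$hpd$young)
  }
  list(taxon = taxon, fad = fad, lad = lad,
       n_calibrated = nrow(cal), n_modern = n_mod, n_beyond = n_bey,
       defined = TRUE)
}

#' Fraction of a taxon's dates younger than a threshold
#'
#' Counts calibrated specimens whose median is strictly younger than
#' `threshold` cal BP (a record whose median equals the threshold exactly is
#' excluded — documented strict rule).
#'
#' @param records calibrated specimen table.
#' @param taxon taxon label.
#' @param threshold cal BP cut.
#' @return list with `k` (younger than threshold), `n` (calibrated total),
#'   `fraction`.
#' @export
fraction_after <- function(records, taxon, threshold) {
  stopifnot(!is.null(records$status))
  cal <- records[records$taxon == taxon & records$status == "calibrated", ,
                 drop = FALSE]
  if (!nrow(cal))
    stop("no calibrated records for taxon ", taxon, call. = FALSE)
  k <- sum(cal$median_calbp < threshold)
  list(k = k, n = nrow(cal), fraction = k / nrow(cal))
}

#' Default taxon-to-group mapping for carnivore assemblages
#'
#' Maps species labels onto the three reporting groups used throughout:
#' leopard (*Panthera*), hyena (*Hyaena*), fox (*Vulpes*, both species).
#'
#' @param taxon character vector of taxon labels.
#' @return character vector of `"leopard"`, `"hyena"`, `"fox"` or `"other"`.
#' @export
taxon_group <- function(taxon) {
  out <- rep("other", length(taxon))
  out[grepl("Panthera|leopard", taxon, ignore.case = TRUE)] <- "leopard"
  out[grepl("Hyaena|hyena", taxon, ignore.case = TRUE)] <- "hyena"
  out[grepl("Vulpes|fox", taxon, ignore.case = TRUE)] <- "fox"
  out
}

#' Per-site taxonomic composition
#'
#' Relative proportions of the leopard / hyena / fox groups among the
#' specimens recovered at each site; proportions sum to 1 at every site with
#' at least one grouped specimen.
#'
#' @param records specimen table.
#' @param groups optional custom mapping function from taxon labels to group
#'   names (defaults to [taxon_group()]); specimens mapped to `"other"` are
#'   dropped.
#' @return data.frame with columns `site_id`, `leopard`, `hyena`, `fox`, `n`.
#' @export
cave_composition <- function(records, groups = taxon_group) {
  g <- groups(records$taxon)
  keep <- g != "other"
  records <- records[keep, , drop = FALSE]; g <- g[keep]
  sites <- sort(unique(records$site_id))
  out <- data.frame(site_id = sites,
                    leopard = 0, hyena = 0, fox = 0, n = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    gi <- g[records$site_id == sites[i]]
    out$n[i] <- length(gi)
    for (grp in c("leopard", "hyena", "fox"))
      out[[grp]][i] <- mean(gi == grp)
  }
  out
}
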