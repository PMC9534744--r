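#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Used for every
#' distance in the pipeline (buffers, rarefaction, Ripley's K); the source
#' analysis used projected GIS tools with an unstated metric, and the
#' spherical great-circle distance is this package's documented stand-in.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

# Pairwise distance matrix (km) between two point sets.
cross_dist_km <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(matrix(numeric(), nrow(a), nrow(b)))
  geosphere::distm(as.matrix(a[, c("lon", "lat")]),
                   as.matrix(b[, c("lon", "lat")]),
                   fun = function(p1, p2)
                     geosphere::distHaversine(p1, p2, r = 6371.0088))
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting over all rings of a [range_polygon()]. Points on an edge
#' follow the half-open convention of the ray casting (stable, documented
#' as implementation-defined for degenerate on-boundary points).
#'
#' @param lon,lat point coordinates (vectorised).
#' @param poly a `range_polygon`; empty polygon contains nothing.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  stopifnot(inherits(poly, "range_polygon"))
  inside <- rep(FALSE, length(lon))
  for (p in unclass(poly)) for (r in p) {
    x <- r[, 1]; y <- r[, 2]
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((y[i] > lat) != (y[j] > lat)) &
        (lon < (x[j] - x[i]) * (lat - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, crosses & !is.na(crosses))
      j <- i
    }
  }
  inside
}

#' Screen historical records for extinction occurrences
#'
#' A 1970-2000 historical record is flagged `outside_range` when it falls
#' outside the current-range polygon, and `outside_buffers` when it lies
#' more than `buffer_km` from every extant record (vacuously true when no
#' extant records exist). The final extinction set is the conjunction:
#' `is_extinction = outside_range & outside_buffers`. All three counts are
#' reported, because the two marginal bins overlap; downstream stages use
#' only the conjunction.
#'
#' @param historical occurrence data.frame (the 1970-2000 window).
#' @param extant occurrence data.frame of extant records (may be empty).
#' @param range_poly a [range_polygon()] (may be empty).
#' @param buffer_km buffer radius around each extant record, km.
#' @return list with `records` (historical plus logical columns
#'   `outside_range`, `outside_buffers`, `is_extinction`) and `counts`
#'   (named: `outside_range`, `outside_buffers`, `extinction`, `total`).
#' @export
screen_extinctions <- function(historical, extant, range_poly, buffer_km) {
  stopifnot(buffer_km > 0)
  rec <- historical
  if (nrow(rec) == 0) {
    rec$outside_range <- logical(); rec$outside_buffers <- logical()
    rec$is_extinction <- logical()
    return(list(records = rec,
                counts = c(outside_range = 0L, outside_buffers = 0L,
                           extinction = 0L, total = 0L)))
  }
  rec$outside_range <- !point_in_polygon(rec$lon, rec$lat, range_poly)
  if (nrow(extant) == 0) {
    rec$outside_buffers <- rep(TRUE, nrow(rec))
  } else {
    d <- cross_dist_km(rec, extant)
    rec$outside_buffers <- apply(d, 1, min) > buffer_km
  }
  rec$is_extinction <- rec$outside_range & rec$outside_buffers
  list(records = rec,
       counts = c(outside_range = sum(rec$outside_range),
                  outside_buffers = sum(rec$outside_buffers),
                  extinction = sum(rec$is_extinction),
                  total = nrow(rec)))
}

#' Spatial rarefaction of records
#'
#' Deterministic greedy thinning in ascending record-id order: a record is
#' kept iff it lies at least `min_km` from every already-kept record; a
#' second pass then enforces at most one record per `cell_arcmin` grid
#' cell (lowest id wins). Idempotent.
#'
#' @param records occurrence data.frame with `id`, `lon`, `lat`.
#' @param min_km minimum pairwise distance retained, km.
#' @param cell_arcmin dedup cell size in arc-minutes (default 5, the
#'   resolution of the risk-model environmental layers).
#' @param order `"id"` (default, deterministic) or `"random"` (seeded
#'   shuffle, mirroring thinning tools that randomise the scan order).
#' @param seed seed for `order = "random"`.
#' @return the kept subset of `records` (original row order).
#' @export
rarefy <- function(records, min_km, cell_arcmin = 5,
                   order = c("id", "random"), seed = 1L) {
  order <- match.arg(order)
  stopifnot(min_km > 0)
  if (nrow(records) <= 1) return(records)
  ord <- order(records$id)
  if (order == "random")
    ord <- with_seed(seed, sample(nrow(records)))
  kept_idx <- integer()
  for (i in ord) {
    if (length(kept_idx)) {
      d <- haversine_km(records$lon[i], records$lat[i],
                        records$lon[kept_idx], records$lat[kept_idx])
      if (any(d < min_km)) next
    }
    kept_idx <- c(kept_idx, i)
  }
  kept <- records[sort(kept_idx), , drop = FALSE]
  # one record per cell_arcmin cell, lowest id wins
  cell <- paste(floor(kept$lon * 60 / cell_arcmin),
                floor(kept$lat * 60 / cell_arcmin))
  first <- !duplicated(cell[order(kept$id)])[order(order(kept$id))]
  out <- kept[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ripley's K function with a CSR envelope
#'
#' Unadjusted estimator (no edge correction):
#' `Khat(r) = (A / n^2) * sum_{i != j} 1[d_ij <= r]`, distances by
#' great-circle km and `A` the study-area size in km^2. A Monte-Carlo
#' envelope under complete spatial randomness is built from `n_sims`
#' uniform point sets of the same size in the study rectangle.
#'
#' @param records data.frame with `lon`, `lat` (>= 2 rows).
#' @param radii evaluation radii, km.
#' @param bbox study rectangle `c(lon_min, lon_max, lat_min, lat_max)`;
#'   default the records' bounding box.
#' @param n_sims envelope simulations (default 99).
#' @param seed envelope seed.
#' @return object of class `kfunction`: data.frame with `r`, `khat`,
#'   `csr` (`pi r^2`), `l_minus_r`, `env_lo`, `env_hi`; attributes `area`
#'   (km^2) and `n`.
#' @export
ripley_k <- function(records, radii, bbox = NULL, n_sims = 99, seed = 1L) {
  n <- nrow(records)
  if (n < 2) stop("Ripley's K needs at least 2 points")
  if (is.null(bbox))
    bbox <- c(range(records$lon), range(records$lat))
  area <- bbox_area_km2(bbox)
  khat_of <- function(pts) {
    d <- cross_dist_km(pts, pts)
    diag(d) <- Inf
    m <- nrow(pts)
    vapply(radii, function(r) (area / m^2) * sum(d <= r), 0)
  }
  khat <- khat_of(records)
  env <- with_seed(seed, {
    sims <- replicate(n_sims, {
      pts <- data.frame(lon = stats::runif(n, bbox[1], bbox[2]),
                        lat = stats::runif(n, bbox[3], bbox[4]))
      khat_of(pts)
    })
    if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1)
    list(lo = apply(sims, 1, min), hi = apply(sims, 1, max))
  })
  out <- data.frame(r = radii, khat = khat, csr = pi * radii^2,
                    l_minus_r = sqrt(khat / pi) - radii,
                    env_lo = env$lo, env_hi = env$hi)
  attr(out, "area") <- area
  attr(out, "n") <- n
  class(out) <- c("kfunction", "data.frame")
  out
}

# Area of a lon/lat rectangle in km^2 (spherical zone formula).
bbox_area_km2 <- function(bbox) {
  R <- 6371.0088
  dlon <- (bbox[2] - bbox[1]) * pi / 180
  R^2 * dlon * abs(sin(bbox[4] * pi / 180) - sin(bbox[3] * pi / 180))
}
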