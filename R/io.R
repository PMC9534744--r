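#' Read an occurrence table
#'
#' Occurrence CSVs carry one dated, georeferenced sighting per row with
#' columns `id, lon, lat, year, source` (`source` is `"historical"` or
#' `"extant"`). Rows with missing or out-of-range coordinates or an
#' unparseable year are rejected, collected with their row numbers, and
#' attached to the result as the `"rejected"` attribute rather than being
#' silently dropped.
#'
#' @param path CSV file path. CRLF line endings and quoted fields parse to
#'   the same records as plain LF/unquoted files.
#' @return data.frame of valid records (`id, lon, lat, year, source`) with
#'   attribute `rejected`: data.frame of `row` (1-based data row) and
#'   `reason` for every rejected input row.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "lon", "lat", "year", "source")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("occurrence file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  year <- suppressWarnings(as.numeric(raw$year))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(year)] <- "unparseable year"
  reason[is.na(lat) | lat < -90 | lat > 90] <- "latitude out of range"
  reason[is.na(lon) | lon < -180 | lon > 180] <- "longitude out of range"
  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), reason = reason[bad],
                         stringsAsFactors = FALSE)
  out <- data.frame(id = raw$id[!bad], lon = lon[!bad], lat = lat[!bad],
                    year = year[!bad], source = raw$source[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Write an occurrence table
#'
#' Inverse of [read_occurrences()] on valid records (round-trip identity).
#'
#' @param occ data.frame with columns `id, lon, lat, year, source`.
#' @param path output CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("id", "lon", "lat", "year", "source")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- ESRI ASCII grid rasters -------------------------------------------

#' Read one ESRI ASCII grid layer
#'
#' @param path `.asc` file. Header keys `ncols nrows xllcorner yllcorner
#'   cellsize NODATA_value` followed by rows listed north to south.
#' @return list with `values` (matrix `n_x` columns x `n_y` rows, indexed
#'   `[ix, iy]` with `iy = 1` the southernmost row; NA where nodata) and
#'   `grid` (a [grid_spec()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  nx <- hdr[["ncols"]]; ny <- hdr[["nrows"]]
  if (length(vals) != nx * ny)
    stop("value count does not match header in ", path)
  # file rows run north->south; flip into south-origin [ix, iy] indexing
  m <- matrix(vals, nrow = nx, ncol = ny)[, ny:1, drop = FALSE]
  m[m == hdr[["nodata_value"]]] <- NA_real_
  list(values = m,
       grid = grid_spec(hdr[["xllcorner"]], hdr[["yllcorner"]],
                        hdr[["cellsize"]], nx, ny))
}

#' Write one ESRI ASCII grid layer
#'
#' @param values matrix indexed `[ix, iy]`, `iy = 1` southernmost.
#' @param grid a [grid_spec()].
#' @param path output path.
#' @param nodata value written for NA cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid$n_x, ncol(values) == grid$n_y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_x),
               sprintf("nrows %d", grid$n_y),
               sprintf("xllcorner %.10g", grid$origin_lon),
               sprintf("yllcorner %.10g", grid$origin_lat),
               sprintf("cellsize %.10g", grid$cell_degrees),
               sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  for (iy in grid$n_y:1)
    writeLines(paste(formatC(v[, iy], format = "g", digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' Assemble a covariate stack from raster layers
#'
#' A covariate stack is the pipeline's raster container: named layers on a
#' shared grid, each with one or more time slices. The nodata mask is the
#' union of nodata cells across all layers and slices.
#'
#' @param paths named list; one character vector of `.asc` paths (the time
#'   slices, in order) per layer name.
#' @return an object of class `covariate_stack`: list with `grid`
#'   ([grid_spec()]), `layers` (named list of `n_x x n_y x n_slices`
#'   arrays), `n_slices`, and `nodata` (logical `n_x x n_y` union mask).
#' @export
read_raster_stack <- function(paths) {
  stopifnot(is.list(paths), !is.null(names(paths)))
  layers <- list(); grid <- NULL; n_slices <- NULL
  for (nm in names(paths)) {
    slices <- lapply(paths[[nm]], read_ascii_grid)
    for (s in slices) {
      if (is.null(grid)) grid <- s$grid
      else if (!isTRUE(all.equal(unclass(grid), unclass(s$grid))))
        stop("layer '", nm, "' is not aligned with the stack grid")
    }
    if (is.null(n_slices)) n_slices <- length(slices)
    else if (length(slices) != n_slices)
      stop("layer '", nm, "' has ", length(slices),
           " slices; expected ", n_slices)
    layers[[nm]] <- array(unlist(lapply(slices, `[[`, "values")),
                          dim = c(grid$n_x, grid$n_y, n_slices))
  }
  covariate_stack(layers, grid)
}

#' Build a covariate stack in memory
#'
#' @param layers named list of `n_x x n_y x n_slices` arrays (matrices are
#'   promoted to one slice).
#' @param grid a [grid_spec()].
#' @return a `covariate_stack` (see [read_raster_stack()]).
#' @export
covariate_stack <- function(layers, grid) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  layers <- lapply(layers, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1))
    stopifnot(dim(a)[1] == grid$n_x, dim(a)[2] == grid$n_y)
    a
  })
  ns <- unique(vapply(layers, function(a) dim(a)[3], 0))
  if (length(ns) != 1)
    stop("all layers must share the slice count; got: ",
         paste(ns, collapse = ", "))
  nodata <- Reduce(`|`, lapply(layers, function(a)
    apply(is.na(a), c(1, 2), any)))
  structure(list(grid = grid, layers = layers, n_slices = ns,
                 nodata = nodata),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layer(s) x %d slice(s) on %d x %d grid; %d nodata cell(s)\n",
              length(x$layers), x$n_slices, x$grid$n_x, x$grid$n_y,
              sum(x$nodata)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Write a covariate stack as ESRI ASCII grids
#'
#' Files are named `<layer>_<slice>.asc` under `dir`.
#'
#' @param stack a `covariate_stack`.
#' @param dir output directory (created if absent).
#' @return named list of written paths, suitable for [read_raster_stack()].
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (nm in names(stack$layers)) {
    out[[nm]] <- vapply(seq_len(stack$n_slices), function(s) {
      p <- file.path(dir, sprintf("%s_%02d.asc", nm, s))
      write_ascii_grid(stack$layers[[nm]][, , s], stack$grid, p)
      p
    }, "")
  }
  invisible(out)
}

#' Average a stack over the slices of one period
#'
#' @param stack a `covariate_stack` whose slices tile the study window.
#' @param slice_idx integer vector of slice indices to average.
#' @return named list of `n_x x n_y` matrices (one per layer), NA on the
#'   union nodata mask.
#' @export
stack_slice_mean <- function(stack, slice_idx) {
  stopifnot(all(slice_idx >= 1), all(slice_idx <= stack$n_slices))
  out <- lapply(stack$layers, function(a) {
    m <- apply(a[, , slice_idx, drop = FALSE], c(1, 2), mean)
    m[stack$nodata] <- NA_real_
    m
  })
  out
}

## ---- GeoJSON polygons ---------------------------------------------------

#' Read a range polygon from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry (bare geometry, Feature,
#' or single-feature FeatureCollection), WGS84 coordinates.
#'
#' @param path GeoJSON file.
#' @return object of class `range_polygon`: list of polygons, each a list
#'   of rings, each ring a 2-column matrix of (lon, lat). Empty geometries
#'   yield a zero-length list.
#' @export
read_range_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(g$type) && g$type == "FeatureCollection") {
    if (length(g$features) == 0) return(range_polygon(list()))
    g <- g$features[[1]]
  }
  if (!is.null(g$type) && g$type == "Feature") g <- g$geometry
  ring_mat <- function(r)
    matrix(unlist(r), ncol = 2, byrow = TRUE)
  polys <- switch(g$type,
    Polygon = list(lapply(g$coordinates, ring_mat)),
    MultiPolygon = lapply(g$coordinates, function(p) lapply(p, ring_mat)),
    stop("unsupported GeoJSON geometry type: ", g$type))
  range_polygon(polys)
}

#' Construct a range polygon
#'
#' @param polys list of polygons; each polygon a list of rings; each ring a
#'   2-column (lon, lat) matrix. Rings need not be explicitly closed.
#' @return a `range_polygon` object.
#' @export
range_polygon <- function(polys) {
  for (p in polys) for (r in p)
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      stop("invalid polygon ring: need a 2-column matrix with >= 3 vertices")
  structure(polys, class = "range_polygon")
}

#' Write a range polygon as GeoJSON (MultiPolygon)
#'
#' @param poly a `range_polygon`.
#' @param path output file.
#' @export
write_range_polygon <- function(poly, path) {
  coords <- lapply(unclass(poly), function(p) lapply(p, function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }))
  obj <- list(type = "MultiPolygon", coordinates = coords)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("range_polygon: %d polygon(s), %d ring(s)\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
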