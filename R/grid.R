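#' Analysis grid specification
#'
#' A regular longitude/latitude grid of square cells. Cells are half-open
#' rectangles `[west, east) x [south, north)`; points landing exactly on the
#' east or north edge of the whole domain are assigned to the last cell so
#' the cell map covers the closed domain.
#'
#' @param origin_lon,origin_lat south-west corner of the grid, degrees.
#' @param cell_degrees cell edge length, degrees (> 0).
#' @param n_x,n_y number of cells east-/northwards.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_degrees, n_x, n_y) {
  stopifnot(cell_degrees > 0, n_x >= 1, n_y >= 1)
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_degrees = cell_degrees,
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, origin (%g, %g)\n",
              x$n_x, x$n_y, x$cell_degrees, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Assign points to grid cells
#'
#' @param lon,lat coordinate vectors, degrees.
#' @param grid a [grid_spec()].
#' @param ids optional record identifiers used in error messages.
#' @return integer cell ids, counted row-major from the south-west cell
#'   (cell 1 = column 1, row 1); `cell_id = (iy - 1) * n_x + ix`.
#' @export
assign_cell <- function(lon, lat, grid, ids = NULL) {
  ix <- floor((lon - grid$origin_lon) / grid$cell_degrees) + 1
  iy <- floor((lat - grid$origin_lat) / grid$cell_degrees) + 1
  east <- grid$origin_lon + grid$n_x * grid$cell_degrees
  north <- grid$origin_lat + grid$n_y * grid$cell_degrees
  # closed east/north domain edge folds into the last cell
  ix[lon == east] <- grid$n_x
  iy[lat == north] <- grid$n_y
  out <- ix < 1 | ix > grid$n_x | iy < 1 | iy > grid$n_y |
    !is.finite(lon) | !is.finite(lat)
  if (any(out)) {
    which_bad <- if (is.null(ids)) which(out) else ids[out]
    stop("point(s) outside grid domain: ",
         paste(utils::head(which_bad, 10), collapse = ", "))
  }
  as.integer((iy - 1) * grid$n_x + ix)
}

#' Cell centre coordinates
#'
#' @param cell_id integer cell ids as produced by [assign_cell()].
#' @param grid a [grid_spec()].
#' @return data.frame with `lon`, `lat` of each cell centre.
#' @export
cell_center <- function(cell_id, grid) {
  ix <- (cell_id - 1L) %% grid$n_x + 1L
  iy <- (cell_id - 1L) %/% grid$n_x + 1L
  data.frame(
    lon = grid$origin_lon + (ix - 0.5) * grid$cell_degrees,
    lat = grid$origin_lat + (iy - 0.5) * grid$cell_degrees)
}

#' Period specification
#'
#' Half-open periods `[start, start + length)` tiling the study window.
#'
#' @param start_year first year of the window, AD.
#' @param length_years period length, years.
#' @param n_periods number of periods.
#' @return an object of class `period_spec`.
#' @export
period_spec <- function(start_year, length_years, n_periods) {
  stopifnot(length_years > 0, n_periods >= 1)
  structure(list(start_year = start_year, length_years = length_years,
                 n_periods = as.integer(n_periods)),
            class = "period_spec")
}

#' Assign years to periods
#'
#' @param year numeric vector of years AD.
#' @param periods a [period_spec()].
#' @return integer period indices starting at 1.
#' @export
bin_period <- function(year, periods) {
  idx <- floor((year - periods$start_year) / periods$length_years) + 1
  bad <- idx < 1 | idx > periods$n_periods | !is.finite(year)
  if (any(bad))
    stop("year(s) outside study window: ",
         paste(utils::head(year[bad], 10), collapse = ", "))
  as.integer(idx)
}

period_from_config <- function(cfg) {
  period_spec(cfg$study_start, cfg$period_years,
              (cfg$study_end - cfg$study_start) %/% cfg$period_years)
}
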