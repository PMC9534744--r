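#' Simulation parameters
#'
#' Parameters of the synthetic chronicle generator. The generator emulates
#' the structure of the real inputs: dated sightings over a 300-year window
#' whose per-cell disappearance hazard is a logistic function of a rising
#' temperature proxy and human-population covariates, a set of recent
#' extant records, and a current-range polygon.
#'
#' Defaults are the study conditions used throughout the package's own
#' experiments: a 20 x 20 cell grid (400 cells, giving on the order of 800
#' fate rows), ten 30-year periods with three 10-year covariate slices per
#' period, a standardized temperature effect of 1 on the log-odds of
#' extinction, a weaker population effect, a smooth low-frequency spatial
#' term, imperfect detection, and 159 extant records.
#'
#' @param n_cells_x,n_cells_y grid dimensions (cells).
#' @param n_periods number of fate periods (>= 2).
#' @param slices_per_period covariate slices per period (10-year inputs
#'   inside 30-year periods in the emulated data).
#' @param beta0 log-odds intercept of the per-period extinction hazard.
#' @param beta_temp log-odds per unit standardized temperature proxy.
#' @param beta_pop log-odds per unit standardized log population count.
#' @param spatial_effect_amplitude log-odds amplitude of the smooth spatial
#'   term (sum of two sinusoids in lon and lat).
#' @param detection_prob probability that an occupied cell-period yields a
#'   dated record.
#' @param temp_trend temperature-proxy increase per period.
#' @param temp_fluct_sd sd of the period-level temperature fluctuation
#'   shared across cells (the interdecadal variability of an ice-core
#'   isotope proxy; 0 gives a pure trend).
#' @param temp_spatial_amplitude south-to-north span of the static
#'   latitudinal temperature gradient, proxy units (climate varies by
#'   several degrees across a 12.5-degree latitude window).
#' @param temp_noise_sd slice- and cell-level noise sd of the temperature
#'   proxy.
#' @param n_extant number of extant records drawn from cells occupied in
#'   the final period.
#' @param erosion_cells morphological erosion (in cells) applied to the
#'   final occupied area before building the range polygon, so that some
#'   surviving records fall outside it.
#' @param origin_lon,origin_lat,cell_degrees grid geometry (degrees).
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_cells_x = 25, n_cells_y = 25,
                              n_periods = 10, slices_per_period = 3,
                              beta0 = stats::qlogis(0.08),
                              beta_temp = 1.0, beta_pop = 0.5,
                              spatial_effect_amplitude = 0.5,
                              detection_prob = 0.8,
                              temp_trend = 0.5, temp_fluct_sd = 0.5,
                              temp_spatial_amplitude = 3,
                              temp_noise_sd = 0.1,
                              n_extant = 159, erosion_cells = 1,
                              origin_lon = 100, origin_lat = 20,
                              cell_degrees = 0.5, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_periods >= 2, p$detection_prob >= 0, p$detection_prob <= 1,
            p$slices_per_period >= 1, p$n_cells_x >= 2, p$n_cells_y >= 2)
  structure(p, class = "simulation_params")
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

sim_grid <- function(params)
  grid_spec(params$origin_lon, params$origin_lat, params$cell_degrees,
            params$n_cells_x, params$n_cells_y)

# Smooth low-frequency surface on cell centres, mean-centred.
spatial_surface <- function(params) {
  g <- sim_grid(params)
  cc <- cell_center(seq_len(g$n_x * g$n_y), g)
  lx <- g$n_x * g$cell_degrees; ly <- g$n_y * g$cell_degrees
  s <- sin(2 * pi * (cc$lon - g$origin_lon) / lx) +
    sin(2 * pi * (cc$lat - g$origin_lat) / ly)
  params$spatial_effect_amplitude * (s - mean(s)) / 2
}

#' Simulate a covariate stack
#'
#' Generates the raster layers consumed downstream (`popd`, `popc`,
#' `cropland`, `grazing`, `uopp`, `temperature`, `regional_temperature`,
#' `bio3`, `bio7`, `bio8`, `bio14`) at `slices_per_period` slices per
#' period. The temperature proxy rises by `temp_trend` per period (constant
#' within a period up to slice noise); population count grows monotonically
#' in expectation; land-use fractions stay in [0, 1].
#'
#' @param params a [simulation_params()].
#' @return a `covariate_stack` with `n_periods * slices_per_period` slices.
#' @export
simulate_covariates <- function(params) {
  g <- sim_grid(params)
  nx <- g$n_x; ny <- g$n_y
  np <- params$n_periods; spp <- params$slices_per_period
  ns <- np * spp
  with_seed(stage_seed(params$seed, 1), {
    cc <- cell_center(seq_len(nx * ny), g)
    # static spatial fields
    pop_base <- matrix(exp(3 + 1.5 * stats::rnorm(nx * ny) +
                             2 * cos(2 * pi * (cc$lon - g$origin_lon) /
                                       (nx * g$cell_degrees))), nx, ny)
    lat01 <- matrix((cc$lat - g$origin_lat) / (ny * g$cell_degrees), nx, ny)
    lon01 <- matrix((cc$lon - g$origin_lon) / (nx * g$cell_degrees), nx, ny)
    mk <- function(f) array(NA_real_, dim = c(nx, ny, ns))
    L <- list(popd = mk(), popc = mk(), cropland = mk(), grazing = mk(),
              uopp = mk(), temperature = mk(), regional_temperature = mk(),
              bio3 = mk(), bio7 = mk(), bio8 = mk(), bio14 = mk())
    cell_km2 <- 2500  # nominal 50 x 50 km cell
    # static bioclim patterns (1970-2000 climatology analogues)
    bio3 <- 40 + 20 * lat01 + 2 * matrix(stats::rnorm(nx * ny), nx, ny)
    bio7 <- 25 + 10 * lon01 + matrix(stats::rnorm(nx * ny), nx, ny)
    bio8 <- 20 - 8 * lat01 + matrix(stats::rnorm(nx * ny), nx, ny)
    bio14 <- pmax(0, 30 + 25 * lon01 * lat01 +
                    5 * matrix(stats::rnorm(nx * ny), nx, ny))
    # period-level proxy fluctuation shared across cells (interdecadal
    # variability around the warming trend)
    fluct <- params$temp_fluct_sd * stats::rnorm(np)
    for (s in seq_len(ns)) {
      per <- (s - 1) %/% spp  # 0-based period of this slice
      growth <- exp(0.12 * per)
      popc <- pop_base * growth *
        exp(0.05 * matrix(stats::rnorm(nx * ny), nx, ny))
      L$popc[, , s] <- popc
      L$popd[, , s] <- popc / cell_km2
      L$cropland[, , s] <- pmin(1, pmax(0, 0.05 + 0.25 * log1p(popc) / 10 +
        0.03 * matrix(stats::rnorm(nx * ny), nx, ny)))
      L$grazing[, , s] <- pmin(1, pmax(0, 0.10 + 0.10 * lat01 +
        0.03 * matrix(stats::rnorm(nx * ny), nx, ny)))
      L$uopp[, , s] <- pmin(1, pmax(0, 0.002 * sqrt(popc) +
        0.01 * matrix(abs(stats::rnorm(nx * ny)), nx, ny)))
      L$temperature[, , s] <- params$temp_trend * per + fluct[per + 1] +
        params$temp_spatial_amplitude * lat01 + params$temp_noise_sd *
        matrix(stats::rnorm(nx * ny), nx, ny)
      L$regional_temperature[, , s] <- 22 + params$temp_trend * per -
        4 * lat01 + 0.3 * matrix(stats::rnorm(nx * ny), nx, ny)
      L$bio3[, , s] <- bio3; L$bio7[, , s] <- bio7
      L$bio8[, , s] <- bio8; L$bio14[, , s] <- bio14
    }
    covariate_stack(L, g)
  })
}

# Per-cell x per-period hazard matrix from the stack and parameters.
hazard_matrix <- function(params, stack) {
  np <- params$n_periods; spp <- params$slices_per_period
  ncell <- stack$grid$n_x * stack$grid$n_y
  temp <- matrix(NA_real_, ncell, np)
  lpop <- matrix(NA_real_, ncell, np)
  for (t in seq_len(np)) {
    sl <- ((t - 1) * spp + 1):(t * spp)
    m <- stack_slice_mean(stack, sl)
    temp[, t] <- as.vector(m$temperature)
    lpop[, t] <- log1p(as.vector(m$popc))
  }
  z <- function(x) {
    s <- stats::sd(x); if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  eta <- params$beta0 + params$beta_temp * z(as.vector(temp)) +
    params$beta_pop * z(as.vector(lpop))
  eta <- matrix(eta, ncell, np) + spatial_surface(params)
  stats::plogis(eta)
}

#' Simulate occurrence chronicles with known ground truth
#'
#' Every cell starts occupied. Entering each period after the first, an
#' occupied cell goes extinct with probability
#' `logistic(beta0 + beta_temp z_temp + beta_pop z_logpop + spatial)`,
#' evaluated at that period's covariates; there is no recolonization.
#' Each occupied cell-period yields a dated record with probability
#' `detection_prob`, the date uniform within the period and the point
#' uniform within the cell.
#'
#' @param params a [simulation_params()].
#' @param stack the matching [simulate_covariates()] output.
#' @param study_start first year of period 1 (default 1700).
#' @param period_years length of one period in years (default 30).
#' @return list with `occurrences` (historical occurrence data.frame),
#'   `truth` (class `ground_truth`: `occupancy` cell x period logical
#'   matrix, `first_extinct_period` integer per cell or NA, `hazard`
#'   matrix, `beta` the true coefficient vector) and `grid`.
#' @export
simulate_chronicles <- function(params, stack, study_start = 1700,
                                period_years = 30L) {
  g <- stack$grid
  np <- params$n_periods
  stopifnot(stack$n_slices == np * params$slices_per_period)
  ncell <- g$n_x * g$n_y
  h <- hazard_matrix(params, stack)
  with_seed(stage_seed(params$seed, 2), {
    occ <- matrix(FALSE, ncell, np)
    occ[, 1] <- TRUE
    for (t in 2:np)
      occ[, t] <- occ[, t - 1] & (stats::runif(ncell) >= h[, t])
    first_ext <- apply(occ, 1, function(r) {
      w <- which(!r); if (length(w)) w[1] else NA_integer_
    })
    det <- matrix(stats::runif(ncell * np) < params$detection_prob,
                  ncell, np) & occ
    idx <- which(det, arr.ind = TRUE)
    cc <- cell_center(idx[, 1], g)
    half <- g$cell_degrees / 2
    occurrences <- data.frame(
      id = sprintf("h%05d", seq_len(nrow(idx))),
      lon = cc$lon + stats::runif(nrow(idx), -half, half),
      lat = cc$lat + stats::runif(nrow(idx), -half, half),
      year = study_start + (idx[, 2] - 1) * period_years +
        floor(stats::runif(nrow(idx), 0, period_years)),
      source = "historical", stringsAsFactors = FALSE)
    occurrences <- occurrences[order(occurrences$year, occurrences$id), ]
    occurrences$id <- sprintf("h%05d", seq_len(nrow(occurrences)))
    rownames(occurrences) <- NULL
    truth <- structure(list(
      occupancy = occ, first_extinct_period = first_ext, hazard = h,
      detections = det,
      beta = c(beta0 = params$beta0, beta_temp = params$beta_temp,
               beta_pop = params$beta_pop)), class = "ground_truth")
    list(occurrences = occurrences, truth = truth, grid = g)
  })
}

#' Simulate extant records and a current-range polygon
#'
#' Extant records are drawn from cells still occupied in the final period;
#' the range polygon is the union of those cells' rectangles, optionally
#' eroded by `erosion_cells` so some surviving records fall outside it
#' (this exercises the outside-range vs outside-buffer screening split).
#'
#' @param truth a `ground_truth` from [simulate_chronicles()].
#' @param params the matching [simulation_params()].
#' @return list with `extant` (occurrence data.frame, possibly 0 rows) and
#'   `range` (a [range_polygon()]; empty if every cell went extinct).
#' @export
simulate_extant_and_range <- function(truth, params) {
  g <- sim_grid(params)
  np <- ncol(truth$occupancy)
  alive <- matrix(truth$occupancy[, np], g$n_x, g$n_y)
  with_seed(stage_seed(params$seed, 3), {
    cells <- which(as.vector(alive))
    extant <- if (length(cells) == 0) {
      data.frame(id = character(), lon = numeric(), lat = numeric(),
                 year = numeric(), source = character(),
                 stringsAsFactors = FALSE)
    } else {
      pick <- sample(cells, params$n_extant, replace = TRUE)
      cc <- cell_center(pick, g)
      half <- g$cell_degrees / 2
      data.frame(id = sprintf("e%04d", seq_along(pick)),
                 lon = cc$lon + stats::runif(length(pick), -half, half),
                 lat = cc$lat + stats::runif(length(pick), -half, half),
                 year = 2000 + floor(stats::runif(length(pick), 0, 21)),
                 source = "extant", stringsAsFactors = FALSE)
    }
    core <- erode_mask(alive, params$erosion_cells)
    list(extant = extant, range = cells_to_polygon(core, g))
  })
}

# 4-neighbour binary erosion, `n` iterations.
erode_mask <- function(mask, n) {
  if (n <= 0) return(mask)
  for (i in seq_len(n)) {
    nx <- nrow(mask); ny <- ncol(mask)
    pad <- matrix(FALSE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- mask
    mask <- pad[2:(nx + 1), 2:(ny + 1)] &
      pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
      pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
  }
  mask
}

# One rectangle per TRUE cell; adjacent rectangles are a valid MultiPolygon
# for even-odd point-in-polygon purposes.
cells_to_polygon <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  d <- grid$cell_degrees
  polys <- lapply(seq_len(nrow(idx)), function(i) {
    w <- grid$origin_lon + (idx[i, 1] - 1) * d
    s <- grid$origin_lat + (idx[i, 2] - 1) * d
    list(matrix(c(w, s, w + d, s, w + d, s + d, w, s + d, w, s),
                ncol = 2, byrow = TRUE))
  })
  range_polygon(polys)
}

#' Write ground truth as CSV
#'
#' One row per cell: cell id, first extinct period (empty if never), and
#' the occupancy history as a 0/1 string, for test harnesses.
#'
#' @param truth a `ground_truth`.
#' @param path output CSV.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(
    cell_id = seq_len(nrow(truth$occupancy)),
    first_extinct_period = truth$first_extinct_period,
    occupancy = apply(truth$occupancy, 1, function(r)
      paste(as.integer(r), collapse = "")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
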