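small_params <- function(...)
  simulation_params(n_cells_x = 8, n_cells_y = 8, n_periods = 5,
                    slices_per_period = 2, n_extant = 20, ...)

test_that("covariate generation is deterministic and respects the trend", {
  p <- small_params(seed = 11)
  expect_equal(simulate_covariates(p), simulate_covariates(p))

  # no trend, no fluctuation, no noise: temperature constant across slices
  p0 <- small_params(temp_trend = 0, temp_fluct_sd = 0, temp_noise_sd = 0)
  st0 <- simulate_covariates(p0)
  tmp <- st0$layers$temperature
  for (s in 2:dim(tmp)[3]) expect_equal(tmp[, , s], tmp[, , 1])

  # trend 1/period over 5 periods: per-cell mean rises by exactly 4
  p1 <- small_params(temp_trend = 1, temp_fluct_sd = 0, temp_noise_sd = 0)
  st1 <- simulate_covariates(p1)
  first <- apply(st1$layers$temperature[, , 1:2], c(1, 2), mean)
  last <- apply(st1$layers$temperature[, , 9:10], c(1, 2), mean)
  expect_equal(last - first, matrix(4, 8, 8))

  # population count grows monotonically in expectation
  popc <- simulate_covariates(small_params(seed = 3))$layers$popc
  means <- vapply(seq_len(dim(popc)[3]), function(s) mean(popc[, , s]), 0)
  slice_per <- rep(1:5, each = 2)
  expect_true(all(diff(tapply(means, slice_per, mean)) > 0))
})

test_that("degenerate hazards behave as specified", {
  # hazard 0: nothing goes extinct and every cell-period is detected
  p <- small_params(beta0 = -Inf, beta_temp = 0, beta_pop = 0,
                    spatial_effect_amplitude = 0, detection_prob = 1)
  st <- simulate_covariates(p)
  sim <- simulate_chronicles(p, st)
  expect_true(all(is.na(sim$truth$first_extinct_period)))
  expect_equal(nrow(sim$occurrences), 8 * 8 * 5)

  # hazard 1: every cell extinct entering period 2
  p1 <- small_params(beta0 = Inf, beta_temp = 0, beta_pop = 0,
                     spatial_effect_amplitude = 0)
  sim1 <- simulate_chronicles(p1, simulate_covariates(p1))
  expect_true(all(sim1$truth$first_extinct_period == 2))
})

test_that("extinction hazard is calibrated to logistic(beta0)", {
  p <- simulation_params(n_cells_x = 20, n_cells_y = 20, n_periods = 5,
                         slices_per_period = 1,
                         beta0 = qlogis(0.3), beta_temp = 0, beta_pop = 0,
                         spatial_effect_amplitude = 0, seed = 5)
  sim <- simulate_chronicles(p, simulate_covariates(p))
  frac <- mean(!is.na(sim$truth$first_extinct_period) &
                 sim$truth$first_extinct_period == 2)
  se <- sqrt(0.3 * 0.7 / 400)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("occupancy never recolonizes and detection respects occupancy", {
  p <- small_params(seed = 9)
  sim <- simulate_chronicles(p, simulate_covariates(p))
  occ <- sim$truth$occupancy
  for (i in seq_len(nrow(occ)))
    expect_true(all(diff(as.integer(occ[i, ])) <= 0))
  expect_true(all(sim$truth$detections[!occ] == FALSE))
})

test_that("extant records and range polygon reflect the final period", {
  p <- small_params(seed = 2, erosion_cells = 0)
  sim <- simulate_chronicles(p, simulate_covariates(p))
  er <- simulate_extant_and_range(sim$truth, p)
  expect_equal(er, simulate_extant_and_range(sim$truth, p))  # determinism
  if (nrow(er$extant) > 0)  # erosion 0: every extant record inside range
    expect_true(all(point_in_polygon(er$extant$lon, er$extant$lat,
                                     er$range)))

  # all-extinct degenerate case: empty extant set and empty polygon
  pX <- small_params(beta0 = Inf, beta_temp = 0, beta_pop = 0,
                     spatial_effect_amplitude = 0)
  simX <- simulate_chronicles(pX, simulate_covariates(pX))
  erX <- simulate_extant_and_range(simX$truth, pX)
  expect_equal(nrow(erX$extant), 0)
  expect_length(erX$range, 0)
  scr <- screen_extinctions(
    data.frame(id = "h1", lon = 101, lat = 21, year = 1990,
               source = "historical", stringsAsFactors = FALSE),
    erX$extant, erX$range, buffer_km = 50)
  expect_equal(unname(scr$counts["extinction"]), 1L)
})

test_that("chronicle generation is reproducible from the seed", {
  p <- small_params(seed = 31)
  st <- simulate_covariates(p)
  s1 <- simulate_chronicles(p, st)
  s2 <- simulate_chronicles(p, st)
  expect_equal(s1$occurrences, s2$occurrences)
  expect_equal(s1$truth$occupancy, s2$truth$occupancy)
})
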