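test_that("great-circle distances match the closed form", {
  expect_equal(haversine_km(100, 20, 100, 20), 0)
  # one degree of latitude at the equator: pi * R / 180
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371.0088 / 180,
               tolerance = 0.01 / 111)
  set.seed(5)
  a <- cbind(runif(100, -180, 180), runif(100, -60, 60))
  b <- cbind(runif(100, -180, 180), runif(100, -60, 60))
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_km(b[, 1], b[, 2], a[, 1], a[, 2]))
})

test_that("point-in-polygon handles holes and multipolygons", {
  outer <- matrix(c(0, 0, 4, 0, 4, 4, 0, 4), ncol = 2, byrow = TRUE)
  hole <- matrix(c(1, 1, 3, 1, 3, 3, 1, 3), ncol = 2, byrow = TRUE)
  poly <- range_polygon(list(list(outer, hole)))
  expect_true(point_in_polygon(0.5, 0.5, poly))
  expect_false(point_in_polygon(2, 2, poly))   # inside the hole
  expect_false(point_in_polygon(5, 2, poly))
  expect_false(point_in_polygon(2, 2, range_polygon(list())))  # empty
})

test_that("extinction screening applies the range-and-buffer conjunction", {
  # polygon spans lon 100-101, lat 20-20.8; single extant record inside
  poly <- range_polygon(list(list(matrix(c(100, 20, 101, 20, 101, 20.8,
                                           100, 20.8), ncol = 2,
                                         byrow = TRUE))))
  extant <- data.frame(id = "e1", lon = 100.5, lat = 20.5, year = 2010,
                       source = "extant", stringsAsFactors = FALSE)
  # 0.459 deg of latitude is about 51 km: beyond the polygon and buffer
  rec <- data.frame(
    id = c("inside", "coincident", "far_out"),
    lon = c(100.5, 100.5, 100.5),
    lat = c(20.7, 20.5, 20.5 + 51 / (pi * 6371.0088 / 180) * 1),
    year = 1990, source = "historical", stringsAsFactors = FALSE)
  scr <- screen_extinctions(rec, extant, poly, buffer_km = 50)
  r <- scr$records
  expect_false(r$is_extinction[r$id == "inside"])
  expect_false(r$is_extinction[r$id == "coincident"])
  expect_true(r$outside_range[r$id == "far_out"])
  expect_true(r$outside_buffers[r$id == "far_out"])
  expect_true(r$is_extinction[r$id == "far_out"])
  expect_equal(unname(scr$counts["extinction"]), 1L)
})

test_that("screening bins are counted separately and sum via accounting", {
  # fixture: 3 outside polygon only, 5 outside buffers only, 2 outside both
  poly <- range_polygon(list(list(matrix(c(100, 20, 110, 20, 110, 30,
                                           100, 30), ncol = 2,
                                         byrow = TRUE))))
  extant <- data.frame(id = "e1", lon = 105, lat = 25, year = 2010,
                       source = "extant", stringsAsFactors = FALSE)
  rec <- rbind(
    # outside polygon but within 50 km of the extant record: impossible
    # here, so "outside polygon only" records sit just west of the edge
    # but inside the buffer via a second extant record
    data.frame(id = sprintf("a%d", 1:3), lon = 99.95, lat = c(25, 25.1, 24.9),
               year = 1990, source = "historical"),
    # inside polygon, far from any extant record
    data.frame(id = sprintf("b%d", 1:5), lon = 108, lat = c(28, 28.2, 28.4,
                                                            28.6, 28.8),
               year = 1990, source = "historical"),
    # outside both
    data.frame(id = sprintf("c%d", 1:2), lon = 115, lat = c(25, 26),
               year = 1990, source = "historical"))
  extant2 <- rbind(extant,
                   data.frame(id = "e2", lon = 100.05, lat = 25, year = 2010,
                              source = "extant"))
  scr <- screen_extinctions(rec, extant2, poly, buffer_km = 50)
  expect_equal(unname(scr$counts["outside_range"]), 5L)   # a1-3 + c1-2
  expect_equal(unname(scr$counts["outside_buffers"]), 7L) # b1-5 + c1-2
  expect_equal(unname(scr$counts["extinction"]), 2L)      # c1-2 only
  acct <- report_accounting(c(outside_range = 5, outside_buffers = 7))
  expect_equal(acct$total, 12)
})

test_that("enlarging the buffer never increases the extinction count", {
  set.seed(9)
  poly <- range_polygon(list(list(matrix(c(102, 22, 104, 22, 104, 24,
                                           102, 24), ncol = 2,
                                         byrow = TRUE))))
  extant <- data.frame(id = sprintf("e%d", 1:5), lon = runif(5, 100, 110),
                       lat = runif(5, 20, 30), year = 2010,
                       source = "extant", stringsAsFactors = FALSE)
  rec <- data.frame(id = sprintf("h%d", 1:100), lon = runif(100, 100, 110),
                    lat = runif(100, 20, 30), year = 1990,
                    source = "historical", stringsAsFactors = FALSE)
  counts <- vapply(c(10, 25, 50, 100, 200), function(b)
    unname(screen_extinctions(rec, extant, poly, b)$counts["extinction"]),
    0L)
  expect_true(all(diff(counts) <= 0))
  # with no extant records every outside-range record is an extinction
  scr0 <- screen_extinctions(rec, extant[0, ], poly, 50)
  expect_equal(unname(scr0$counts["extinction"]),
               unname(scr0$counts["outside_range"]))
})

test_that("rarefaction thins to the minimum distance and is idempotent", {
  # two records ~5 km apart -> one kept; ~15 km apart -> both kept
  two <- data.frame(id = c("r1", "r2"), lon = c(100, 100),
                    lat = c(20, 20 + 5 / 111.195), year = 1990,
                    source = "historical", stringsAsFactors = FALSE)
  expect_equal(nrow(rarefy(two, 10)), 1)
  two$lat[2] <- 20 + 15 / 111.195
  expect_equal(nrow(rarefy(two, 10)), 2)

  set.seed(33)
  rec <- data.frame(id = sprintf("r%03d", 1:200),
                    lon = runif(200, 100, 102), lat = runif(200, 20, 22),
                    year = 1990, source = "historical",
                    stringsAsFactors = FALSE)
  kept <- rarefy(rec, 10)
  d <- outer(seq_len(nrow(kept)), seq_len(nrow(kept)), function(i, j)
    haversine_km(kept$lon[i], kept$lat[i], kept$lon[j], kept$lat[j]))
  expect_true(all(d[upper.tri(d)] >= 10))
  expect_equal(rarefy(kept, 10), kept)
  # lowest id is preferred
  expect_true("r001" %in% kept$id)
})

test_that("Ripley's K matches hand calculations and detects CSR", {
  two <- data.frame(lon = c(100, 100), lat = c(20, 20 + 50 / 111.195))
  bbox <- c(99, 101, 19, 21)
  kf <- ripley_k(two, radii = c(25, 60), bbox = bbox, n_sims = 5)
  A <- attr(kf, "area")
  expect_equal(kf$khat[1], 0)               # radius below the separation
  expect_equal(kf$khat[2], A / 2)           # (A/4) * 2 ordered pairs
  expect_true(all(diff(kf$khat) >= 0))
  expect_error(ripley_k(two[1, , drop = FALSE], 10), "at least 2")

  set.seed(14)
  csr <- data.frame(lon = runif(300, 100, 102), lat = runif(300, 20, 22))
  kf2 <- ripley_k(csr, radii = seq(10, 80, by = 10),
                  bbox = c(100, 102, 20, 22), n_sims = 99, seed = 3)
  expect_true(all(kf2$khat >= kf2$env_lo & kf2$khat <= kf2$env_hi))
})
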