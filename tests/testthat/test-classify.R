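test_that("max-SSS threshold matches the exhaustive scan", {
  # hand case: candidates tie at 1.5; the smaller threshold wins
  thr <- max_sss_threshold(c(0.8, 0.6), c(0.7, 0.2))
  oracle <- brute_max_sss(c(0.8, 0.6), c(0.7, 0.2))
  expect_equal(thr$threshold, oracle$threshold)
  expect_equal(thr$sum, oracle$sum)
  expect_equal(thr$threshold, 0.6)

  # perfectly separated scores reach sensitivity + specificity = 2
  sep <- max_sss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$sum, 2)
  expect_equal(sep$threshold, 0.8)  # smallest candidate achieving 2
  expect_error(max_sss_threshold(numeric(), 1), "empty")
})

test_that("jenks breaks match hand partitions and handle edge cases", {
  expect_equal(as.numeric(jenks_breaks(c(3, 1, 2), 1)), 3)
  b <- jenks_breaks(c(1, 2, 10, 11), 2)
  expect_equal(as.numeric(b), c(2, 11))  # classes {1,2} and {10,11}
  expect_equal(attr(b, "ssd"), 0.5 + 0.5)
  expect_error(jenks_breaks(c(1, 2), 3), "exceeds")
  # k = n: every value its own class, zero SSD
  expect_equal(as.numeric(jenks_breaks(c(5, 1, 9), 3)), c(1, 5, 9))
})

test_that("jenks on duplicated values keeps the breaks stable", {
  v <- c(0.25, 0.3, 0.42, 0.55, 0.61)
  b1 <- as.numeric(jenks_breaks(v, 3))
  b2 <- as.numeric(jenks_breaks(c(v, 0.42), 3))  # duplicate of a member
  expect_equal(b1, b2)
})

test_that("site classification bins by threshold then natural breaks", {
  g <- grid_spec(100, 20, 1, 4, 1)
  surf <- structure(list(values = matrix(c(0.1, 0.3, 0.5, 0.9), 4, 1),
                         grid = g), class = "risk_surface")
  sites <- data.frame(id = sprintf("s%d", 1:4),
                      lon = c(100.5, 101.5, 102.5, 103.5), lat = 20.5,
                      stringsAsFactors = FALSE)
  cls <- classify_sites(surf, sites, threshold = 0.2, k = 3)
  expect_equal(cls$sites$class, c("none", "low", "moderate", "high"))
  expect_equal(cls$notable_pct, 50)
  expect_equal(sum(cls$percentages), 100, tolerance = 0.01)

  # all below threshold: everything "none"
  cls0 <- classify_sites(surf, sites, threshold = 0.95, k = 3)
  expect_true(all(cls0$sites$class == "none"))
  expect_equal(cls0$notable_pct, 0)

  # a site outside the surface is excluded with a warning
  out <- rbind(sites, data.frame(id = "s5", lon = 150, lat = 50))
  expect_warning(cls1 <- classify_sites(surf, out, 0.2, 3), "outside")
  expect_equal(cls1$n_excluded, 1)
  expect_equal(nrow(cls1$sites), 4)
})

test_that("regional tallies sum to the classified-site total", {
  g <- grid_spec(100, 20, 1, 4, 1)
  surf <- structure(list(values = matrix(c(0.1, 0.3, 0.5, 0.9), 4, 1),
                         grid = g), class = "risk_surface")
  sites <- data.frame(id = sprintf("s%d", 1:8),
                      lon = rep(c(100.5, 101.5, 102.5, 103.5), 2),
                      lat = 20.5,
                      region = rep(c("north", "south"), each = 4),
                      stringsAsFactors = FALSE)
  cls <- classify_sites(surf, sites, threshold = 0.2, k = 3)
  expect_equal(sum(cls$regional), nrow(cls$sites))
})

test_that("accounting reports reproduce the record arithmetic", {
  # 35 dispersed records outside the range + 142 outside the buffers
  acct <- report_accounting(c(outside_range = 35, outside_buffers = 142))
  expect_equal(acct$total, 177)
  # 16 of the 52 moderate-and-high-risk sites fall in one province
  expect_equal(report_accounting(c(guangdong = 16), total = 52)$shares[["guangdong"]],
               30.77)
  # moderate (14.59%) plus high (13.51%) risk share
  expect_equal(report_accounting(c(moderate = 14.59, high = 13.51))$total,
               28.10)
  expect_error(report_accounting(c(a = 2), total = 0), "zero total")
  expect_equal(report_accounting(c(a = 0), total = 0)$shares[["a"]], 0)
})

test_that("percentage rounding is half-up at two decimals", {
  expect_equal(chronex:::round_half_up(0.125 * 100, 2), 12.5)
  expect_equal(chronex:::round_half_up(30.765, 2), 30.77)
  expect_equal(chronex:::round_half_up(30.764, 2), 30.76)
})
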