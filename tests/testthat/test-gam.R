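noise_rows <- function(n, p1 = 0.4, seed = 1) {
  set.seed(seed)
  data.frame(fate = rbinom(n, 1, p1), lon = runif(n, 100, 112),
             lat = runif(n, 20, 32), temperature = rnorm(n),
             popc = exp(rnorm(n, 3)), cropland = runif(n))
}

test_that("intercept-only fit returns the sample mean exactly", {
  set.seed(4)
  rows <- noise_rows(200, p1 = 0.3)
  fit <- fit_extinction_gam(rows, character(), spatial = FALSE)
  expect_equal(unname(fit$fitted), rep(mean(rows$fate), 200),
               tolerance = 1e-8)
  expect_equal(fit$deviance_explained, 0, tolerance = 1e-10)
  expect_equal(fit$n, 200)
})

test_that("adding a smooth never decreases deviance explained", {
  rows <- noise_rows(400, seed = 8)
  rows$fate <- rbinom(400, 1, plogis(-1 + 0.8 * rows$temperature))
  f0 <- suppressWarnings(fit_extinction_gam(rows, "cropland",
                                            spatial = FALSE))
  f1 <- suppressWarnings(fit_extinction_gam(rows,
                                            c("cropland", "temperature"),
                                            spatial = FALSE))
  expect_gte(f1$deviance_explained, f0$deviance_explained - 1e-8)
})

test_that("a near-separable covariate yields near-total deviance explained", {
  rows <- noise_rows(500, seed = 13)
  rows$fate <- as.integer(rows$temperature > stats::median(rows$temperature))
  fit <- suppressWarnings(fit_extinction_gam(rows, "temperature",
                                             spatial = FALSE))
  expect_gt(fit$deviance_explained, 0.95)
})

test_that("collinearity screening drops the weaker duplicate", {
  set.seed(21)
  n <- 400
  x1 <- rnorm(n)
  rows <- data.frame(fate = rbinom(n, 1, plogis(x1)),
                     x1 = x1, x2 = 2 * x1,  # exact duplicate, scaled
                     z = rnorm(n))
  scr <- screen_collinear_predictors(rows, c("x1", "x2", "z"))
  expect_length(scr$kept, 2)
  expect_true("z" %in% scr$kept)
  expect_true(sum(c("x1", "x2") %in% scr$kept) == 1)
  expect_equal(nrow(scr$log), 1)
  expect_gt(abs(scr$log$r), 0.95)

  # orthogonal predictors are all kept
  rows2 <- data.frame(fate = rbinom(n, 1, 0.5), a = rnorm(n), b = rnorm(n))
  expect_setequal(screen_collinear_predictors(rows2, c("a", "b"))$kept,
                  c("a", "b"))

  # constant predictors are excluded with a zero-variance reason
  rows3 <- data.frame(fate = rbinom(n, 1, 0.5), a = rnorm(n), c = 1)
  scr3 <- screen_collinear_predictors(rows3, c("a", "c"))
  expect_equal(scr3$kept, "a")
  expect_match(scr3$log$reason[scr3$log$dropped == "c"], "zero variance")
})

test_that("collinearity screening retains the causal member of an r=.98 pair", {
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 400
    causal <- rnorm(n)
    proxy <- causal + rnorm(n, sd = 0.2)  # r about .98
    rows <- data.frame(fate = rbinom(n, 1, plogis(1.5 * causal)),
                       causal = causal, proxy = proxy)
    scr <- screen_collinear_predictors(rows, c("causal", "proxy"))
    "causal" %in% scr$kept
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("partial effects recover the shape of a known linear effect", {
  set.seed(17)
  n <- 800
  rows <- noise_rows(n, seed = 17)
  rows$fate <- rbinom(n, 1, plogis(-0.5 + 1.2 * rows$temperature))
  fit <- suppressWarnings(fit_extinction_gam(rows, "temperature",
                                             spatial = FALSE))
  qs <- stats::quantile(rows$temperature, c(0.1, 0.9))
  pe <- partial_effect(fit, "temperature",
                       values = seq(qs[1], qs[2], length.out = 40))
  expect_true(all(diff(pe$effect) > 0))
  expect_true(all(pe$upper > pe$lower))
  expect_equal(nrow(partial_effect(fit, "temperature", values = 0.5)), 1)
  expect_error(partial_effect(fit, "cropland"), "not a smooth term")
})

test_that("null partial effects stay inside their uncertainty", {
  flat <- vapply(1:10, function(s) {
    rows <- noise_rows(500, seed = 200 + s)
    fit <- suppressWarnings(fit_extinction_gam(rows, "temperature",
                                               spatial = FALSE))
    pe <- partial_effect(fit, "temperature")
    max(abs(pe$effect)) < 2 * stats::median(pe$upper - pe$effect)
  }, TRUE)
  expect_gte(mean(flat), 0.9)
})
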