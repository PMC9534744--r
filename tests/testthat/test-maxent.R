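test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(auc(c(2, 3), c(0, 1)), 1)
  expect_equal(auc(c(1, 1), c(1, 1)), 0.5)  # all ties
  # enumerate the four pairs: win, win, loss, win -> 3/4
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(auc(numeric(), 1), "nonempty")
})

test_that("features are scaled to [0,1] with decile hinge knots", {
  set.seed(2)
  bg <- cbind(x = runif(200, -3, 7), y = rnorm(200))
  spec <- maxent_features(bg)
  expect_true(all(c("linear", "quadratic", "hinge_fwd", "hinge_rev") %in%
                    spec$type))
  knots <- sort(spec$knot[spec$var == "x" & spec$type == "hinge_fwd"])
  expect_equal(knots, unname(stats::quantile(bg[, "x"], (1:9) / 10)))
  F <- featurize(spec, bg)
  expect_true(all(F >= 0 & F <= 1))
  # clamping: values beyond the background range saturate
  F2 <- featurize(spec, cbind(x = c(-100, 100), y = c(0, 0)))
  expect_equal(unname(F2[, "x:linear"]), c(0, 1))
})

test_that("fitted models satisfy the KKT conditions and normalize", {
  for (s in 1:5) {
    set.seed(s)
    bg <- cbind(a = rnorm(300), b = runif(300))
    pres <- cbind(a = rnorm(40, 1), b = runif(40)^2)
    fit <- suppressWarnings(fit_maxent(pres, bg))
    q <- predict(fit, fit$training_env, type = "raw")
    expect_equal(sum(q), 1, tolerance = 1e-8)
    # feature-mean matching within the per-feature penalty
    g <- fit$presence_means - fit$bg_expectations
    expect_true(all(abs(g) <= fit$beta + 1e-4))
    active <- fit$lambda != 0
    if (any(active))
      expect_true(all(abs(abs(g[active]) - fit$beta[active]) <= 1e-4))
  }
})

test_that("a null fixture predicts near-background-average risk", {
  mean_out <- vapply(1:20, function(s) {
    set.seed(s)
    bg <- cbind(x = rnorm(300), y = runif(300))
    pres <- cbind(x = rnorm(40), y = runif(40))
    fit <- suppressWarnings(fit_maxent(pres, bg))
    mean(predict(fit, bg, type = "logistic"))
  }, 0)
  expect_true(all(mean_out >= 0.4 & mean_out <= 0.6))
})

test_that("a separating feature achieves training AUC 1", {
  fx <- separable_fixture(seed = 6)
  fit <- fit_maxent(fx$pres, fx$bg)
  expect_equal(auc(predict(fit, fx$pres, "raw"),
                   predict(fit, fx$bg, "raw")), 1)
})

test_that("heavy regularization drives all weights to zero", {
  fx <- separable_fixture(seed = 7)
  fit <- fit_maxent(fx$pres, fx$bg, reg_multiplier = 1e6)
  expect_true(all(fit$lambda == 0))
  out <- predict(fit, fx$bg, type = "logistic")
  expect_equal(stats::sd(out), 0, tolerance = 1e-12)
})

test_that("logistic output is the entropy transform of raw suitability", {
  fx <- separable_fixture(seed = 8)
  fit <- fit_maxent(fx$pres, fx$bg)
  q <- predict(fit, fx$bg, type = "raw")
  p <- predict(fit, fx$bg, type = "logistic")
  eH <- exp(fit$entropy)
  expect_equal(p, q * eH / (1 + q * eH), tolerance = 1e-12)
  # a cell whose raw output equals exp(-H) maps exactly to 0.5
  i <- which.min(abs(q - exp(-fit$entropy)))
  expect_equal(p[i], stats::plogis(log(q[i]) + fit$entropy))
})

single_signal_fixture <- function(n_pres = 50, n_bg = 400, seed = 1) {
  set.seed(seed)
  bg <- cbind(a = runif(n_bg), b = rnorm(n_bg))
  pres <- cbind(a = runif(n_pres, 0.7, 1), b = rnorm(n_pres))
  list(pres = pres, bg = bg)
}

test_that("percent contribution normalizes and splits duplicated signal", {
  fx <- single_signal_fixture(seed = 9)
  fit <- fit_maxent(fx$pres, fx$bg)
  pc <- percent_contribution(fit)
  expect_equal(sum(pc), 100, tolerance = 0.01)
  expect_gt(pc["a"], 50)

  # two copies of the same informative signal share the credit
  shares <- vapply(1:20, function(s) {
    set.seed(400 + s)
    sig_bg <- runif(300)
    sig_pr <- runif(60)^0.4
    bg <- cbind(u = sig_bg + rnorm(300, sd = 0.05),
                v = sig_bg + rnorm(300, sd = 0.05))
    pres <- cbind(u = sig_pr + rnorm(60, sd = 0.05),
                  v = sig_pr + rnorm(60, sd = 0.05))
    percent_contribution(fit_maxent(pres, bg))["u"]
  }, 0)
  expect_lt(abs(mean(shares) - 50), 10)
})

test_that("permutation importance isolates the causal variable", {
  fx <- single_signal_fixture(seed = 10)
  fit <- fit_maxent(fx$pres, fx$bg)
  pi_ <- permutation_importance(fit, fx$pres, fx$bg, seed = 2)
  expect_equal(sum(pi_), 100, tolerance = 0.01)
  expect_gt(pi_["a"], 90)
  # a variable with zero weight has zero importance
  zero_vars <- unique(fit$spec$var[fit$lambda == 0])
  unused <- setdiff(zero_vars, unique(fit$spec$var[fit$lambda != 0]))
  if (length(unused)) expect_equal(unname(pi_[unused]), 0)
})

test_that("background sampling is deterministic and exhaustive at n = N", {
  env <- tiny_env(list(x = matrix(rnorm(25), 5, 5)))
  all_cells <- sample_background(env, 25, seed = 1)
  expect_equal(all_cells$cells, 1:25)
  s1 <- sample_background(env, 10, seed = 4)
  expect_equal(s1, sample_background(env, 10, seed = 4))
  expect_length(s1$cells, 10)
  # hypergeometric coverage: each cell appears in about half of many draws
  hits <- rowMeans(vapply(1:400, function(s)
    1:10 %in% sample_background(tiny_env(list(x = matrix(1:10, 10, 1))),
                                5, seed = s)$cells, logical(10)))
  se <- sqrt(0.5 * 0.5 / 400)
  expect_true(all(abs(hits - 0.5) < 4 * se))
})

test_that("pre-experiment screen drops only all-zero variables", {
  set.seed(11)
  bg <- cbind(causal = runif(300), constant = 1,
              noise = rnorm(300))
  pres <- cbind(causal = runif(60)^0.3, constant = 1, noise = rnorm(60))
  pre <- suppressWarnings(prescreen_variables(pres, bg, n_runs = 5))
  expect_true("causal" %in% pre$retained)
  expect_true("constant" %in% pre$dropped)
})

test_that("correlation filter keeps the higher-contribution member", {
  set.seed(12)
  x <- rnorm(300)
  env <- cbind(a = x, b = x + rnorm(300, sd = 0.1), c = rnorm(300))
  out <- correlation_filter(env, c(a = 60, b = 40, c = 10))
  expect_setequal(out$retained, c("a", "c"))
  expect_equal(out$log$dropped, "b")

  # three mutually correlated variables: only the top contributor survives
  env3 <- cbind(a = x, b = x + rnorm(300, sd = 0.05),
                d = x + rnorm(300, sd = 0.05))
  out3 <- correlation_filter(env3, c(a = 50, b = 30, d = 20))
  expect_equal(out3$retained, "a")

  # nothing above the threshold: all retained
  env0 <- cbind(a = rnorm(300), b = rnorm(300))
  expect_setequal(correlation_filter(env0, c(a = 1, b = 2))$retained,
                  c("a", "b"))
})

test_that("replicated fits aggregate into a deterministic risk surface", {
  set.seed(13)
  nx <- 8; ny <- 8
  g <- grid_spec(100, 20, 0.5, nx, ny)
  x_layer <- matrix(seq(0, 1, length.out = nx * ny), nx, ny)
  st <- covariate_stack(list(x = x_layer,
                             y = matrix(rnorm(nx * ny), nx, ny)), g)
  env <- period_env(st, 1, 1)
  bg <- sample_background(env, 64, seed = 1)
  # presences confined to the top-x stratum (true AUC about 0.95)
  pres_cells <- which(as.vector(x_layer) > 0.9)
  pres_X <- env_at_cells(env, sample(pres_cells, 30, replace = TRUE))
  rf <- suppressWarnings(replicate_fit(pres_X, bg, env, replicates = 3,
                                       test_fraction = 0.25, seed = 5))
  rf2 <- suppressWarnings(replicate_fit(pres_X, bg, env, replicates = 3,
                                        test_fraction = 0.25, seed = 5))
  expect_equal(rf$surface$values, rf2$surface$values)
  expect_gt(rf$mean_auc, 0.85)
  expect_true(all(rf$surface$values >= 0 & rf$surface$values <= 1))
  expect_error(suppressWarnings(
    replicate_fit(pres_X[1:3, ], bg, env, replicates = 1,
                  test_fraction = 0.01)), "test split|train split")
})
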