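## Maximum-entropy presence/background extinction-risk model.
##
## The engine fits an L1-penalized Gibbs distribution over background
## cells: maximize  (1/m) sum_i lambda.f(x_i) - log Z_bg(lambda)
##                  - sum_j beta_j |lambda_j|
## with beta_j = reg_multiplier * s_j / sqrt(m), s_j the background SD of
## feature j. Features are linear, quadratic, and forward/reverse hinges
## with knots at the empirical background deciles, each scaled to [0, 1]
## over the background. Optimization is cyclic coordinate ascent with a
## per-coordinate Newton step, soft-thresholding, and backtracking on the
## penalized objective; convergence is declared on the KKT conditions
## (|gradient| within beta of zero for every coordinate).

#' Build a feature specification from background environment values
#'
#' @param bg_env numeric matrix (background cells x variables) with column
#'   names.
#' @param n_hinge number of interior hinge knots per direction (default 9,
#'   the deciles).
#' @return object of class `maxent_features`: per-feature variable map,
#'   type, knot, and the background min/max used for scaling.
#' @export
maxent_features <- function(bg_env, n_hinge = 9) {
  stopifnot(is.matrix(bg_env), !is.null(colnames(bg_env)))
  feats <- list()
  for (v in colnames(bg_env)) {
    x <- bg_env[, v]
    lo <- min(x); hi <- max(x)
    feats[[length(feats) + 1]] <- data.frame(
      var = v, type = "linear", knot = NA_real_, lo = lo, hi = hi)
    feats[[length(feats) + 1]] <- data.frame(
      var = v, type = "quadratic", knot = NA_real_, lo = lo, hi = hi)
    if (hi > lo && n_hinge > 0) {
      knots <- unique(stats::quantile(
        x, probs = seq_len(n_hinge) / (n_hinge + 1), names = FALSE))
      knots <- knots[knots > lo & knots < hi]
      for (k in knots) {
        feats[[length(feats) + 1]] <- data.frame(
          var = v, type = "hinge_fwd", knot = k, lo = lo, hi = hi)
        feats[[length(feats) + 1]] <- data.frame(
          var = v, type = "hinge_rev", knot = k, lo = lo, hi = hi)
      }
    }
  }
  spec <- do.call(rbind, feats)
  spec$name <- paste0(spec$var, ":", spec$type,
                      ifelse(is.na(spec$knot), "",
                             sprintf(":%g", spec$knot)))
  class(spec) <- c("maxent_features", "data.frame")
  spec
}

#' Evaluate features on an environment matrix
#'
#' @param spec a [maxent_features()] specification.
#' @param env matrix (rows x variables) containing every `spec` variable.
#' @return feature matrix in [0, 1] (values clamped to the background
#'   range), columns named as in `spec`.
#' @export
featurize <- function(spec, env) {
  n <- nrow(env)
  F <- matrix(0, n, nrow(spec), dimnames = list(NULL, spec$name))
  for (j in seq_len(nrow(spec))) {
    x <- env[, spec$var[j]]
    lo <- spec$lo[j]; hi <- spec$hi[j]; k <- spec$knot[j]
    u <- if (hi > lo) pmin(1, pmax(0, (x - lo) / (hi - lo))) else
      rep(0, n)
    F[, j] <- switch(spec$type[j],
      linear = u,
      quadratic = u^2,
      hinge_fwd = if (hi > k) pmin(1, pmax(0, (x - k) / (hi - k))) else 0,
      hinge_rev = if (k > lo) pmin(1, pmax(0, (k - x) / (k - lo))) else 0)
  }
  F
}

#' Fit the maximum-entropy model
#'
#' @param pres_env presence matrix (records x variables).
#' @param bg_env background matrix (cells x variables), same columns.
#' @param reg_multiplier L1 regularisation multiplier (default 1).
#' @param spec optional [maxent_features()]; built from `bg_env` if NULL.
#' @param tol KKT gradient tolerance (default 1e-6).
#' @param max_cycles maximum full coordinate sweeps.
#' @param max_outer maximum proximal-Newton steps.
#' @return object of class `maxent_sdm`: feature weights `lambda`,
#'   penalties `beta`, log-normalizer `log_z` (so that raw suitability
#'   `q(x) = exp(lambda.f(x) - log_z)` sums to 1 over the background),
#'   background entropy `entropy`, per-variable training `gain`
#'   increments, presence feature means, convergence info.
#' @details Presence samples are added to the background for the
#'   normalization (the add-samples-to-background convention of reference
#'   MaxEnt implementations): this keeps the presence feature means inside
#'   the achievable hull, so the penalized optimum is finite even for
#'   perfectly separable data. Feature scaling, hinge knots and the
#'   penalties still derive from the supplied background alone.
#'
#'   The penalized objective is maximised by proximal Newton: at
#'   each outer step the exact gradient (presence means minus background
#'   expectations) and Hessian (background feature covariance under the
#'   current Gibbs weights) define an L1-penalized quadratic subproblem,
#'   solved by inner coordinate descent with soft-thresholding; a
#'   backtracking line search on the true penalized objective guarantees
#'   monotone ascent. Convergence is declared when every KKT violation is
#'   at most `tol`. The positive objective increment of each outer step
#'   is attributed to variables in proportion to the first-order credit
#'   `|gradient_j x step_j|` of their features, giving the path-dependent
#'   per-variable training gains behind [percent_contribution()].
#' @export
fit_maxent <- function(pres_env, bg_env, reg_multiplier = 1.0,
                       spec = NULL, tol = 1e-6, max_outer = 200L) {
  stopifnot(is.matrix(pres_env), is.matrix(bg_env))
  if (any(!is.finite(pres_env)) || any(!is.finite(bg_env)))
    stop("non-finite environmental values in presence or background")
  m <- nrow(pres_env)
  if (m < 5) stop("need at least 5 presence records")
  if (m < 30) warning("fewer than 30 presences; fit may be unstable")
  if (is.null(spec)) spec <- maxent_features(bg_env)
  Fp <- featurize(spec, pres_env)
  p_mean <- colMeans(Fp)
  s <- apply(featurize(spec, bg_env), 2, stats::sd)
  beta <- reg_multiplier * s / sqrt(m)
  active <- s > 0  # constant background features are unidentifiable
  # presence samples join the training background (finite-optimum
  # guarantee; see Details)
  training_env <- rbind(bg_env, pres_env)
  Fb <- featurize(spec, training_env)
  J <- ncol(Fb); n <- nrow(Fb)
  lambda <- numeric(J)
  eta <- numeric(n)
  gain <- stats::setNames(numeric(length(unique(spec$var))),
                          unique(spec$var))
  pen_obj <- function(lambda, eta) {
    M <- max(eta)
    sum(lambda * p_mean) - (M + log(sum(exp(eta - M)))) -
      sum(beta * abs(lambda))
  }
  obj <- pen_obj(lambda, eta)
  trace <- obj
  converged <- FALSE
  for (cycle in seq_len(max_outer)) {
    M <- max(eta); w <- exp(eta - M); q <- w / sum(w)
    Eq <- as.vector(crossprod(Fb, q))
    g <- p_mean - Eq
    viol <- ifelse(lambda == 0, pmax(0, abs(g) - beta),
                   abs(g - sign(lambda) * beta))
    viol[!active] <- 0
    if (max(viol) <= tol) { converged <- TRUE; break }
    # Hessian of -loglik: covariance of features under q (+ small ridge)
    Fq <- Fb * sqrt(q)
    H <- crossprod(Fq) - tcrossprod(Eq)
    diag(H) <- diag(H) + 1e-9
    # inner CD on: max g'd - d'Hd/2 - sum beta |lambda + d|
    d <- numeric(J)
    Hd <- numeric(J)
    for (pass in 1:100) {
      max_move <- 0
      for (j in which(active)) {
        a <- H[j, j]
        c_j <- g[j] - Hd[j] + a * d[j]
        z <- lambda[j] + c_j / a
        v <- sign(z) * max(0, abs(z) - beta[j] / a)
        dj_new <- v - lambda[j]
        move <- dj_new - d[j]
        if (move != 0) {
          Hd <- Hd + move * H[, j]
          d[j] <- dj_new
          max_move <- max(max_move, abs(move))
        }
      }
      if (max_move < 1e-10) break
    }
    if (max(abs(d)) == 0) { converged <- max(viol) <= tol; break }
    step_eta <- as.vector(Fb %*% d)
    t_step <- 1
    repeat {
      o <- pen_obj(lambda + t_step * d, eta + t_step * step_eta)
      if (o > obj || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    if (o <= obj) break  # no ascent possible; KKT checked next round
    # first-order credit of this step, pooled per variable
    credit <- abs(g * t_step * d)
    inc <- o - obj
    if (sum(credit) > 0) {
      per_var <- tapply(credit, spec$var, sum)
      gain[names(per_var)] <- gain[names(per_var)] +
        inc * as.vector(per_var) / sum(credit)
    }
    lambda <- lambda + t_step * d
    eta <- eta + t_step * step_eta
    obj <- o
    trace <- c(trace, obj)
  }
  if (!converged) {
    # final KKT check (the loop may exit via the no-ascent branch)
    M <- max(eta); w <- exp(eta - M); q <- w / sum(w)
    g <- p_mean - as.vector(crossprod(Fb, q))
    viol <- ifelse(lambda == 0, pmax(0, abs(g) - beta),
                   abs(g - sign(lambda) * beta))
    viol[!active] <- 0
    converged <- max(viol) <= tol * 10
  }
  if (!converged)
    stop("maxent fit did not converge in ", max_outer,
         " steps; objective trace tail: ",
         paste(sprintf("%.8f", utils::tail(trace, 5)), collapse = ", "))
  M <- max(eta); w <- exp(eta - M); Z <- sum(w)
  log_z <- M + log(Z)
  q <- w / Z
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(spec = spec, lambda = stats::setNames(lambda, spec$name),
                 beta = stats::setNames(beta, spec$name),
                 log_z = log_z, entropy = entropy,
                 presence_means = p_mean, bg_expectations =
                   as.vector(crossprod(Fb, q)),
                 gain = gain, objective = obj, n_presence = m,
                 n_background = n, training_env = training_env,
                 cycles = cycle, reg_multiplier = reg_multiplier),
            class = "maxent_sdm")
}

#' @export
print.maxent_sdm <- function(x, ...) {
  cat("Maximum-entropy extinction-risk model\n")
  cat(sprintf("  %d presences vs %d background cells; %d features (%d active)\n",
              x$n_presence, x$n_background, length(x$lambda),
              sum(x$lambda != 0)))
  cat(sprintf("  penalized objective %.4f; background entropy %.4f; %d cycles\n",
              x$objective, x$entropy, x$cycles))
  pc <- percent_contribution(x)
  top <- sort(pc, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  percent contribution:",
        paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.maxent_sdm <- function(object, ...) object$lambda

#' Predict suitability from a fitted maximum-entropy model
#'
#' @param object a `maxent_sdm`.
#' @param env matrix (rows x variables).
#' @param type `"logistic"` (default) `p = q e^H / (1 + q e^H)` with `H`
#'   the background entropy, `"cloglog"` `1 - exp(-q e^H)`, or `"raw"`
#'   (`q`, summing to 1 over the training background).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_sdm <- function(object, env,
                               type = c("logistic", "cloglog", "raw"),
                               ...) {
  type <- match.arg(type)
  F <- featurize(object$spec, env)
  eta <- as.vector(F %*% object$lambda) - object$log_z
  q <- exp(eta)
  switch(type,
         raw = q,
         logistic = {
           qe <- q * exp(object$entropy)
           qe / (1 + qe)
         },
         cloglog = 1 - exp(-q * exp(object$entropy)))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Exact `P(score_pos > score_neg) + 0.5 P(tie)` via midranks.
#'
#' @param pos,neg score vectors (both nonempty).
#' @return AUC in [0, 1].
#' @export
auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both score sets must be nonempty")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Percent contribution of each variable
#'
#' Share of the positive penalized-objective increments accumulated by each
#' variable's features during coordinate ascent, normalized to 100. The
#' measure is path-dependent (it depends on the update order), as in the
#' reference MaxEnt implementation, and is therefore reported per seeded
#' fit.
#'
#' @param model a `maxent_sdm`.
#' @return named percentage vector summing to 100 (all zero for a null
#'   model with no positive gain).
#' @export
percent_contribution <- function(model) {
  g <- model$gain
  if (sum(g) <= 0) return(g * 0)
  100 * g / sum(g)
}

#' Permutation importance of each variable
#'
#' For each variable, its values are permuted across the pooled
#' presence-plus-background rows, the model is re-scored, and the drop in
#' training AUC is recorded; negative drops are floored at zero and the
#' drops normalized to 100.
#'
#' @param model a `maxent_sdm`.
#' @param pres_env,bg_env the training matrices.
#' @param seed permutation seed.
#' @return named percentage vector (sums to 100 when any positive drop
#'   exists, otherwise all zero).
#' @export
permutation_importance <- function(model, pres_env, bg_env, seed = 1L) {
  vars <- unique(model$spec$var)
  base <- auc(predict(model, pres_env, type = "raw"),
              predict(model, bg_env, type = "raw"))
  m <- nrow(pres_env)
  drops <- with_seed(seed, vapply(vars, function(v) {
    all_env <- rbind(pres_env, bg_env)
    all_env[, v] <- sample(all_env[, v])
    a <- auc(predict(model, all_env[seq_len(m), , drop = FALSE], "raw"),
             predict(model, all_env[-seq_len(m), , drop = FALSE], "raw"))
    base - a
  }, 0))
  drops <- pmax(drops, 0)
  if (sum(drops) <= 0) return(drops * 0)
  100 * drops / sum(drops)
}

#' Sample background cells from an environment layer set
#'
#' Uniform sample without replacement over valid (non-nodata) cells; all
#' valid cells are returned (with a warning) if fewer than `n` exist.
#'
#' @param env an environment layer set from [period_env()].
#' @param n requested background size.
#' @param seed sampling seed.
#' @return list with `cells` (cell ids) and `X` (cells x variables
#'   matrix).
#' @export
sample_background <- function(env, n, seed = 1L) {
  valid <- which(!as.vector(env$nodata))
  if (!length(valid)) stop("no valid cells to sample background from")
  cells <- if (length(valid) <= n) {
    if (length(valid) < n)
      warning("only ", length(valid), " valid cells; using all")
    valid
  } else with_seed(seed, sort(sample(valid, n)))
  list(cells = cells, X = env_at_cells(env, cells))
}

#' Extract an environment matrix at cell ids
#'
#' @param env a [period_env()] layer set.
#' @param cells integer cell ids.
#' @return matrix (cells x variables).
#' @export
env_at_cells <- function(env, cells) {
  X <- vapply(env$layers, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1) X <- matrix(X, 1, dimnames = list(NULL, names(env$layers)))
  colnames(X) <- names(env$layers)
  X
}

#' Single-period environment layer set
#'
#' Averages a covariate stack over one period's slices and keeps the named
#' variables, producing the static layer set used by the risk model and
#' the PCA stage.
#'
#' @param stack a `covariate_stack`.
#' @param period period index (averaged over its slices).
#' @param n_periods number of periods the stack tiles.
#' @param variables layer names to keep (default all).
#' @return object of class `env_layers`: `grid`, `layers` (named list of
#'   matrices), `nodata`.
#' @export
period_env <- function(stack, period, n_periods, variables = NULL) {
  spp <- stack$n_slices %/% n_periods
  sl <- ((period - 1) * spp + 1):(period * spp)
  layers <- stack_slice_mean(stack, sl)
  if (!is.null(variables)) {
    missing <- setdiff(variables, names(layers))
    if (length(missing))
      stop("unknown layer(s): ", paste(missing, collapse = ", "))
    layers <- layers[variables]
  }
  structure(list(grid = stack$grid, layers = layers,
                 nodata = stack$nodata),
            class = "env_layers")
}

#' Pre-experiment variable screen
#'
#' Runs `n_runs` seeded fits (each on a random 75% presence subsample) and
#' drops every variable whose percent contribution is zero and whose
#' permutation importance is zero in all runs — the literal
#' "0% contribution and 0 permutation importance" pre-experiment rule.
#'
#' @param pres_env,bg_env training matrices.
#' @param n_runs number of pre-experiment fits (default 25).
#' @param reg_multiplier passed to [fit_maxent()].
#' @param seed base seed; run `i` uses `seed + i`.
#' @return list with `retained` (character), `dropped`, and `summary`
#'   (per-variable max contribution / importance across runs).
#' @export
prescreen_variables <- function(pres_env, bg_env, n_runs = 25,
                                reg_multiplier = 1.0, seed = 1L) {
  vars <- colnames(pres_env)
  stopifnot(length(vars) >= 1)
  max_pc <- stats::setNames(numeric(length(vars)), vars)
  max_pi <- max_pc
  m <- nrow(pres_env)
  for (i in seq_len(n_runs)) {
    idx <- with_seed(stage_seed(seed, 40 + i),
                     sample(m, max(5, ceiling(0.75 * m))))
    fit <- fit_maxent(pres_env[idx, , drop = FALSE], bg_env,
                      reg_multiplier = reg_multiplier)
    pc <- percent_contribution(fit)
    pi_ <- permutation_importance(fit, pres_env[idx, , drop = FALSE],
                                  bg_env, seed = stage_seed(seed, 80 + i))
    max_pc[names(pc)] <- pmax(max_pc[names(pc)], pc)
    max_pi[names(pi_)] <- pmax(max_pi[names(pi_)], pi_)
  }
  retained <- vars[max_pc > 0 | max_pi > 0]
  if (!length(retained)) stop("pre-experiment dropped every variable")
  list(retained = retained, dropped = setdiff(vars, retained),
       summary = data.frame(var = vars, max_contribution = max_pc,
                            max_importance = max_pi, row.names = NULL))
}

#' Pairwise-correlation variable filter
#'
#' Scans variable pairs by descending |Pearson r|; whenever |r| exceeds
#' `threshold` and both members are still retained, the member with the
#' lower contribution is discarded. Deterministic.
#'
#' @param env matrix used to estimate the correlations (typically the
#'   background).
#' @param contributions named per-variable percentages.
#' @param threshold |r| cutoff (default 0.7).
#' @return list with `retained`, `dropped`, and `log` (pair, r, dropped).
#' @export
correlation_filter <- function(env, contributions, threshold = 0.7) {
  vars <- colnames(env)
  stopifnot(all(vars %in% names(contributions)))
  if (length(vars) < 2)
    return(list(retained = vars, dropped = character(),
                log = data.frame()))
  cm <- suppressWarnings(stats::cor(env))
  cm[!is.finite(cm)] <- 0
  prs <- which(upper.tri(cm), arr.ind = TRUE)
  ord <- order(abs(cm[prs]), decreasing = TRUE)
  retained <- vars
  log_rows <- list()
  for (k in ord) {
    i <- prs[k, 1]; j <- prs[k, 2]
    r <- cm[i, j]
    if (abs(r) <= threshold) break
    v1 <- vars[i]; v2 <- vars[j]
    if (!(v1 %in% retained) || !(v2 %in% retained)) next
    drop <- if (contributions[v1] < contributions[v2]) v1 else v2
    retained <- setdiff(retained, drop)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(var1 = v1, var2 = v2, r = r, dropped = drop)
  }
  list(retained = retained, dropped = setdiff(vars, retained),
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(var1 = character(), var2 = character(), r = numeric(),
                    dropped = character()))
}

#' Replicated fits and the averaged risk surface
#'
#' Runs `replicates` seeded subsample replicates: each holds out
#' `test_fraction` of the presences, fits on the remainder, scores test
#' presences against the background for a test AUC, and predicts the
#' logistic surface over all valid cells. The risk surface is the
#' per-cell mean of the replicate logistic outputs; contributions and
#' importances are averaged across replicates.
#'
#' @param pres_env presence matrix (already restricted to retained
#'   variables).
#' @param bg background list from [sample_background()] (same variables).
#' @param env the [period_env()] layer set predictions are made over.
#' @param replicates number of replicates.
#' @param test_fraction presence fraction held out per replicate.
#' @param reg_multiplier passed to [fit_maxent()].
#' @param seed base seed; replicate `i` uses a derived sub-seed.
#' @return object of class `risk_surface_fit`: `surface` (a
#'   `risk_surface`: matrix with NA nodata plus grid), `auc` per
#'   replicate, `mean_auc`, `sd_auc`, `contribution`, `importance`,
#'   `models` (the first replicate's `maxent_sdm`, kept for inspection).
#' @export
replicate_fit <- function(pres_env, bg, env, replicates = 100,
                          test_fraction = 0.25, reg_multiplier = 1.0,
                          seed = 1L) {
  m <- nrow(pres_env)
  n_test <- floor(m * test_fraction)
  if (n_test < 1)
    stop("test split is empty; reduce test_fraction or add presences")
  if (m - n_test < 5)
    stop("train split too small (", m - n_test, " presences)")
  valid <- which(!as.vector(env$nodata))
  Xall <- env_at_cells(env, valid)
  acc <- numeric(length(valid))
  aucs <- numeric(replicates)
  pc_sum <- NULL; pi_sum <- NULL
  first_model <- NULL
  for (i in seq_len(replicates)) {
    test_idx <- with_seed(stage_seed(seed, 100 + i), sample(m, n_test))
    train <- pres_env[-test_idx, , drop = FALSE]
    test <- pres_env[test_idx, , drop = FALSE]
    fit <- fit_maxent(train, bg$X, reg_multiplier = reg_multiplier)
    if (is.null(first_model)) first_model <- fit
    aucs[i] <- auc(predict(fit, test, type = "raw"),
                   predict(fit, bg$X, type = "raw"))
    acc <- acc + predict(fit, Xall, type = "logistic")
    pc <- percent_contribution(fit)
    pi_ <- permutation_importance(fit, train, bg$X,
                                  seed = stage_seed(seed, 300 + i))
    pc_sum <- if (is.null(pc_sum)) pc else pc_sum + pc
    pi_sum <- if (is.null(pi_sum)) pi_ else pi_sum + pi_
  }
  g <- env$grid
  surf <- matrix(NA_real_, g$n_x, g$n_y)
  surf[valid] <- acc / replicates
  surface <- structure(list(values = surf, grid = g), class = "risk_surface")
  structure(list(surface = surface, auc = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs),
                 contribution = pc_sum / replicates,
                 importance = pi_sum / replicates,
                 model = first_model, replicates = replicates),
            class = "risk_surface_fit")
}

#' @export
print.risk_surface_fit <- function(x, ...) {
  cat(sprintf("Replicated extinction-risk model: %d replicate(s)\n",
              x$replicates))
  cat(sprintf("  mean test AUC %.3f (sd %.3f)\n", x$mean_auc,
              if (is.na(x$sd_auc)) 0 else x$sd_auc))
  rng <- range(x$surface$values, na.rm = TRUE)
  cat(sprintf("  risk surface range %.3f-%.3f\n", rng[1], rng[2]))
  pc <- sort(x$contribution, decreasing = TRUE)
  cat("  mean contribution:",
      paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "), "\n")
  invisible(x)
}

#' Look up risk-surface values at point locations
#'
#' @param surface a `risk_surface`.
#' @param lon,lat coordinates.
#' @return numeric values (NA outside the domain or on nodata cells).
#' @export
surface_at <- function(surface, lon, lat) {
  g <- surface$grid
  out <- rep(NA_real_, length(lon))
  ok <- lon >= g$origin_lon & lat >= g$origin_lat &
    lon <= g$origin_lon + g$n_x * g$cell_degrees &
    lat <= g$origin_lat + g$n_y * g$cell_degrees
  if (any(ok))
    out[ok] <- surface$values[assign_cell(lon[ok], lat[ok], g)]
  out
}
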