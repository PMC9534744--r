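#' Screen collinear predictors before the additive-model fit
#'
#' For every pair of candidate covariates whose Pearson |r| exceeds
#' `threshold`, single-smooth binomial fits of the fate response on each
#' member are compared and the member with the worse fit (lower adjusted
#' R-squared; AIC as tie-breaker) is dropped. Constant predictors are
#' excluded outright. The original analysis used this rule to drop the
#' China-wide human population total, which tracks the temperature proxy
#' at r = .98 over the study window.
#'
#' @param rows fate-row data.frame containing `fate` and the candidates.
#' @param candidates character vector of covariate column names.
#' @param threshold Pearson |r| above which a pair is adjudicated
#'   (default 0.95).
#' @return list with `kept` (character vector) and `log` (data.frame of
#'   adjudications: variables, r, p, adjusted R-squared and AIC of each
#'   single-term fit, the member dropped, or the zero-variance reason).
#' @export
screen_collinear_predictors <- function(rows, candidates,
                                        threshold = 0.95) {
  stopifnot(length(candidates) >= 2, nrow(rows) >= 3)
  log_rows <- list()
  kept <- candidates
  const <- vapply(candidates, function(v)
    stats::sd(rows[[v]]) == 0 || !is.finite(stats::sd(rows[[v]])), TRUE)
  for (v in candidates[const]) {
    kept <- setdiff(kept, v)
    log_rows[[length(log_rows) + 1]] <- data.frame(
      var1 = v, var2 = NA, r = NA, p = NA, dropped = v,
      reason = "zero variance")
  }
  single_fit <- function(v) {
    d <- data.frame(fate = rows$fate, x = rows[[v]])
    f <- mgcv::gam(fate ~ s(x, k = 10), family = stats::binomial(),
                   data = d, method = "GCV.Cp")
    c(adj_r2 = summary(f)$r.sq, aic = stats::AIC(f))
  }
  pairs <- if (length(kept) >= 2)
    utils::combn(kept, 2, simplify = FALSE) else list()
  for (pr in pairs) {
    if (!all(pr %in% kept)) next
    ct <- stats::cor.test(rows[[pr[1]]], rows[[pr[2]]])
    if (abs(ct$estimate) <= threshold) next
    f1 <- single_fit(pr[1]); f2 <- single_fit(pr[2])
    # worse = lower adjusted R2; ties by higher AIC
    drop <- if (f1["adj_r2"] != f2["adj_r2"]) {
      pr[which.min(c(f1["adj_r2"], f2["adj_r2"]))]
    } else pr[which.max(c(f1["aic"], f2["aic"]))]
    kept <- setdiff(kept, drop)
    log_rows[[length(log_rows) + 1]] <- data.frame(
      var1 = pr[1], var2 = pr[2], r = unname(ct$estimate),
      p = ct$p.value, dropped = drop, reason = "collinear")
  }
  list(kept = kept,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(var1 = character(), var2 = character(), r = numeric(),
                    p = numeric(), dropped = character(),
                    reason = character()))
}

#' Fit the additive logistic extinction model
#'
#' Penalized-spline binomial GAM of the 0/1 fate response: thin-regularized
#' cubic smooths for each covariate plus a tensor-product surface in
#' (lon, lat), smoothing parameters chosen by GCV (REML available). The
#' fit itself is delegated to mgcv; this wrapper fixes the model form,
#' collects the per-term summary the pipeline reports, and defines the fit
#' statistics used downstream: deviance explained = 1 - D_model/D_null,
#' and adjusted R-squared = 1 - (1 - D_expl) (n - 1) / (n - edf - 1).
#'
#' @param rows fate-row data.frame (`fate`, `lon`, `lat`, covariates).
#' @param smooth_vars covariate names to receive univariate smooths; empty
#'   for an intercept-only fit.
#' @param spatial include the tensor-product (lon, lat) smooth.
#' @param k basis size per univariate smooth (default 10).
#' @param k_spatial marginal basis size of the spatial tensor (default 5).
#' @param method smoothing criterion, `"REML"` (default; more stable than
#'   GCV for binary responses) or `"GCV.Cp"`.
#' @param gamma smoothing-parameter inflation passed to mgcv (default 1.4,
#'   the standard correction against undersmoothing).
#' @return object of class `extinction_gam`: list with the mgcv `fit`,
#'   `terms` (per-smooth edf, chi-square, p-value), `deviance_explained`,
#'   `adj_r2`, `n`, `fitted`.
#' @export
fit_extinction_gam <- function(rows, smooth_vars, spatial = TRUE,
                               k = 10, k_spatial = 5,
                               method = c("REML", "GCV.Cp"),
                               gamma = 1.4) {
  method <- match.arg(method)
  stopifnot(all(c("fate", smooth_vars) %in% names(rows)))
  terms <- character()
  if (length(smooth_vars))
    terms <- sprintf("s(%s, k = %d)", smooth_vars, k)
  if (spatial)
    terms <- c(terms, sprintf("te(lon, lat, k = %d)", k_spatial))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("fate ~", rhs))
  nb <- length(smooth_vars) * k + if (spatial) k_spatial^2 else 0
  if (nb > 0 && nrow(rows) < 10 * nb)
    warning("fewer than 10 rows per basis function (n = ", nrow(rows),
            ", total basis ", nb, ")")
  fit <- tryCatch(
    mgcv::gam(form, family = stats::binomial(), data = rows,
              method = method, gamma = gamma),
    error = function(e) {
      # REML can fail outright under (near-)separation; fall back to GCV
      warning("smoothing-criterion failure (", conditionMessage(e),
              "); refitting with GCV")
      mgcv::gam(form, family = stats::binomial(), data = rows,
                method = "GCV.Cp", gamma = gamma)
    })
  if (any(abs(fit$linear.predictors) > 30)) {
    warning("possible separation (|linear predictor| > 30); ",
            "refitting with extra ridge penalty")
    fit <- mgcv::gam(form, family = stats::binomial(), data = rows,
                     method = method, gamma = gamma,
                     H = diag(1e-4, length(stats::coef(fit))))
  }
  sm <- summary(fit)
  dev_expl <- 1 - fit$deviance / fit$null.deviance
  edf_tot <- sum(fit$edf)
  n <- nrow(rows)
  adj <- 1 - (1 - dev_expl) * (n - 1) / (n - edf_tot - 1)
  term_tab <- if (!is.null(sm$s.table) && nrow(sm$s.table)) data.frame(
    term = rownames(sm$s.table), edf = sm$s.table[, "edf"],
    chi_sq = sm$s.table[, "Chi.sq"],
    p_value = sm$s.table[, "p-value"], row.names = NULL) else
      data.frame(term = character(), edf = numeric(), chi_sq = numeric(),
                 p_value = numeric())
  structure(list(fit = fit, terms = term_tab,
                 deviance_explained = dev_expl, adj_r2 = adj, n = n,
                 fitted = stats::fitted(fit), smooth_vars = smooth_vars,
                 spatial = spatial),
            class = "extinction_gam")
}

#' @export
print.extinction_gam <- function(x, ...) {
  cat("Additive logistic extinction model (penalized splines)\n")
  cat(sprintf("  n = %d fate rows; deviance explained = %.3f; adjusted R2 = %.3f\n",
              x$n, x$deviance_explained, x$adj_r2))
  if (nrow(x$terms)) {
    stars <- ifelse(x$terms$p_value < .001, "***",
                    ifelse(x$terms$p_value < .01, "**",
                           ifelse(x$terms$p_value < .05, "*", "")))
    for (i in seq_len(nrow(x$terms)))
      cat(sprintf("  %-22s edf %5.2f  Chi.sq %8.2f  p %.4g %s\n",
                  x$terms$term[i], x$terms$edf[i], x$terms$chi_sq[i],
                  x$terms$p_value[i], stars[i]))
  }
  invisible(x)
}

#' @export
summary.extinction_gam <- function(object, ...) summary(object$fit, ...)

#' Centered partial effect of one smooth
#'
#' Evaluates the fitted smooth of `var` on a grid of values, centered, with
#' a pointwise plus/minus 2 SE band from the penalized covariance matrix.
#' Other covariates are held at their training means (the smooth's own
#' contribution does not depend on them).
#'
#' @param object an `extinction_gam`.
#' @param var one of the fitted smooth variables.
#' @param values numeric grid; default 50 points over the training range.
#' @return data.frame `value`, `effect` (logit scale, centered), `lower`,
#'   `upper`.
#' @export
partial_effect <- function(object, var, values = NULL) {
  if (!var %in% object$smooth_vars)
    stop("'", var, "' is not a smooth term of this model")
  dat <- object$fit$model
  if (is.null(values))
    values <- seq(min(dat[[var]]), max(dat[[var]]), length.out = 50)
  nd <- dat[rep(1, length(values)), , drop = FALSE]
  for (v in setdiff(names(nd), c("fate", var)))
    nd[[v]] <- mean(dat[[v]])
  nd[[var]] <- values
  pr <- mgcv::predict.gam(object$fit, newdata = nd, type = "terms",
                          se.fit = TRUE)
  col <- grep(paste0("s\\(", var, "\\)"), colnames(pr$fit))
  if (length(col) != 1) stop("could not locate the smooth for '", var, "'")
  eff <- pr$fit[, col] - mean(pr$fit[, col])
  se <- pr$se.fit[, col]
  data.frame(value = values, effect = eff,
             lower = eff - 2 * se, upper = eff + 2 * se)
}

#' @export
plot.extinction_gam <- function(x, var = x$smooth_vars[1], ...) {
  pe <- partial_effect(x, var)
  graphics::plot(pe$value, pe$effect, type = "l",
                 xlab = var, ylab = "effect on logit(extinction)", ...)
  graphics::lines(pe$value, pe$lower, lty = 2)
  graphics::lines(pe$value, pe$upper, lty = 2)
  invisible(pe)
}
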