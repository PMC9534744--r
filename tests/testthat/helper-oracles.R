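# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# Exhaustive Fisher-Jenks: enumerate every partition of sorted values into
# k contiguous classes and return the minimum total within-class SSD.
brute_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd(x))
  best <- Inf
  # choose k-1 cut points out of n-1 gaps
  for (cuts in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cuts, n)
    tot <- 0
    for (i in seq_len(k))
      tot <- tot + ssd(x[(bounds[i] + 1):bounds[i + 1]])
    if (tot < best) best <- tot
  }
  best
}

# Exhaustive max-SSS scan over all candidate thresholds.
brute_max_sss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_sum <- -Inf; best_t <- NA
  for (t in cand) {
    s <- mean(pres >= t) + mean(bg < t)
    if (s > best_sum + 1e-12) { best_sum <- s; best_t <- t }
  }
  list(threshold = best_t, sum = best_sum)
}

# Exhaustive per-cell fate enumeration: for each cell, walk its detection
# periods directly.
brute_encode <- function(det_cells, det_periods, n_periods) {
  out <- list()
  for (cell in sort(unique(det_cells))) {
    p <- det_periods[det_cells == cell]
    last <- max(p)
    out[[length(out) + 1]] <- data.frame(cell_id = cell, period = last,
                                         fate = 0L)
    if (last + 1 <= n_periods)
      out[[length(out) + 1]] <- data.frame(cell_id = cell,
                                           period = last + 1L, fate = 1L)
  }
  res <- do.call(rbind, out)
  res[order(res$cell_id, res$period), c("cell_id", "period", "fate")]
}

# Small single-slice stack on an nx x ny grid from named matrices.
tiny_env <- function(layers, origin = c(100, 20), cell = 0.5) {
  nx <- nrow(layers[[1]]); ny <- ncol(layers[[1]])
  g <- grid_spec(origin[1], origin[2], cell, nx, ny)
  st <- covariate_stack(layers, g)
  period_env(st, 1, 1)
}

# Separable presence/background fixture: presences occupy the top-right
# corner of (a, b) space with a clear margin to the nearest background
# point, so a perfect training ranking is attainable.
separable_fixture <- function(n_pres = 50, n_bg = 400, seed = 1) {
  set.seed(seed)
  a <- runif(3 * n_bg); b <- runif(3 * n_bg)
  keep <- !(a > 0.8 & b > 0.8)
  bg <- cbind(a = a[keep][1:n_bg], b = b[keep][1:n_bg])
  pres <- cbind(a = runif(n_pres, 0.9, 1), b = runif(n_pres, 0.9, 1))
  list(pres = pres, bg = bg)
}
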