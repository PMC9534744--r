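#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every distinct score value as a candidate threshold `t`;
#' sensitivity is the fraction of presences with score >= t, specificity
#' the fraction of background with score < t. Returns the candidate
#' maximising their sum (ties broken by the smallest t).
#'
#' @param pres,bg score vectors (both nonempty).
#' @return object of class `sss_threshold`: `threshold`, `sensitivity`,
#'   `specificity`, `sum`.
#' @export
max_sss_threshold <- function(pres, bg) {
  if (!length(pres) || !length(bg)) stop("empty score set")
  cand <- sort(unique(c(pres, bg)))
  sens <- vapply(cand, function(t) mean(pres >= t), 0)
  spec <- vapply(cand, function(t) mean(bg < t), 0)
  tot <- sens + spec
  # smallest candidate within float tolerance of the maximum (ties break
  # toward the smaller threshold)
  i <- which(tot >= max(tot) - 1e-12)[1]
  structure(list(threshold = cand[i], sensitivity = sens[i],
                 specificity = spec[i], sum = sens[i] + spec[i]),
            class = "sss_threshold")
}

#' @export
print.sss_threshold <- function(x, ...) {
  cat(sprintf("max-SSS threshold %.4f (sensitivity %.3f + specificity %.3f = %.3f)\n",
              x$threshold, x$sensitivity, x$specificity, x$sum))
  invisible(x)
}

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic program minimising the total within-class sum of squared
#' deviations over all partitions of the sorted values into `k` contiguous
#' classes. Ties are broken toward the smallest class-boundary index.
#'
#' @param values numeric vector (`n >= k`).
#' @param k number of classes (>= 1).
#' @return numeric vector of `k` class maxima in ascending order (the last
#'   is `max(values)`), with attribute `ssd` (the achieved minimum).
#' @export
jenks_breaks <- function(values, k) {
  n <- length(values)
  if (k > n) stop("k (", k, ") exceeds the number of values (", n, ")")
  if (k < 1) stop("k must be >= 1")
  x <- sort(values)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[(i+1)..j], 0-based prefix offsets
  seg <- function(i, j) {
    s <- cs[j] - if (i > 0) cs[i] else 0
    s2 <- cs2[j] - if (i > 0) cs2[i] else 0
    s2 - s^2 / (j - i)
  }
  cost <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- seg(0, j)
  if (k > 1) for (c in 2:k) for (j in c:n) {
    for (i in (c - 1):(j - 1)) {
      v <- cost[c - 1, i] + seg(i, j)
      if (v < cost[c, j]) { cost[c, j] <- v; split_at[c, j] <- i }
    }
  }
  ends <- integer(k)
  j <- n
  for (c in k:1) { ends[c] <- j; j <- if (c > 1) split_at[c, j] else 0 }
  structure(x[ends], ssd = cost[k, n])
}

#' Classify extant sites by extinction risk
#'
#' Each site takes the risk value of its containing surface cell. Sites
#' below the threshold are "none"; Fisher-Jenks with `k` classes on the
#' remaining risks defines the ascending levels (`"low"`, `"moderate"`,
#' `"high"` for `k = 3`). `k` is reduced when fewer at-risk sites than
#' classes exist. Sites outside the surface domain (or on nodata cells)
#' are excluded from all denominators with a warning.
#'
#' @param surface a `risk_surface` (from [replicate_fit()]).
#' @param sites data.frame with `id`, `lon`, `lat` and optionally
#'   `region` for regional tallies.
#' @param threshold probability below which a site is at no risk
#'   (typically the [max_sss_threshold()]).
#' @param k number of at-risk classes (default 3).
#' @return object of class `risk_classes`: `sites` (with `risk` and
#'   `class`), `breaks`, `threshold`, `counts`, `percentages` (half-up,
#'   2 dp), `notable_pct` (moderate + high), `regional` (class x region
#'   table or NULL), `n_excluded`.
#' @export
classify_sites <- function(surface, sites, threshold, k = 3) {
  risk <- surface_at(surface, sites$lon, sites$lat)
  excluded <- is.na(risk)
  if (any(excluded))
    warning(sum(excluded), " site(s) outside the risk surface; excluded")
  s <- sites[!excluded, , drop = FALSE]
  s$risk <- risk[!excluded]
  labels_all <- c("low", "moderate", "high")
  s$class <- "none"
  at_risk <- s$risk >= threshold
  breaks <- numeric()
  if (any(at_risk)) {
    k_eff <- min(k, length(unique(s$risk[at_risk])), sum(at_risk))
    breaks <- as.numeric(jenks_breaks(s$risk[at_risk], k_eff))
    lab <- utils::tail(labels_all, k_eff)
    s$class[at_risk] <- lab[findInterval(s$risk[at_risk],
                                         breaks[-length(breaks)] +
                                           .Machine$double.eps^.5) + 1]
  }
  lv <- c("none", labels_all)
  counts <- table(factor(s$class, levels = lv))
  pct <- if (nrow(s)) round_half_up(100 * as.numeric(counts) / nrow(s), 2)
    else rep(0, length(lv))
  names(pct) <- lv
  notable <- round_half_up(sum(pct[c("moderate", "high")]), 2)
  regional <- if ("region" %in% names(s))
    table(region = s$region, class = factor(s$class, levels = lv))
  structure(list(sites = s, breaks = breaks, threshold = threshold,
                 counts = counts, percentages = pct,
                 notable_pct = notable, regional = regional,
                 n_excluded = sum(excluded)),
            class = "risk_classes")
}

#' @export
print.risk_classes <- function(x, ...) {
  cat(sprintf("Site risk classification (threshold %.3f; breaks %s)\n",
              x$threshold, paste(sprintf("%.3f", x$breaks), collapse = ", ")))
  for (lv in names(x$percentages))
    cat(sprintf("  %-9s %4d site(s)  %6.2f%%\n", lv, x$counts[[lv]],
                x$percentages[[lv]]))
  cat(sprintf("  notable (moderate + high): %.2f%%\n", x$notable_pct))
  if (x$n_excluded) cat("  excluded (outside surface):", x$n_excluded, "\n")
  invisible(x)
}

# Round half away from zero (the convention behind the reported
# percentages), to `digits` decimals.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Accounting report over bins
#'
#' Sums nonnegative bins and derives percentage shares (half-up, 2
#' decimals), mirroring the record-count accounting style of the original
#' study's results (e.g. 35 + 142 dispersed records, or a province's share
#' of the at-risk sites).
#'
#' @param parts named nonnegative numeric vector of bin values.
#' @param total denominator for the shares; defaults to `sum(parts)`.
#' @return list with `parts`, `total`, and `shares` (percent, 2 dp).
#' @export
report_accounting <- function(parts, total = NULL) {
  stopifnot(all(parts >= 0))
  if (is.null(total)) total <- sum(parts)
  if (total == 0 && any(parts > 0))
    stop("zero total with nonzero parts")
  shares <- if (total > 0) round_half_up(100 * parts / total, 2)
    else parts * 0
  list(parts = parts, total = total, shares = shares)
}
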