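#' Extract environmental values at record locations
#'
#' Looks up each named layer at the cell containing each record. Records
#' falling on nodata cells (or outside the domain) are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param records data.frame with `lon`, `lat`.
#' @param env an [period_env()] layer set.
#' @param variables layer names to extract (default all).
#' @return matrix (records x variables); attribute `n_dropped`.
#' @export
extract_env_at_records <- function(records, env, variables = NULL) {
  if (is.null(variables)) variables <- names(env$layers)
  missing <- setdiff(variables, names(env$layers))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  cells <- assign_cell(records$lon, records$lat, env$grid,
                       ids = records$id)
  X <- env_at_cells(env, cells)[, variables, drop = FALSE]
  bad <- apply(is.na(X), 1, any)
  out <- X[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Principal component analysis of extinction-site environments
#'
#' Correlation-matrix PCA via singular value decomposition of the
#' column-standardized data (variables mix units — persons, millimetres,
#' degrees — so standardization is the default). Components are ordered
#' by variance; the sign convention makes the largest-magnitude loading
#' of each component positive. Per-variable contributions to a component
#' are 100 x squared loading.
#'
#' @param x numeric matrix (>= 2 rows, >= 2 finite columns).
#' @param standardize divide columns by their SD (default TRUE); a
#'   zero-variance column is an error when TRUE.
#' @return object of class `env_pca`: `loadings` (p x p, orthonormal
#'   columns), `ratios` (variance-explained fractions, nonincreasing,
#'   summing to 1), `scores` (n x p), `contributions` (p x p percent
#'   matrix; each column sums to 100), `sdev`.
#' @export
env_pca <- function(x, standardize = TRUE) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2)
  if (any(!is.finite(x))) stop("non-finite values in PCA input")
  ctr <- scale(x, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    zero <- s == 0
    if (any(zero))
      stop("zero-variance column(s): ",
           paste(colnames(x)[zero], collapse = ", "))
    ctr <- sweep(ctr, 2, s, "/")
  }
  sv <- svd(ctr)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  V <- sweep(sv$v, 2, flip, "*")
  U <- sweep(sv$u, 2, flip, "*")
  ratios <- sv$d^2 / sum(sv$d^2)
  scores <- U %*% diag(sv$d, length(sv$d))
  rownames(V) <- colnames(x)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  colnames(scores) <- colnames(V)
  structure(list(loadings = V, ratios = ratios, scores = scores,
                 contributions = 100 * V^2,
                 sdev = sv$d / sqrt(nrow(x) - 1)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of extinction-site environments\n")
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$ratios),
                    100 * x$ratios), collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative variance explained by the leading components
#'
#' @param pca an `env_pca`.
#' @param n_components number of leading components (default 2).
#' @return percentage (0-100), rounded half-up to 2 decimals.
#' @export
variance_summary <- function(pca, n_components = 2) {
  stopifnot(n_components <= length(pca$ratios))
  round_half_up(100 * sum(pca$ratios[seq_len(n_components)]), 2)
}
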