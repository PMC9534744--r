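#' Encode dated occurrences as gridded fate rows
#'
#' Implements the chronicle fate-coding rule on a grid of half-open cells
#' and half-open periods. For every cell with at least one detection the
#' encoder emits a presence row (`fate = 0`) at the last detection period,
#' and an absence row (`fate = 1`) at the immediately following period
#' provided that period is still inside the study window — i.e. the cell's
#' disappearance was observed rather than right-censored. A re-detection
#' after a gap cancels any earlier putative absence, because the rule keys
#' on the *last* detection. Each observed extinction event therefore
#' contributes exactly one 0-row and one 1-row.
#'
#' With `presence_rows = "all"` a presence row is emitted at every
#' detection period instead (sensitivity analysis); absence rows are
#' unchanged.
#'
#' @param records occurrence data.frame (`id, lon, lat, year`).
#' @param grid a [grid_spec()].
#' @param periods a [period_spec()].
#' @param presence_rows `"last"` (default) or `"all"`.
#' @return data.frame with `cell_id`, `period`, `fate` (0 presence / 1
#'   absence), and cell-centre `lon`, `lat`; ordered by cell then period.
#'   Empty input yields an empty data.frame.
#' @export
encode_fates <- function(records, grid, periods,
                         presence_rows = c("last", "all")) {
  presence_rows <- match.arg(presence_rows)
  empty <- data.frame(cell_id = integer(), period = integer(),
                      fate = integer(), lon = numeric(), lat = numeric())
  if (nrow(records) == 0) return(empty)
  cell <- assign_cell(records$lon, records$lat, grid, ids = records$id)
  per <- bin_period(records$year, periods)
  rows <- lapply(split(per, cell), function(p) {
    last <- max(p)
    pres <- if (presence_rows == "all") sort(unique(p)) else last
    out <- data.frame(period = pres, fate = 0L)
    if (last < periods$n_periods)
      out <- rbind(out, data.frame(period = last + 1L, fate = 1L))
    out
  })
  cell_ids <- as.integer(names(rows))
  n_each <- vapply(rows, nrow, 0L)
  res <- do.call(rbind, rows)
  res$cell_id <- rep(cell_ids, n_each)
  cc <- cell_center(res$cell_id, grid)
  res <- data.frame(cell_id = res$cell_id, period = res$period,
                    fate = res$fate, lon = cc$lon, lat = cc$lat)
  res <- res[order(res$cell_id, res$period), ]
  rownames(res) <- NULL
  res
}

#' Restrict fate rows to observed extinction events
#'
#' Keeps only the rows of cells with an observed absence row, i.e. the
#' presence/absence pairs of uncensored extinction events; cells whose last
#' detection falls in the final period (right-censored) are dropped. With
#' the default last-detection presence coding this leaves exactly
#' `2 x (number of extinction events)` rows, the observation count the
#' additive-model stage is fitted on.
#'
#' @param fates output of [encode_fates()] (optionally with covariates).
#' @return the subset of `fates` belonging to cells with a fate-1 row.
#' @export
uncensored_rows <- function(fates) {
  ext_cells <- unique(fates$cell_id[fates$fate == 1])
  out <- fates[fates$cell_id %in% ext_cells, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach period-averaged covariates to fate rows
#'
#' The emulated inputs have a 10-year resolution inside 30-year periods, so
#' each fate row receives the arithmetic mean of its period's slices at its
#' cell, one column per stack layer. Rows falling on nodata cells are
#' dropped; their count is attached as attribute `n_dropped_nodata`.
#'
#' @param fates output of [encode_fates()].
#' @param stack a `covariate_stack` whose slices tile the study window
#'   (`n_slices = n_periods * slices_per_period`).
#' @param n_periods number of periods the slices tile.
#' @return `fates` with one numeric column per layer appended.
#' @export
attach_covariates <- function(fates, stack, n_periods) {
  if (stack$n_slices %% n_periods != 0)
    stop("stack has ", stack$n_slices, " slices; not a multiple of ",
         n_periods, " periods")
  spp <- stack$n_slices %/% n_periods
  if (max(fates$period, 0) > n_periods)
    stop("fate rows reference period beyond the stack coverage")
  for (nm in names(stack$layers)) fates[[nm]] <- NA_real_
  for (t in sort(unique(fates$period))) {
    sl <- ((t - 1) * spp + 1):(t * spp)
    m <- stack_slice_mean(stack, sl)
    sel <- fates$period == t
    for (nm in names(m))
      fates[[nm]][sel] <- m[[nm]][fates$cell_id[sel]]
  }
  on_nodata <- as.vector(stack$nodata)[fates$cell_id]
  out <- fates[!on_nodata, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nodata") <- sum(on_nodata)
  out
}
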