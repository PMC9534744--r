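#' Pipeline configuration
#'
#' Builds a validated configuration object holding every tunable constant of
#' the chronicle pipeline. Defaults are the study conditions of the original
#' Chinese pangolin analysis: 0.5-degree grid cells (about 50 x 50 km),
#' ten 30-year periods over 1700-2000 AD, 50-km buffers around extant
#' records, 10-km rarefaction, 100 maximum-entropy replicates.
#'
#' @param grid_cell_degrees cell size of the analysis grid, decimal degrees.
#' @param period_years length of one fate period, years.
#' @param study_start,study_end study window, years AD; `period_years` must
#'   divide `study_end - study_start`.
#' @param buffer_km radius of the circular buffers drawn around extant
#'   records when screening for extinction records, km.
#' @param rarefy_km minimum distance retained between extinction records
#'   after spatial rarefaction, km.
#' @param background_n number of background cells sampled for the
#'   maximum-entropy model (all valid cells are used if fewer exist).
#' @param replicates number of replicate maximum-entropy fits averaged into
#'   the risk surface.
#' @param prescreen_runs number of pre-experiment fits used to drop
#'   variables with zero contribution and zero permutation importance.
#' @param test_fraction fraction of presences held out per replicate for
#'   test AUC, in (0, 1).
#' @param reg_multiplier L1 regularisation multiplier of the
#'   maximum-entropy fit.
#' @param cor_threshold Pearson |r| above which the lower-contribution
#'   member of a variable pair is discarded.
#' @param collinear_threshold Pearson |r| above which the additive-model
#'   stage compares single-term fits and drops the weaker variable.
#' @param jenks_k number of natural-breaks classes above the threshold.
#' @param presence_rows `"last"` (default) places one presence row at the
#'   last detection period of a cell; `"all"` places one at every detection
#'   period (sensitivity analysis).
#' @param rng_seed integer seed from which all stage sub-streams derive.
#' @return an object of class `chronex_config` (a named list).
#' @export
chronex_config <- function(grid_cell_degrees = 0.5,
                           period_years = 30,
                           study_start = 1700,
                           study_end = 2000,
                           buffer_km = 50,
                           rarefy_km = 10,
                           background_n = 10000,
                           replicates = 100,
                           prescreen_runs = 25,
                           test_fraction = 0.25,
                           reg_multiplier = 1.0,
                           cor_threshold = 0.7,
                           collinear_threshold = 0.95,
                           jenks_k = 3,
                           presence_rows = c("last", "all"),
                           rng_seed = 1L) {
  presence_rows <- match.arg(presence_rows)
  cfg <- list(
    grid_cell_degrees = grid_cell_degrees, period_years = period_years,
    study_start = study_start, study_end = study_end,
    buffer_km = buffer_km, rarefy_km = rarefy_km,
    background_n = as.integer(background_n),
    replicates = as.integer(replicates),
    prescreen_runs = as.integer(prescreen_runs),
    test_fraction = test_fraction, reg_multiplier = reg_multiplier,
    cor_threshold = cor_threshold,
    collinear_threshold = collinear_threshold,
    jenks_k = as.integer(jenks_k), presence_rows = presence_rows,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "chronex_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "chronex_config"))
  with(cfg, {
    if (grid_cell_degrees <= 0) stop("grid_cell_degrees must be > 0")
    if (buffer_km <= 0 || rarefy_km <= 0) stop("distances must be > 0")
    if (!(test_fraction > 0 && test_fraction < 1))
      stop("test_fraction must lie in (0, 1)")
    if (study_end <= study_start) stop("study_end must exceed study_start")
    if ((study_end - study_start) %% period_years != 0)
      stop("period_years must divide study_end - study_start")
    if (replicates < 1 || background_n < 1 || jenks_k < 1)
      stop("counts must be >= 1")
  })
  invisible(cfg)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file of `key: value` pairs; any subset of the
#'   [chronex_config()] arguments.
#' @return a `chronex_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(chronex_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(chronex_config, raw)
}

#' @export
print.chronex_config <- function(x, ...) {
  cat("chronex pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Derive a stage-specific sub-seed from the master seed by a fixed offset,
# kept below 2^31 so it stays a valid R integer.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000L * offset) %% 2147483647)
}
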