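## Pipeline orchestration: each stage reads its inputs from the output
## directory of the previous stages, writes plain-text artifacts (CSV,
## ESRI ASCII, GeoJSON, JSON) plus a run manifest, and logs one line with
## its in/out counts.

stage_log <- function(verbose, fmt, ...)
  if (verbose) message(sprintf(paste0("[chronex] ", fmt), ...))

write_manifest <- function(out_dir, stage, inputs, outputs, cfg, seed) {
  existing <- inputs[file.exists(inputs)]
  man <- list(stage = stage,
              inputs = as.list(tools::md5sum(existing)),
              outputs = outputs,
              config = unclass(cfg), seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

need_inputs <- function(out_dir, files, stage, produced_by) {
  paths <- file.path(out_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing input(s) ",
         paste(missing, collapse = ", "),
         "; run the '", produced_by, "' stage first")
  invisible(paths)
}

# Generator study conditions, tied to the pipeline config where the two
# overlap (cell size, period structure, master seed).
sim_params_from_config <- function(cfg) {
  simulation_params(
    cell_degrees = cfg$grid_cell_degrees,
    n_periods = (cfg$study_end - cfg$study_start) %/% cfg$period_years,
    seed = cfg$rng_seed)
}

stage_simulate <- function(cfg, out_dir, verbose = FALSE) {
  params <- sim_params_from_config(cfg)
  stack <- simulate_covariates(params)
  sim <- simulate_chronicles(params, stack, study_start = cfg$study_start,
                             period_years = cfg$period_years)
  ext <- simulate_extant_and_range(sim$truth, params)
  write_occurrences(sim$occurrences, file.path(out_dir, "occurrences.csv"))
  write_occurrences(ext$extant, file.path(out_dir, "extant.csv"))
  write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.csv"))
  write_range_polygon(ext$range, file.path(out_dir, "range.geojson"))
  paths <- write_raster_stack(stack, file.path(out_dir, "rasters"))
  jsonlite::write_json(paths, file.path(out_dir, "rasters", "stack.json"),
                       auto_unbox = FALSE, digits = NA)
  stage_log(verbose,
            "simulate: %d historical record(s), %d extant, %d/%d cell(s) extinct",
            nrow(sim$occurrences), nrow(ext$extant),
            sum(!is.na(sim$truth$first_extinct_period)),
            nrow(sim$truth$occupancy))
  write_manifest(out_dir, "simulate", character(),
                 c("occurrences.csv", "extant.csv", "ground_truth.csv",
                   "range.geojson", "rasters/"), cfg, cfg$rng_seed)
  invisible(TRUE)
}

read_stack_dir <- function(out_dir) {
  idx <- file.path(out_dir, "rasters", "stack.json")
  if (!file.exists(idx))
    stop("no raster stack under ", out_dir, "; run 'simulate' first")
  paths <- jsonlite::read_json(idx, simplifyVector = TRUE)
  read_raster_stack(lapply(paths, function(p)
    ifelse(file.exists(p), p, file.path(out_dir, "rasters", basename(p)))))
}

stage_encode <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, "occurrences.csv", "encode", "simulate")
  occ <- read_occurrences(file.path(out_dir, "occurrences.csv"))
  stack <- read_stack_dir(out_dir)
  periods <- period_from_config(cfg)
  fates <- encode_fates(occ, stack$grid, periods,
                        presence_rows = cfg$presence_rows)
  fates <- attach_covariates(fates, stack, periods$n_periods)
  # China-wide population total per period (the "holistic" covariate the
  # source analysis screened against the temperature proxy)
  totals <- vapply(seq_len(periods$n_periods), function(t) {
    m <- period_env(stack, t, periods$n_periods, "popc")$layers$popc
    sum(m, na.rm = TRUE)
  }, 0)
  fates$population <- totals[fates$period]
  utils::write.csv(fates, file.path(out_dir, "fate_rows.csv"),
                   row.names = FALSE, quote = FALSE)
  stage_log(verbose, "encode: %d record(s) -> %d fate row(s) (%d absence)",
            nrow(occ), nrow(fates), sum(fates$fate == 1))
  write_manifest(out_dir, "encode",
                 file.path(out_dir, "occurrences.csv"),
                 "fate_rows.csv", cfg, cfg$rng_seed)
  invisible(TRUE)
}

gam_candidate_vars <- c("popd", "popc", "cropland", "grazing",
                        "population", "temperature",
                        "regional_temperature")

stage_gam <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, "fate_rows.csv", "gam", "encode")
  rows <- uncensored_rows(utils::read.csv(file.path(out_dir,
                                                    "fate_rows.csv")))
  scr <- screen_collinear_predictors(rows, gam_candidate_vars,
                                     threshold = cfg$collinear_threshold)
  fit <- fit_extinction_gam(rows, scr$kept)
  summary_json <- list(
    n = fit$n, deviance_explained = fit$deviance_explained,
    adjusted_r2 = fit$adj_r2,
    terms = fit$terms,
    screened_out = scr$log)
  jsonlite::write_json(summary_json,
                       file.path(out_dir, "gam_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  for (v in intersect(c("temperature"), scr$kept)) {
    pe <- partial_effect(fit, v)
    utils::write.csv(pe, file.path(out_dir,
                                   sprintf("partial_%s.csv", v)),
                     row.names = FALSE, quote = FALSE)
  }
  stage_log(verbose,
            "gam: %d row(s); kept %d/%d covariate(s); deviance explained %.3f",
            fit$n, length(scr$kept), length(gam_candidate_vars),
            fit$deviance_explained)
  write_manifest(out_dir, "gam", file.path(out_dir, "fate_rows.csv"),
                 "gam_summary.json", cfg, cfg$rng_seed)
  invisible(TRUE)
}

stage_screen <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, c("occurrences.csv", "extant.csv", "range.geojson"),
              "screen", "simulate")
  occ <- read_occurrences(file.path(out_dir, "occurrences.csv"))
  extant <- read_occurrences(file.path(out_dir, "extant.csv"))
  poly <- read_range_polygon(file.path(out_dir, "range.geojson"))
  recent <- occ[occ$year >= cfg$study_end - cfg$period_years &
                  occ$year < cfg$study_end, , drop = FALSE]
  scr <- screen_extinctions(recent, extant, poly, cfg$buffer_km)
  ext_rec <- scr$records[scr$records$is_extinction, , drop = FALSE]
  rar <- rarefy(ext_rec, cfg$rarefy_km)
  utils::write.csv(scr$records, file.path(out_dir, "screened.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(rar, file.path(out_dir, "extinction_rarefied.csv"),
                   row.names = FALSE, quote = FALSE)
  kf <- NULL
  if (nrow(ext_rec) >= 2) {
    radii <- seq(10, 200, by = 10)
    kf <- ripley_k(ext_rec, radii,
                   seed = stage_seed(cfg$rng_seed, 7))
    utils::write.csv(as.data.frame(kf),
                     file.path(out_dir, "ripley_k.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report <- list(window = c(cfg$study_end - cfg$period_years,
                            cfg$study_end),
                 n_window = nrow(recent),
                 counts = as.list(scr$counts),
                 n_extinction = nrow(ext_rec),
                 n_rarefied = nrow(rar))
  jsonlite::write_json(report,
                       file.path(out_dir, "screening_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(verbose,
            "screen: %d window record(s) -> %d outside range, %d outside buffers, %d extinction, %d after rarefaction",
            nrow(recent), scr$counts["outside_range"],
            scr$counts["outside_buffers"], scr$counts["extinction"],
            nrow(rar))
  write_manifest(out_dir, "screen",
                 file.path(out_dir, c("occurrences.csv", "extant.csv",
                                      "range.geojson")),
                 c("screened.csv", "extinction_rarefied.csv",
                   "screening_report.json"), cfg, cfg$rng_seed)
  invisible(TRUE)
}

risk_variables <- c("popc", "popd", "cropland", "grazing", "uopp",
                    "bio3", "bio7", "bio8", "bio14")

stage_risk <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, "extinction_rarefied.csv", "risk", "screen")
  pres <- read_occurrences(file.path(out_dir, "extinction_rarefied.csv"))
  if (nrow(pres) < 5)
    stop("too few extinction records (", nrow(pres),
         ") to fit the risk model")
  stack <- read_stack_dir(out_dir)
  periods <- period_from_config(cfg)
  env <- period_env(stack, periods$n_periods, periods$n_periods,
                    risk_variables)
  bg <- sample_background(env, cfg$background_n,
                          seed = stage_seed(cfg$rng_seed, 8))
  pres_X <- extract_env_at_records(pres, env)
  pre <- prescreen_variables(pres_X, bg$X,
                             n_runs = cfg$prescreen_runs,
                             reg_multiplier = cfg$reg_multiplier,
                             seed = cfg$rng_seed)
  contrib0 <- stats::setNames(pre$summary$max_contribution,
                              pre$summary$var)[pre$retained]
  cf <- correlation_filter(bg$X[, pre$retained, drop = FALSE], contrib0,
                           threshold = cfg$cor_threshold)
  vars <- cf$retained
  rep_fit <- replicate_fit(pres_X[, vars, drop = FALSE],
                           list(cells = bg$cells,
                                X = bg$X[, vars, drop = FALSE]),
                           structure(list(grid = env$grid,
                                          layers = env$layers[vars],
                                          nodata = env$nodata),
                                     class = "env_layers"),
                           replicates = cfg$replicates,
                           test_fraction = cfg$test_fraction,
                           reg_multiplier = cfg$reg_multiplier,
                           seed = cfg$rng_seed)
  write_ascii_grid(rep_fit$surface$values, env$grid,
                   file.path(out_dir, "risk_surface.asc"))
  valid <- which(!is.na(rep_fit$surface$values))
  cc <- cell_center(valid, env$grid)
  utils::write.csv(data.frame(cell_id = valid, lon = cc$lon, lat = cc$lat,
                              risk = rep_fit$surface$values[valid]),
                   file.path(out_dir, "risk_surface.csv"),
                   row.names = FALSE, quote = FALSE)
  model_json <- list(
    variables_candidate = risk_variables,
    variables_prescreened = pre$retained,
    variables_retained = vars,
    correlation_filter = cf$log,
    contribution = as.list(rep_fit$contribution),
    importance = as.list(rep_fit$importance),
    auc = rep_fit$auc, mean_auc = rep_fit$mean_auc,
    sd_auc = rep_fit$sd_auc,
    replicates = cfg$replicates,
    n_presence = nrow(pres_X), n_background = nrow(bg$X),
    lambda_first_replicate = as.list(rep_fit$model$lambda),
    entropy_first_replicate = rep_fit$model$entropy)
  jsonlite::write_json(model_json, file.path(out_dir, "sdm_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  stage_log(verbose,
            "risk: %d presence(s) vs %d background; %d -> %d variable(s); mean test AUC %.3f",
            nrow(pres_X), nrow(bg$X), length(risk_variables),
            length(vars), rep_fit$mean_auc)
  write_manifest(out_dir, "risk",
                 file.path(out_dir, "extinction_rarefied.csv"),
                 c("risk_surface.asc", "risk_surface.csv",
                   "sdm_model.json"), cfg, cfg$rng_seed)
  invisible(TRUE)
}

stage_classify <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, c("risk_surface.asc", "extinction_rarefied.csv",
                         "extant.csv"), "classify", "risk")
  ras <- read_ascii_grid(file.path(out_dir, "risk_surface.asc"))
  surface <- structure(list(values = ras$values, grid = ras$grid),
                       class = "risk_surface")
  pres <- read_occurrences(file.path(out_dir, "extinction_rarefied.csv"))
  extant <- read_occurrences(file.path(out_dir, "extant.csv"))
  pres_scores <- surface_at(surface, pres$lon, pres$lat)
  bg_scores <- surface$values[!is.na(surface$values)]
  thr <- max_sss_threshold(pres_scores[!is.na(pres_scores)], bg_scores)
  cls <- classify_sites(surface, extant, thr$threshold, k = cfg$jenks_k)
  utils::write.csv(cls$sites, file.path(out_dir, "classification.csv"),
                   row.names = FALSE, quote = FALSE)
  report <- list(threshold = thr$threshold,
                 sensitivity = thr$sensitivity,
                 specificity = thr$specificity,
                 breaks = cls$breaks,
                 counts = as.list(cls$counts),
                 percentages = as.list(cls$percentages),
                 notable_pct = cls$notable_pct,
                 n_sites = nrow(cls$sites),
                 n_excluded = cls$n_excluded,
                 risk_range = range(bg_scores))
  jsonlite::write_json(report,
                       file.path(out_dir, "classification_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(verbose,
            "classify: threshold %.3f; %s; notable %.2f%%",
            thr$threshold,
            paste(names(cls$counts), as.integer(cls$counts),
                  collapse = ", ", sep = "="),
            cls$notable_pct)
  write_manifest(out_dir, "classify",
                 file.path(out_dir, c("risk_surface.asc", "extant.csv")),
                 c("classification.csv", "classification_report.json"),
                 cfg, cfg$rng_seed)
  invisible(TRUE)
}

stage_pca <- function(cfg, out_dir, verbose = FALSE) {
  need_inputs(out_dir, "screened.csv", "pca", "screen")
  scr <- utils::read.csv(file.path(out_dir, "screened.csv"))
  ext_rec <- scr[scr$is_extinction, , drop = FALSE]
  if (nrow(ext_rec) < 3) stop("too few extinction records for PCA")
  stack <- read_stack_dir(out_dir)
  periods <- period_from_config(cfg)
  # variables retained by the risk model where available, else defaults
  vars <- risk_variables
  mj <- file.path(out_dir, "sdm_model.json")
  if (file.exists(mj))
    vars <- jsonlite::read_json(mj,
                                simplifyVector = TRUE)$variables_retained
  env <- period_env(stack, periods$n_periods, periods$n_periods, vars)
  X <- extract_env_at_records(ext_rec, env)
  pca <- env_pca(X)
  load_df <- data.frame(var = rownames(pca$loadings),
                        pca$loadings[, 1:min(2, ncol(pca$loadings))],
                        row.names = NULL)
  utils::write.csv(load_df, file.path(out_dir, "pca_loadings.csv"),
                   row.names = FALSE, quote = FALSE)
  report <- list(
    variables = colnames(X), n_records = nrow(X),
    n_dropped_nodata = attr(X, "n_dropped"),
    explained_ratios = pca$ratios,
    first_two_pct = variance_summary(pca, min(2, length(pca$ratios))),
    contribution_pc1 = as.list(pca$contributions[, 1]),
    contribution_pc2 = if (ncol(pca$contributions) > 1)
      as.list(pca$contributions[, 2]))
  jsonlite::write_json(report, file.path(out_dir, "pca_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(verbose, "pca: %d record(s), %d variable(s); PC1+PC2 %.2f%%",
            nrow(X), ncol(X), report$first_two_pct)
  write_manifest(out_dir, "pca", file.path(out_dir, "screened.csv"),
                 c("pca_loadings.csv", "pca_report.json"), cfg,
                 cfg$rng_seed)
  invisible(TRUE)
}

pipeline_stages <- c("simulate", "encode", "gam", "screen", "risk",
                     "classify", "pca")

#' Run the chronicle pipeline
#'
#' Executes the requested stages in order, reading and writing plain-text
#' artifacts under `out_dir`. `stages = "all"` chains every stage and
#' additionally writes `report.json` summarising all of them.
#'
#' @param cfg a [chronex_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stage names, or `"all"`.
#' @param verbose log one line per stage with in/out counts.
#' @return invisibly, the path to `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir, stages = "all", verbose = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in stages) {
    fn <- get(paste0("stage_", st), mode = "function")
    fn(cfg, out_dir, verbose = verbose)
  }
  if (setequal(stages, pipeline_stages)) {
    rep_files <- c(gam = "gam_summary.json",
                   screen = "screening_report.json",
                   risk = "sdm_model.json",
                   classify = "classification_report.json",
                   pca = "pca_report.json")
    report <- lapply(rep_files, function(f)
      jsonlite::read_json(file.path(out_dir, f), simplifyVector = TRUE))
    occ <- read_occurrences(file.path(out_dir, "occurrences.csv"))
    report$simulate <- list(n_occurrences = nrow(occ))
    fates <- utils::read.csv(file.path(out_dir, "fate_rows.csv"))
    report$encode <- list(n_rows = nrow(fates),
                          n_absence = sum(fates$fate == 1))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()]; installed as
#' `inst/cli.R` (run `Rscript $(Rscript -e
#' 'cat(system.file("cli.R", package = "chronex"))') <subcommand> ...`).
#' Subcommands: `simulate`, `encode`, `gam`, `screen`, `risk`,
#' `classify`, `pca`, `all`. Flags: `--config PATH`, `--seed INT`,
#' `--out DIR`, `--verbose`.
#'
#' @param args character vector (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status: 0 on success, 1 on a stage error, 2 on
#'   usage errors.
#' @export
chronex_cli <- function(args) {
  usage <- paste(
    "usage: chronex <subcommand> [--config PATH] [--seed INT]",
    "[--out DIR] [--verbose]\n  subcommands:",
    paste(c(pipeline_stages, "all"), collapse = " | "))
  if (length(args) < 1) { message(usage); return(2L) }
  sub <- args[1]
  if (!sub %in% c(pipeline_stages, "all")) {
    message("unknown subcommand '", sub, "'\n", usage)
    return(2L)
  }
  flag <- function(name) {
    i <- which(args == name)
    if (length(i) != 1 || i == length(args)) NULL else args[i + 1]
  }
  out_dir <- flag("--out"); if (is.null(out_dir)) out_dir <- "."
  cfg <- tryCatch({
    cfg <- if (!is.null(flag("--config"))) read_config(flag("--config"))
      else chronex_config()
    seed <- flag("--seed")
    if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)
    validate_config(cfg)
    cfg
  }, error = function(e) { message("config error: ", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  verbose <- "--verbose" %in% args
  status <- tryCatch({
    run_pipeline(cfg, out_dir, stages = if (sub == "all") "all" else sub,
                 verbose = verbose)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
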