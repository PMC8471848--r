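.pipeline_keys <- c("seed", "stages", "sim", "motility", "proximity",
                    "secretion", "inputs")
.pipeline_stages <- c("simulate", "motility", "proximity", "secretion")

#' Validate a pipeline run configuration
#'
#' @param config named list (or YAML file path). Recognised keys: `seed`
#'   (integer), `stages` (subset of simulate/motility/proximity/secretion),
#'   `sim` (overrides for [sim_config()]), `motility` (`interval`),
#'   `proximity` (`k`, `alternative`), `secretion` (`linkage`, `k`),
#'   `inputs` (paths to `tracks`/`population`/`plate` CSVs when the
#'   simulate stage is not run). Unknown keys are rejected by name.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config$seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  if (is.null(config$stages)) config$stages <- .pipeline_stages
  bad <- setdiff(config$stages, .pipeline_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (k in c("sim", "motility", "proximity", "secretion", "inputs")) {
    if (is.null(config[[k]])) config[[k]] <- list()
  }
  if (!("simulate" %in% config$stages)) {
    need <- c(if (any(c("motility", "proximity") %in% config$stages))
      c("tracks") else character(0),
      if ("proximity" %in% config$stages) "population" else character(0),
      if ("secretion" %in% config$stages) "plate" else character(0))
    miss <- setdiff(unique(need), names(config$inputs))
    if (length(miss) > 0) {
      stop("without the simulate stage, config$inputs must provide: ",
           paste(miss, collapse = ", "))
    }
  }
  config
}

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the quantification pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> motility -> proximity -> secretion), writing every stage's
#' tables under `out_dir` together with a provenance manifest
#' (`manifest.json`: seed, stages, config hash, package version, file
#' list). All randomness flows from the single configured seed, so a rerun
#' with the same config reproduces every output byte-identically.
#'
#' @param config list or YAML path, see [run_config()].
#' @param out_dir output directory (created if absent); stages write only
#'   here.
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_df(df, p)
    files <<- c(files, name)
  }

  tracks <- NULL; population <- NULL; plate <- NULL
  if ("simulate" %in% config$stages) {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    population <- simulate_population(cfg)
    traj <- simulate_trajectories(population, cfg)
    tracks <- traj$tracks
    plate_sim <- simulate_secretion_plate(cfg)
    plate <- plate_sim$table
    emit(as.data.frame(population), "population.csv")
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    files <- c(files, "tracks.csv")
    emit(traj$truth, "trajectory_truth.csv")
    write_secretion_csv(plate, file.path(out_dir, "plate.csv"))
    files <- c(files, "plate.csv")
    jsonlite::write_json(
      list(plate_groups = plate_sim$truth$group,
           plate_log_mean = plate_sim$truth$log_mean,
           lod = plate_sim$truth$lod),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "ground_truth.json")
    results$simulate <- list(config = cfg, truth = traj$truth,
                             plate_truth = plate_sim$truth)
  } else {
    if (!is.null(config$inputs$tracks)) tracks <- read_tracks(config$inputs$tracks)
    if (!is.null(config$inputs$population)) {
      population <- utils::read.csv(config$inputs$population,
                                    stringsAsFactors = FALSE)
    }
    if (!is.null(config$inputs$plate)) {
      plate <- read_secretion_csv(config$inputs$plate)
    }
  }

  if ("motility" %in% config$stages) {
    interval <- if (is.null(config$motility$interval)) 1 else config$motility$interval
    if (is.null(tracks)) stop("stage motility failed: no track input")
    sp <- track_speeds(tracks, interval = interval)
    em <- ensemble_msd(tracks)
    emit(sp, "speeds.csv")
    emit(as.data.frame(em), "ensemble_msd.csv")
    results$motility <- list(speeds = sp, ensemble_msd = em)
  }

  if ("proximity" %in% config$stages) {
    if (is.null(tracks) || is.null(population)) {
      stop("stage proximity failed: needs tracks and population inputs")
    }
    k <- if (is.null(config$proximity$k)) 15 else config$proximity$k
    alt <- if (is.null(config$proximity$alternative)) "greater"
    else config$proximity$alternative
    pa <- proximity_analysis(tracks, population, k = k, alternative = alt)
    emit(pa$records, "proximity_records.csv")
    jsonlite::write_json(pa$test, file.path(out_dir, "proximity_test.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "proximity_test.json")
    results$proximity <- pa
  }

  if ("secretion" %in% config$stages) {
    if (is.null(plate)) stop("stage secretion failed: no plate input")
    linkage <- if (is.null(config$secretion$linkage)) "average"
    else config$secretion$linkage
    imp <- impute_oor(plate)
    zt <- transform_secretion(imp, "zscore")
    cl <- cluster_profiles(zt, linkage = linkage,
                           k = config$secretion$k)
    cm <- correlation_matrix(transform_secretion(imp, "ln"))
    pca <- pca_scores(zt)
    write_secretion_csv(imp, file.path(out_dir, "plate_imputed.csv"))
    files <- c(files, "plate_imputed.csv")
    emit(data.frame(sample = rownames(zt$conc), zt$conc,
                    check.names = FALSE), "plate_z.csv")
    emit(data.frame(sample = rownames(cm), as.data.frame(cm),
                    check.names = FALSE), "sample_correlation.csv")
    emit(data.frame(sample = rownames(pca$scores), pca$scores,
                    check.names = FALSE), "pca_scores.csv")
    jsonlite::write_json(
      list(row_order = cl$row_order, col_order = cl$col_order,
           explained = pca$explained),
      file.path(out_dir, "secretion_summary.json"),
      auto_unbox = TRUE, digits = NA)
    files <- c(files, "secretion_summary.json")
    results$secretion <- list(imputed = imp, z = zt, clusters = cl,
                              correlation = cm, pca = pca)
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "tmequant",
    version = as.character(utils::packageVersion("tmequant")),
    seed = config$seed,
    stages = config$stages,
    config_md5 = unname(tools::md5sum(tmp)),
    files = sort(files))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
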