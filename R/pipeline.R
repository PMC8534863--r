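# Pipeline orchestration: simulate -> extract -> stats, with a YAML config,
# structured logging and a JSON run manifest.

#' Default run configuration
#'
#' Every convention that is configurable (gray-level count, distance
#' correction, direction aggregation, histogram mode, statistics options)
#' surfaces here as a key, so alternative toolbox conventions can be
#' toggled and compared.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    out_dir = NULL,
    input_dir = NULL,           # existing cohort dir; NULL => simulate
    seed = 1L,
    log_level = "info",
    simulate = list(n_male = 25L, n_female = 54L,
                    grid_shape = c(64L, 64L, 10L),
                    voxel_size = c(1.5, 1.5, 1.5),
                    slices_per_roi = 10L,
                    correlation_length = 2),
    extract = list(ng = 200L, dist_correction = TRUE,
                   aggregate = "pooled", raw_moments = FALSE),
    stats = list(by_sex = TRUE, fdr = FALSE, corr_method = "pearson",
                 alpha = 0.05))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Keys absent from the file keep their [default_config()] values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_pdff("config file not found: %s", path, class = "pdff_io_error")
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

validate_config <- function(config) {
  if (is.null(config$out_dir))
    stop_pdff("config validation: `out_dir` is required",
              class = "pdff_config_error")
  invisible(config)
}

#' Simulate a cohort to disk
#'
#' @param config configuration list (see [default_config()]).
#' @return the simulation directory, invisibly.
#' @export
run_simulate <- function(config) {
  validate_config(config)
  sim_dir <- file.path(config$out_dir, "cohort")
  sp <- config$simulate
  spec <- cohort_spec(n_male = sp$n_male, n_female = sp$n_female,
                      grid_shape = sp$grid_shape,
                      voxel_size = sp$voxel_size,
                      slices_per_roi = sp$slices_per_roi,
                      correlation_length = sp$correlation_length,
                      seed = config$seed)
  log_msg("info", sprintf("simulating %d subjects (seed %d)",
                          spec$n_male + spec$n_female, spec$seed))
  write_cohort(generate_cohort(spec), sim_dir)
  invisible(sim_dir)
}

read_manifest <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    stop_pdff("no manifest.json in %s", dir, class = "pdff_io_error")
  jsonlite::read_json(mp, simplifyVector = FALSE)
}

#' Extract features for every subject of a cohort directory
#'
#' Reads the cohort manifest, loads each subject's PDFF volume and the six
#' shared masks, and writes one bilateral feature row per subject x muscle
#' to `features.csv`. Per-subject or per-muscle failures (e.g. missing
#' masks) are logged and skipped; zero successfully processed subjects is
#' fatal. Deterministic given its inputs.
#'
#' @param config configuration list; `input_dir` must point at a cohort
#'   directory (as written by [run_simulate()]/[write_cohort()]).
#' @return path of the features CSV, invisibly.
#' @export
run_extract <- function(config) {
  validate_config(config)
  in_dir <- config$input_dir %||% file.path(config$out_dir, "cohort")
  man <- read_manifest(in_dir)
  vs <- as.double(unlist(man$voxel_size))

  masks <- list()
  for (mus in MUSCLES) for (side in SIDES) {
    nm <- paste0(mus, "_", side)
    f <- man$masks[[nm]]
    if (is.null(f) || !file.exists(file.path(in_dir, f))) {
      log_msg("warn", sprintf("mask %s missing; muscle will be skipped", nm))
      next
    }
    masks[[nm]] <- load_mask(file.path(in_dir, f), mus, side)
  }

  ex <- config$extract
  rows <- list()
  n_ok <- 0L
  for (s in man$subjects) {
    res <- tryCatch({
      vol <- load_volume(file.path(in_dir, s$volume))
      have <- MUSCLES[vapply(MUSCLES, function(m)
        all(paste0(m, "_", SIDES) %in% names(masks)), logical(1))]
      if (length(have) < length(MUSCLES))
        log_msg("warn", sprintf("subject %s: skipping muscles %s",
                                s$subject_id,
                                paste(setdiff(MUSCLES, have), collapse = ",")))
      fx <- extract_features(vol, masks[unlist(lapply(have, function(m)
        paste0(m, "_", SIDES)))], ng = ex$ng,
        dist_correction = ex$dist_correction, aggregate = ex$aggregate,
        raw_moments = ex$raw_moments)
      cbind(data.frame(subject_id = s$subject_id), fx)
    }, error = function(e) {
      log_msg("warn", sprintf("subject %s failed: %s", s$subject_id,
                              conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <- res
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L)
    stop_pdff("extract: zero successfully processed subjects",
              class = "pdff_fatal_error")
  feat <- do.call(rbind, rows)
  out <- file.path(config$out_dir, "features.csv")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(feat, out, row.names = FALSE)
  log_msg("info", sprintf("extracted %d feature rows from %d subjects",
                          nrow(feat), n_ok))
  invisible(out)
}

#' Pivot a long feature table to the wide cohort table
#'
#' @param features long data.frame (`subject_id`, `muscle`, features).
#' @param covariates covariate data.frame (`subject_id`, `sex`, `age`,
#'   `bmi`).
#' @return wide data.frame with `<feature>_<muscle>` columns.
#' @export
build_cohort_table <- function(features, covariates) {
  wide <- covariates
  for (mus in unique(features$muscle)) {
    sub <- features[features$muscle == mus, ]
    cols <- intersect(feature_names(), names(sub))
    sub <- sub[, c("subject_id", cols)]
    names(sub)[-1] <- paste0(cols, "_", mus)
    wide <- merge(wide, sub, by = "subject_id", all.x = FALSE)
  }
  wide[order(wide$subject_id), , drop = FALSE]
}

#' Run the statistics stage
#'
#' @param config configuration list; reads `features.csv` and the cohort
#'   covariates, writes the three tidy statistics CSVs.
#' @return paths of the written CSVs, invisibly.
#' @export
run_stats <- function(config) {
  validate_config(config)
  in_dir <- config$input_dir %||% file.path(config$out_dir, "cohort")
  feat <- utils::read.csv(file.path(config$out_dir, "features.csv"),
                          stringsAsFactors = FALSE)
  cov <- read_covariates(file.path(in_dir, "covariates.csv"))
  tab <- build_cohort_table(feat, cov)
  st <- config$stats
  res <- run_cohort_statistics(tab, by_sex = st$by_sex, fdr = st$fdr,
                               corr_method = st$corr_method,
                               alpha = st$alpha)
  invisible(write_cohort_statistics(res, config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulate (unless `input_dir` points at an existing cohort), extract,
#' stats; then write `run_manifest.json` recording the config echo, seeds,
#' package version and MD5 hashes of all outputs. Any fatal stage error
#' aborts with the stage name.
#'
#' @param config configuration list (see [default_config()]).
#' @return the manifest path, invisibly.
#' @export
run_all <- function(config) {
  validate_config(config)
  old <- options(pdfftexture.log_level = config$log_level %||% "info")
  on.exit(options(old))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_pdff("pipeline stage '%s' failed: %s", name,
                conditionMessage(e), class = "pdff_stage_error"))
  }
  if (is.null(config$input_dir))
    stage("simulate", run_simulate(config))
  stage("extract", run_extract(config))
  stage("stats", run_stats(config))

  outputs <- list.files(config$out_dir, recursive = TRUE,
                        full.names = TRUE)
  outputs <- outputs[!grepl("run_manifest\\.json$", outputs)]
  manifest <- list(
    package = "pdfftexture",
    version = as.character(utils::packageVersion("pdfftexture")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       substring(outputs, nchar(config$out_dir) + 2L)))
  mp <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}
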