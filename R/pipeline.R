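#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a simulation request
#' (a design plus group sizes) or paths to existing scan TSVs, the window
#' and multilayer parameters, the statistics levels, the master seed and the
#' output directory. Can also be loaded from a YAML file with the same field
#' names via `pipeline_config(yaml = path)`.
#'
#' @param out_dir Output directory.
#' @param seed Master seed recorded in every output sidecar.
#' @param simulate `NULL`, or a list of [generate_cohort()] arguments
#'   (e.g. `n_per_group`, `design_by_condition`, `effect`).
#' @param scans Optional data frame `subject_id, scan, path` of scan TSVs
#'   (used when `simulate` is `NULL`).
#' @param atlas Atlas data frame or TSV path; `NULL` for a synthetic map.
#' @param window A [window_config()] or list of its arguments.
#' @param multilayer A [multilayer_params()] or list of its arguments.
#' @param stats_levels Levels at which to run the statistics.
#' @param yaml Optional YAML path; fields in the file override defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("netswitch_run_"),
                            seed = 1L, simulate = list(), scans = NULL,
                            atlas = NULL, window = window_config(),
                            multilayer = multilayer_params(n_repetitions = 5L),
                            stats_levels = c("global", "subnetwork"),
                            yaml = NULL) {
  if (!is.null(yaml)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    y <- yaml::read_yaml(yaml)
    for (f in names(y)) assign(f, y[[f]])
  }
  if (is.list(simulate) && is.list(simulate$n_per_group)) {
    simulate$n_per_group <- unlist(simulate$n_per_group)
  }
  if (is.list(window) && !inherits(window, "window_config")) {
    window <- do.call(window_config, window)
  }
  if (is.list(multilayer) && !inherits(multilayer, "multilayer_params")) {
    multilayer <- do.call(multilayer_params, multilayer)
  }
  if (is.character(atlas)) atlas <- read_atlas_tsv(atlas)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, scans = scans, atlas = atlas,
                 window = window, multilayer = multilayer,
                 stats_levels = stats_levels),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks shapes, atlas coverage, cohort completeness and motion quality
#' without raising: every problem becomes one row of the returned issue
#' table. An empty table means the configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional cohort to validate against (otherwise simulated
#'   lazily when the config requests simulation).
#' @return Data frame with columns `stage`, `subject`, `issue`.
#' @export
validate_inputs <- function(config, cohort = NULL) {
  issues <- list()
  note <- function(stage, subject, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      stage = stage, subject = subject, issue = issue,
      stringsAsFactors = FALSE)
  }
  cfg_len <- config$window$trim_initial + config$window$width
  if (is.null(cohort) && length(config$simulate)) {
    cohort <- tryCatch(
      do.call(generate_cohort,
              c(config$simulate,
                list(seed = config$seed, window = config$window))),
      error = function(e) {
        note("simulate", "-", conditionMessage(e))
        NULL
      })
  }
  if (!is.null(cohort)) {
    for (id in cohort$subjects$subject_id) {
      d <- cohort$designs[[id]]
      for (sc in c("pre", "post")) {
        if (is.null(d[[sc]])) {
          note("paired-analysis", id, sprintf("missing %s scan", sc))
        } else if (d[[sc]]$n_volumes < cfg_len) {
          note("connect", id, sprintf(
            "scan has %d volumes; window config needs >= %d",
            d[[sc]]$n_volumes, cfg_len))
        }
      }
      qc <- motion_qc(scan_motion(d$pre$n_volumes, d$seed_pre))
      if (!qc$pass) {
        note("motion-qc", id, paste("excess motion on",
                                    paste(qc$issues$axis, collapse = ", ")))
      }
      miss <- is.na(cohort$subjects[cohort$subjects$subject_id == id,
                                    c("age", "education", "mean_fd")])
      if (any(miss)) note("stats", id, "incomplete covariates")
    }
    atlas <- if (!is.null(config$atlas)) config$atlas else cohort$atlas
    n_nodes <- cohort$designs[[1L]]$pre$n_nodes
    mapped <- paste0("n", seq_len(n_nodes)) %in% atlas$node_id
    if (!all(mapped)) {
      note("switching", "-", sprintf("atlas misses %d node(s)", sum(!mapped)))
    }
  }
  if (!is.null(config$scans)) {
    for (r in seq_len(nrow(config$scans))) {
      if (!file.exists(config$scans$path[r])) {
        note("inputs", config$scans$subject_id[r],
             sprintf("scan file not found: %s", config$scans$path[r]))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(stage = character(), subject = character(),
                  issue = character(), stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> connect -> partition -> switching ->
#' stats, writing per-scan partitions and profiles, the statistics tables,
#' and a JSON manifest (inputs, parameters, seeds, package version) that
#' makes the run reproducible bit-for-bit under the same configuration.
#' Any stage error aborts with the stage and subject named and leaves a
#' `FAILED` marker in the output directory.
#'
#' @param config A [pipeline_config()].
#' @return A run report: list with `manifest` (also written to
#'   `manifest.json`), `profiles`, `stats`, and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  subject <- "-"
  on.exit({
    if (!identical(stage, "done")) {
      writeLines(sprintf("FAILED at stage %s (subject %s)", stage, subject),
                 file.path(config$out_dir, "FAILED"))
    }
  }, add = TRUE)

  manifest <- list(package = "netswitch",
                   version = as.character(utils::packageVersion("netswitch")),
                   seed = config$seed,
                   window = unclass(config$window),
                   multilayer = unclass(config$multilayer)[
                     c("gamma", "omega", "n_repetitions")],
                   stages = character())
  mark <- function(s) manifest$stages <<- c(manifest$stages, s)

  stage <- "simulate"
  if (length(config$simulate) || is.null(config$scans)) {
    cohort <- do.call(generate_cohort,
                      c(config$simulate,
                        list(seed = config$seed, window = config$window)))
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort"))
    scan_ids <- expand.grid(subject_id = cohort$subjects$subject_id,
                            scan = c("pre", "post"),
                            stringsAsFactors = FALSE)
    get_scan <- function(id, sc) subject_scan(cohort, id, sc)
    atlas <- if (!is.null(config$atlas)) config$atlas else cohort$atlas
    mark("simulate")
  } else {
    cohort <- NULL
    scan_ids <- config$scans[, c("subject_id", "scan")]
    get_scan <- function(id, sc) {
      read_scan_tsv(config$scans$path[config$scans$subject_id == id &
                                        config$scans$scan == sc][1L])
    }
    atlas <- config$atlas
  }

  profiles <- list()
  layer_counts <- integer(0)
  for (r in seq_len(nrow(scan_ids))) {
    subject <- scan_ids$subject_id[r]
    sc <- scan_ids$scan[r]
    key <- paste(subject, sc, sep = "_")

    stage <- "connect"
    stack <- zero_negative(window_connectivity(get_scan(subject, sc),
                                               config$window))
    layer_counts[key] <- dim(stack$layers)[3L]

    stage <- "partition"
    params <- config$multilayer
    params$seed <- derive_seed(config$seed, r)
    parts <- repeat_partitions(stack, params)
    write_partition_tsv(parts[[1L]],
                        file.path(config$out_dir,
                                  sprintf("partition_%s.tsv", key)))

    stage <- "switching"
    prof <- average_profiles(lapply(parts, switching_rates, atlas = atlas,
                                    node_ids = stack$node_ids))
    write_profile_csv(prof, file.path(config$out_dir,
                                      sprintf("profile_%s.csv", key)))
    profiles[[key]] <- prof
  }
  subject <- "-"
  mark("connect"); mark("partition"); mark("switching")

  stage <- "stats"
  stats_out <- NULL
  if (!is.null(cohort)) {
    # replace planted outcomes with the measured profiles
    measured <- cohort
    measured$outcomes <- do.call(rbind, lapply(names(profiles), function(k) {
      parts <- strsplit(k, "_(?=[^_]+$)", perl = TRUE)[[1L]]
      outcomes_for(parts[1L], parts[2L], profiles[[k]]$node_rates, atlas)
    }))
    stats_out <- do.call(rbind, lapply(config$stats_levels, function(lv) {
      run_study_stats(measured, level = lv)
    }))
    df <- stats_out
    for (cc in c("statistic", "p", "p_fdr")) df[[cc]] <- fmt_num(df[[cc]])
    utils::write.csv(df, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  mark("stats")

  manifest$layer_counts <- as.list(layer_counts)
  manifest$n_scans <- nrow(scan_ids)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- "done"
  list(manifest = manifest, profiles = profiles, stats = stats_out,
       out_dir = config$out_dir)
}
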