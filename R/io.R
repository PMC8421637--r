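# Plain-text readers and writers for the pipeline's artifacts.  All numeric
# output uses 12 significant digits so reruns are byte-reproducible.

fmt_num <- function(x) signif(x, 12)

#' Write / read a scan as TSV
#'
#' Scans are stored nodes x volumes: one row per node, a `node_id` column
#' followed by volume columns `v0..v{T-1}`.
#'
#' @param scan A [timeseries_scan()].
#' @param path Output path.
#' @return `write_scan_tsv` returns `path` invisibly; `read_scan_tsv`
#'   returns a [timeseries_scan()].
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "timeseries_scan"))
  df <- data.frame(node_id = scan$node_ids, fmt_num(scan$values),
                   check.names = FALSE)
  names(df) <- c("node_id", paste0("v", seq_len(ncol(scan$values)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @param sampling_interval Sampling interval in seconds for the scan read.
#' @param motion Optional motion trace (or path to a motion TSV).
#' @export
read_scan_tsv <- function(path, sampling_interval = 2, motion = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (is.character(motion)) motion <- read_motion_tsv(motion)
  timeseries_scan(as.matrix(df[, -1L, drop = FALSE]),
                  node_ids = as.character(df[[1L]]),
                  sampling_interval = sampling_interval, motion = motion)
}

#' Write / read a 6-column motion trace as TSV
#' @param motion Time x 6 matrix.
#' @param path File path.
#' @return The path (write) or the motion matrix (read).
#' @export
write_motion_tsv <- function(motion, path) {
  motion <- as.matrix(motion)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(fmt_num(motion), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Write / read a node-to-subnetwork atlas as TSV
#' @param atlas Data frame with `node_id`, `subnetwork`.
#' @param path File path.
#' @export
write_atlas_tsv <- function(atlas, path) {
  utils::write.table(atlas[, c("node_id", "subnetwork")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("node_id", "subnetwork") %in% names(df))) {
    stop("atlas TSV needs columns node_id and subnetwork", call. = FALSE)
  }
  df
}

#' Write a partition stack as TSV plus JSON sidecar
#'
#' The label matrix (rows = nodes, columns = windows) goes to `path`; run
#' metadata `{Q, gamma, omega, seed, n_modules}` goes to `paste0(path,
#' ".json")`.
#'
#' @param partition A `partition_stack`.
#' @param path Output TSV path.
#' @export
write_partition_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "partition_stack"))
  utils::write.table(partition$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(Q = partition$quality, gamma = partition$gamma,
         omega = partition$omega, seed = partition$seed,
         n_modules = partition$n_modules),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  labels <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(labels) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = labels, n_modules = meta$n_modules,
                 quality = meta$Q, gamma = meta$gamma, omega = meta$omega,
                 seed = meta$seed), class = "partition_stack")
}

#' Write a switching profile as CSV plus JSON summary
#'
#' Per-node rows (`node_id`, `subnetwork`, `n_switch`, `rate`) go to `path`;
#' the global and per-subnetwork means to `paste0(path, ".json")`.
#'
#' @param profile A `switching_profile`.
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "switching_profile"))
  df <- as.data.frame(profile)
  df$n_switch <- fmt_num(df$n_switch)
  df$rate <- fmt_num(df$rate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(global = profile$global_rate,
         subnetworks = as.list(profile$subnet_rates),
         n_max = profile$n_max, n_repetitions = profile$n_repetitions),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cohort tables as CSV
#'
#' Writes `subjects.csv` and `outcomes.csv` into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "netswitch_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sj <- cohort$subjects
  num <- vapply(sj, is.numeric, TRUE)
  sj[num] <- lapply(sj[num], fmt_num)
  utils::write.csv(sj, file.path(dir, "subjects.csv"), row.names = FALSE,
                   quote = FALSE)
  oc <- cohort$outcomes
  oc$value <- fmt_num(oc$value)
  utils::write.csv(oc, file.path(dir, "outcomes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
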