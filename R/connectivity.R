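#' Sliding-window configuration
#'
#' Parameters of the sliding-window segmentation used to build the dynamic
#' network: a rectangular window of `width` volumes advanced by `step`
#' volumes, after discarding the first `trim_initial` volumes of the scan
#' (signal-equilibration volumes that are conventionally dropped).
#'
#' @param width Window width in volumes. Default 50 (100 s at a 2 s sampling
#'   interval), chosen so the window exceeds the period of the slowest
#'   retained frequency component.
#' @param step Step between consecutive window starts, in volumes. Default 1.
#' @param trim_initial Number of initial volumes removed before windowing.
#'   Default 10.
#' @return An object of class `window_config`.
#' @examples
#' cfg <- window_config()
#' nrow(sliding_windows(250, cfg))  # 191 windows
#' @export
window_config <- function(width = 50L, step = 1L, trim_initial = 10L) {
  width <- stop_if_not_count(width, "width", min = 2L)
  step <- stop_if_not_count(step, "step", min = 1L)
  trim_initial <- stop_if_not_count(trim_initial, "trim_initial", min = 0L)
  structure(list(width = width, step = step, trim_initial = trim_initial),
            class = "window_config")
}

#' Regional time-series scan
#'
#' Container for one scan: a node x time matrix of regional signals, the
#' sampling interval in seconds, and an optional time x 6 rigid-body motion
#' trace (3 translations in mm, 3 rotations in degrees).
#'
#' @param values Numeric node x time matrix (rows = nodes).
#' @param node_ids Character vector of node identifiers (default `n1..nK`).
#' @param sampling_interval Sampling interval (repetition time) in seconds.
#' @param motion Optional time x 6 numeric matrix of motion parameters.
#' @return An object of class `timeseries_scan`.
#' @export
timeseries_scan <- function(values, node_ids = NULL, sampling_interval = 2,
                            motion = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || !is.numeric(values)) {
    stop("scan values must be numeric with no missing entries", call. = FALSE)
  }
  if (nrow(values) < 2L) stop("a scan needs at least 2 nodes", call. = FALSE)
  if (ncol(values) < 2L) stop("a scan needs at least 2 time points", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(values)))
  if (length(node_ids) != nrow(values)) {
    stop("node_ids length must match the number of rows", call. = FALSE)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L || nrow(motion) != ncol(values)) {
      stop("motion must be a time x 6 matrix matching the scan length",
           call. = FALSE)
    }
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
  }
  dimnames(values) <- list(as.character(node_ids), NULL)
  structure(list(values = values, node_ids = as.character(node_ids),
                 sampling_interval = sampling_interval, motion = motion),
            class = "timeseries_scan")
}

#' @export
print.timeseries_scan <- function(x, ...) {
  cat(sprintf("<timeseries_scan> %d nodes x %d volumes, TR = %g s%s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval,
              if (is.null(x$motion)) "" else ", with motion trace"))
  invisible(x)
}

#' Enumerate sliding windows
#'
#' Computes the half-open volume intervals `[start, start + width)` covering a
#' scan of `series_length` volumes after trimming, 0-based and relative to the
#' trimmed series. The number of windows is
#' `floor((L - width) / step) + 1` with `L = series_length - trim_initial`.
#'
#' @param series_length Scan length in volumes (before trimming).
#' @param config A [window_config()].
#' @return A data frame with integer columns `start` and `end` (half-open).
#' @examples
#' nrow(sliding_windows(250, window_config(50, 1, 10)))  # 191
#' @export
sliding_windows <- function(series_length, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  L <- as.integer(series_length) - config$trim_initial
  if (config$width > L) {
    stop(sprintf(
      "window width %d exceeds the post-trim series length %d",
      config$width, L), call. = FALSE)
  }
  starts <- seq.int(0L, L - config$width, by = config$step)
  data.frame(start = starts, end = starts + config$width)
}

#' Windowed Fisher-z connectivity layers
#'
#' Builds the dynamic network: for every sliding window, the Pearson
#' correlation matrix of the windowed node signals is Fisher z-transformed
#' (`atanh`, with correlations clipped to `|r| <= 1 - 1e-7` so weights stay
#' finite), the diagonal is set to zero, and the layers are stacked in time
#' order.
#'
#' @param scan A [timeseries_scan()].
#' @param config A [window_config()].
#' @return An object of class `layer_stack`: list with `layers` (a node x
#'   node x n_windows array), `window_starts` (0-based, post-trim),
#'   `node_ids`, and the `nonnegative` flag (`FALSE` until
#'   [zero_negative()] is applied).
#' @export
window_connectivity <- function(scan, config = window_config()) {
  stopifnot(inherits(scan, "timeseries_scan"))
  wins <- sliding_windows(ncol(scan$values), config)
  vals <- scan$values[, (config$trim_initial + 1L):ncol(scan$values), drop = FALSE]
  n <- nrow(vals)
  L <- nrow(wins)
  layers <- array(0, dim = c(n, n, L))
  clip <- 1 - 1e-7
  for (w in seq_len(L)) {
    seg <- t(vals[, (wins$start[w] + 1L):wins$end[w], drop = FALSE])
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1L]
      stop(sprintf(
        "node %s has zero variance in window %d [%d, %d); cannot correlate",
        scan$node_ids[bad], w, wins$start[w], wins$end[w]), call. = FALSE)
    }
    r <- stats::cor(seg)
    z <- atanh(pmin(pmax(r, -clip), clip))
    diag(z) <- 0
    layers[, , w] <- z
  }
  structure(list(layers = layers, window_starts = wins$start,
                 node_ids = scan$node_ids, nonnegative = FALSE),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$layers)
  cat(sprintf("<layer_stack> %d x %d x %d layers%s\n", d[1L], d[2L], d[3L],
              if (isTRUE(x$nonnegative)) " (nonnegative)" else ""))
  invisible(x)
}

#' Zero out negative connectivity weights
#'
#' Sets all negative entries of every layer to zero (entrywise
#' `max(., 0)`), the conventional preparation for modularity-based community
#' detection, which requires nonnegative weights. Idempotent.
#'
#' @param stack A `layer_stack`.
#' @return The stack with nonnegative layers and `nonnegative = TRUE`.
#' @export
zero_negative <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  stack$layers[stack$layers < 0] <- 0
  stack$nonnegative <- TRUE
  stack
}

#' Residualize node signals against nuisance regressors
#'
#' Replaces every node series by its least-squares residual against an
#' intercept plus the supplied regressor columns (e.g. white-matter, CSF and
#' global-mean signals). With `regressors = NULL` the series are mean-centred
#' only. The operation is a projection: applying it twice equals once.
#'
#' @param scan A [timeseries_scan()].
#' @param regressors Optional time x k numeric matrix.
#' @return The scan with residualized values.
#' @export
regress_nuisance <- function(scan, regressors = NULL) {
  stopifnot(inherits(scan, "timeseries_scan"))
  T_ <- ncol(scan$values)
  X <- cbind(intercept = rep(1, T_))
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != T_) {
      stop("regressors must have one row per volume", call. = FALSE)
    }
    X <- cbind(X, regressors)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop(sprintf("nuisance design is rank deficient (column %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  res <- t(qr.resid(qx, t(scan$values)))
  scan$values <- res
  rownames(scan$values) <- scan$node_ids
  scan
}

#' Band-pass filter node signals
#'
#' Zero-phase frequency-domain filter: each node series is Fourier
#' transformed, bins whose frequency falls outside `[low, high]` Hz are set to
#' zero, and the series is inverse transformed. The DC component is removed
#' whenever `low > 0`.
#'
#' @param scan A [timeseries_scan()].
#' @param low,high Band edges in Hz; `0 <= low < high <=` Nyquist
#'   (`1 / (2 * sampling_interval)`). Defaults 0.01 and 0.10.
#' @return The filtered scan (same length).
#' @export
bandpass <- function(scan, low = 0.01, high = 0.10) {
  stopifnot(inherits(scan, "timeseries_scan"))
  nyq <- 1 / (2 * scan$sampling_interval)
  if (!(low >= 0 && low < high && high <= nyq + 1e-12)) {
    stop(sprintf("invalid band [%g, %g] Hz; need 0 <= low < high <= %g",
                 low, high, nyq), call. = FALSE)
  }
  T_ <- ncol(scan$values)
  freq <- pmin(0:(T_ - 1L), T_ - (0:(T_ - 1L))) / (T_ * scan$sampling_interval)
  keep <- freq >= low & freq <= high
  sp <- stats::mvfft(t(scan$values))
  sp[!keep, ] <- 0
  scan$values <- t(Re(stats::mvfft(sp, inverse = TRUE)) / T_)
  rownames(scan$values) <- scan$node_ids
  scan
}

#' Mean framewise displacement
#'
#' Per-frame framewise displacement (FD) in the Power formulation: the sum of
#' absolute frame-to-frame translation changes plus the absolute rotation
#' changes converted to arc length on a 50 mm sphere. Rotations are assumed
#' stored in degrees unless `rotation_unit = "radians"`.
#'
#' @param motion Time x 6 matrix (3 translations mm, 3 rotations).
#' @param rotation_unit Either `"degrees"` (default) or `"radians"`.
#' @return Mean FD in mm over frames `2..T`.
#' @export
mean_fd <- function(motion, rotation_unit = c("degrees", "radians")) {
  rotation_unit <- match.arg(rotation_unit)
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L) {
    stop("motion must be a time x 6 matrix with >= 2 time points", call. = FALSE)
  }
  d <- abs(diff(motion))
  rot <- d[, 4:6, drop = FALSE]
  if (rotation_unit == "degrees") rot <- rot * pi / 180
  fd <- rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(rot)
  mean(fd)
}

#' Motion quality control
#'
#' Applies the exclusion rule for severe head motion: a scan fails if any
#' translation exceeds 2 mm or any rotation exceeds 2 degrees on any axis
#' (strict inequalities; the trace columns are cumulative realignment
#' parameters).
#'
#' @param motion Time x 6 matrix (3 translations mm, 3 rotations degrees).
#' @param max_translation,max_rotation Thresholds (2 mm, 2 degrees).
#' @return A list with `pass` (logical) and `issues` (data frame of
#'   offending axes with their maximum absolute excursion).
#' @export
motion_qc <- function(motion, max_translation = 2, max_rotation = 2) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns", call. = FALSE)
  axes <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  mx <- apply(abs(motion), 2L, max)
  lim <- c(rep(max_translation, 3L), rep(max_rotation, 3L))
  bad <- which(mx > lim)
  issues <- data.frame(axis = axes[bad],
                       type = ifelse(bad <= 3L, "translation", "rotation"),
                       max_abs = unname(mx[bad]),
                       limit = lim[bad])
  list(pass = length(bad) == 0L, issues = issues)
}
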