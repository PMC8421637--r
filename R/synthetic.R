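#' Planted modular design for synthetic scans
#'
#' Describes a synthetic scan with known, time-varying modular structure: a
#' base node-to-module labeling, optional switch events that reassign single
#' nodes at given volumes, a target within-module correlation, and a
#' frequency band for the latent signals. The module labeling over time (the
#' partition schedule) is the ground truth against which pipeline switching
#' rates can be validated.
#'
#' The signal model is a common band-limited Gaussian source per module with
#' node loading `sqrt(within_module_corr)` plus independent band-limited
#' noise of standard deviation `noise_sd`, so the expected correlation of two
#' nodes sharing a module is available in closed form:
#' `c / (c + noise_sd^2)` with `c = within_module_corr`. With the default
#' `noise_sd = sqrt(1 - c)` this equals `c` exactly.
#'
#' @param n_nodes Number of nodes (default 160).
#' @param n_volumes Number of volumes before trimming (default 250).
#' @param sampling_interval Sampling interval in seconds (default 2).
#' @param base_partition Integer module label per node at volume 1.
#' @param within_module_corr Target within-module correlation in `[0, 1)`.
#' @param noise_sd Independent-noise standard deviation (> 0).
#' @param band Pass band in Hz for the latent signals (default 0.01-0.10).
#' @param switch_events Optional data frame with columns `node`, `volume`,
#'   `module`: node `node` is reassigned to `module` from volume `volume`
#'   (1-based) onward.
#' @param partition_schedule Optional explicit schedule: a list of
#'   `list(start, end, labels)` with 1-based half-open volume intervals
#'   `[start, end)` tiling `1..n_volumes + 1` and an integer label per node.
#'   When supplied it overrides `base_partition`/`switch_events`.
#' @return An object of class `planted_design`.
#' @examples
#' d <- planted_design(n_nodes = 20, n_volumes = 120,
#'                     base_partition = rep(1:2, each = 10))
#' scan <- generate_scan(d, seed = 1)
#' @export
planted_design <- function(n_nodes = 160L, n_volumes = 250L,
                           sampling_interval = 2,
                           base_partition = rep_len(1:4, n_nodes),
                           within_module_corr = 0.6,
                           noise_sd = sqrt(1 - within_module_corr),
                           band = c(0.01, 0.10),
                           switch_events = NULL,
                           partition_schedule = NULL) {
  n_nodes <- stop_if_not_count(n_nodes, "n_nodes", min = 2L)
  n_volumes <- stop_if_not_count(n_volumes, "n_volumes", min = 2L)
  if (!(within_module_corr >= 0 && within_module_corr < 1)) {
    stop("within_module_corr must lie in [0, 1)", call. = FALSE)
  }
  if (!(noise_sd > 0)) stop("noise_sd must be > 0", call. = FALSE)
  if (length(band) != 2L || !(band[1L] >= 0 && band[1L] < band[2L])) {
    stop("band must be (low, high) with 0 <= low < high", call. = FALSE)
  }
  if (is.null(partition_schedule)) {
    base_partition <- as.integer(rep_len(base_partition, n_nodes))
    partition_schedule <- build_schedule(base_partition, n_volumes, switch_events)
  }
  validate_schedule(partition_schedule, n_nodes, n_volumes)
  structure(list(n_nodes = n_nodes, n_volumes = n_volumes,
                 sampling_interval = sampling_interval,
                 within_module_corr = within_module_corr,
                 noise_sd = noise_sd, band = band,
                 switch_events = switch_events,
                 partition_schedule = partition_schedule),
            class = "planted_design")
}

# Turn base labeling + events into an interval schedule.
build_schedule <- function(base, n_volumes, events) {
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("node", "volume", "module") %in% names(events))) {
      stop("switch_events needs columns node, volume, module", call. = FALSE)
    }
    if (any(events$volume < 2 | events$volume > n_volumes)) {
      stop("switch-event volumes must lie in 2..n_volumes", call. = FALSE)
    }
    if (any(events$node < 1 | events$node > length(base))) {
      stop("switch-event nodes out of range", call. = FALSE)
    }
  }
  cuts <- sort(unique(c(1L, if (!is.null(events)) as.integer(events$volume),
                        n_volumes + 1L)))
  labels <- base
  sched <- vector("list", length(cuts) - 1L)
  ev_order <- if (!is.null(events)) events[order(events$volume), , drop = FALSE]
  for (k in seq_len(length(cuts) - 1L)) {
    if (!is.null(ev_order)) {
      hit <- ev_order$volume == cuts[k]
      labels[ev_order$node[hit]] <- as.integer(ev_order$module[hit])
    }
    sched[[k]] <- list(start = cuts[k], end = cuts[k + 1L], labels = labels)
  }
  sched
}

validate_schedule <- function(sched, n_nodes, n_volumes) {
  if (!length(sched)) stop("empty partition schedule", call. = FALSE)
  starts <- vapply(sched, `[[`, 1L, "start")
  ends <- vapply(sched, `[[`, 1L, "end")
  if (starts[1L] != 1L || ends[length(sched)] != n_volumes + 1L ||
      any(ends[-length(sched)] != starts[-1L]) || any(ends <= starts)) {
    stop("partition_schedule intervals must tile 1..n_volumes without overlap",
         call. = FALSE)
  }
  ok <- vapply(sched, function(iv) {
    length(iv$labels) == n_nodes && !anyNA(iv$labels)
  }, TRUE)
  if (!all(ok)) {
    stop("every node needs a module label in every interval", call. = FALSE)
  }
  invisible(sched)
}

#' @export
print.planted_design <- function(x, ...) {
  mods <- sort(unique(unlist(lapply(x$partition_schedule, `[[`, "labels"))))
  cat(sprintf(paste0("<planted_design> %d nodes x %d volumes, %d modules, ",
                     "%d schedule interval(s), target corr %.2f\n"),
              x$n_nodes, x$n_volumes, length(mods),
              length(x$partition_schedule), x$within_module_corr))
  invisible(x)
}

# Node x volume module label matrix implied by the schedule.
schedule_matrix <- function(design) {
  out <- matrix(0L, design$n_nodes, design$n_volumes)
  for (iv in design$partition_schedule) {
    out[, iv$start:(iv$end - 1L)] <- iv$labels
  }
  out
}

# White noise band-limited by frequency-domain masking, columns standardized
# to unit variance. `m` series of length `T_`.
band_limited_noise <- function(T_, dt, band, m) {
  freq <- pmin(0:(T_ - 1L), T_ - (0:(T_ - 1L))) / (T_ * dt)
  keep <- freq >= band[1L] & freq <= band[2L]
  if (!any(keep)) stop("band keeps no frequency bin at this length", call. = FALSE)
  x <- matrix(stats::rnorm(T_ * m), T_, m)
  sp <- stats::mvfft(x)
  sp[!keep, ] <- 0
  y <- Re(stats::mvfft(sp, inverse = TRUE)) / T_
  sds <- apply(y, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(y, 2L, sds, "/")
}

#' Generate a synthetic scan from a planted design
#'
#' Simulates a node x time matrix in which, within each scheduled interval,
#' nodes sharing a module load on a common band-limited latent source
#' (loading `sqrt(within_module_corr)`) plus independent band-limited noise,
#' and attaches a small-amplitude random-walk motion trace. Deterministic
#' given `seed`.
#'
#' @param design A [planted_design()].
#' @param seed Integer seed.
#' @return A [timeseries_scan()].
#' @export
generate_scan <- function(design, seed = 1L) {
  stopifnot(inherits(design, "planted_design"))
  vals <- with_seed(derive_seed(seed, 101L), {
    T_ <- design$n_volumes
    n <- design$n_nodes
    lab <- schedule_matrix(design)
    mods <- sort(unique(as.vector(lab)))
    src <- band_limited_noise(T_, design$sampling_interval, design$band,
                              length(mods))
    noise <- band_limited_noise(T_, design$sampling_interval, design$band, n)
    loading <- sqrt(design$within_module_corr)
    out <- matrix(0, n, T_)
    for (i in seq_len(n)) {
      out[i, ] <- loading * src[cbind(seq_len(T_), match(lab[i, ], mods))] +
        design$noise_sd * noise[, i]
    }
    out
  })
  timeseries_scan(vals, sampling_interval = design$sampling_interval,
                  motion = scan_motion(design$n_volumes, seed))
}

# Motion trace stream is derived separately from the signal stream so a
# trace (and hence mean FD) can be reproduced without simulating signals.
scan_motion <- function(T_, seed) {
  with_seed(derive_seed(seed, 202L), {
    apply(matrix(stats::rnorm(T_ * 6L, sd = 0.02), T_, 6L), 2L, cumsum)
  })
}

#' Ground-truth switching rate of a planted design
#'
#' For each node, the fraction of consecutive-window transitions at which the
#' node's majority module over the window (per the design's schedule)
#' changes. This is the planted analogue of the pipeline's switching rate
#' and serves as recovery ground truth. Ties in the window majority go to
#' the smaller module id.
#'
#' @param design A [planted_design()].
#' @param window A [window_config()] valid for the design's length.
#' @return Named numeric vector of per-node rates in `[0, 1]`.
#' @export
planted_switch_rate <- function(design, window = window_config()) {
  stopifnot(inherits(design, "planted_design"))
  wins <- sliding_windows(design$n_volumes, window)
  lab <- schedule_matrix(design)[, (window$trim_initial + 1L):design$n_volumes,
                                 drop = FALSE]
  W <- nrow(wins)
  rates <- numeric(design$n_nodes)
  for (i in seq_len(design$n_nodes)) {
    maj <- window_majority(lab[i, ], wins$start, window$width)
    rates[i] <- if (W > 1L) mean(maj[-1L] != maj[-W]) else 0
  }
  names(rates) <- paste0("n", seq_len(design$n_nodes))
  rates
}

# Majority label per window for one node; starts are 0-based.
window_majority <- function(lab, starts, width) {
  u <- sort(unique(lab))
  if (length(u) == 1L) return(rep(u, length(starts)))
  counts <- vapply(u, function(m) {
    cs <- c(0L, cumsum(lab == m))
    cs[starts + width + 1L] - cs[starts + 1L]
  }, numeric(length(starts)))
  counts <- matrix(counts, nrow = length(starts))
  u[max.col(counts, ties.method = "first")]
}
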