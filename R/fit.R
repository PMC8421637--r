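#' Fit switching rates to a scan
#'
#' The package's core estimator. From a regional time-series scan it (1)
#' builds the sliding-window Fisher-z connectivity layers, (2) zeroes
#' negative weights, (3) runs `n_repetitions` seeded generalized-Louvain
#' optimizations of the multilayer modularity, and (4) averages the node,
#' subnetwork and global switching rates over the repetitions.
#'
#' @param scan A [timeseries_scan()].
#' @param window A [window_config()].
#' @param atlas Optional node-to-subnetwork map (see [switching_rates()]).
#' @param gamma,omega Resolution and inter-layer coupling (defaults 1, 1).
#' @param n_repetitions Number of stochastic repetitions to average
#'   (default 100, the conventional protocol; reduce for quick looks).
#' @param seed Master seed.
#' @param keep_partitions If `TRUE`, retain the individual
#'   `partition_stack` objects under `$partitions`.
#' @return An object of class `switch_fit` with elements `profile` (the
#'   averaged [switching_rates()] profile), `quality` (mean modularity Q
#'   across repetitions), `n_layers`, `window`, `params`, `node_ids`,
#'   `call`.
#' @seealso [coef.switch_fit()], [summary.switch_fit()], [plot.switch_fit()]
#' @examples
#' d <- planted_design(n_nodes = 12, n_volumes = 80,
#'                     base_partition = rep(1:2, each = 6),
#'                     within_module_corr = 0.8)
#' scan <- generate_scan(d, seed = 1)
#' fit <- fit_switching(scan, window_config(width = 30, step = 10,
#'                                          trim_initial = 0),
#'                      n_repetitions = 3, seed = 1)
#' coef(fit)
#' @export
fit_switching <- function(scan, window = window_config(), atlas = NULL,
                          gamma = 1, omega = 1, n_repetitions = 100L,
                          seed = 1L, keep_partitions = FALSE) {
  stopifnot(inherits(scan, "timeseries_scan"))
  params <- multilayer_params(gamma = gamma, omega = omega,
                              n_repetitions = n_repetitions, seed = seed)
  stack <- zero_negative(window_connectivity(scan, window))
  parts <- repeat_partitions(stack, params)
  profiles <- lapply(parts, switching_rates, atlas = atlas,
                     node_ids = scan$node_ids)
  out <- structure(list(
    profile = average_profiles(profiles),
    quality = mean(vapply(parts, `[[`, 0, "quality")),
    n_layers = dim(stack$layers)[3L],
    window = window, params = params, node_ids = scan$node_ids,
    call = match.call()), class = "switch_fit")
  if (keep_partitions) out$partitions <- parts
  out
}

#' @export
print.switch_fit <- function(x, ...) {
  cat("Dynamic-network switching-rate fit\n")
  cat(sprintf("  %d nodes, %d layers (width %d, step %d, trim %d), N = %d\n",
              length(x$node_ids), x$n_layers, x$window$width, x$window$step,
              x$window$trim_initial, x$profile$n_max))
  cat(sprintf("  gamma = %g, omega = %g, %d repetition(s), mean Q = %.4f\n",
              x$params$gamma, x$params$omega, x$params$n_repetitions,
              x$quality))
  cat(sprintf("  global switching rate: %.4f\n", x$profile$global_rate))
  invisible(x)
}

#' Extract node-level switching rates
#' @param object A `switch_fit`.
#' @param ... Unused.
#' @return Named numeric vector of per-node rates in `[0, 1]`.
#' @export
coef.switch_fit <- function(object, ...) object$profile$node_rates

#' Summarize a switching-rate fit
#' @param object A `switch_fit`.
#' @param ... Unused.
#' @return A `summary.switch_fit` with the subnetwork table and globals.
#' @export
summary.switch_fit <- function(object, ...) {
  pr <- object$profile
  tab <- data.frame(subnetwork = names(pr$subnet_rates),
                    n_nodes = as.integer(table(pr$subnetwork)[names(pr$subnet_rates)]),
                    rate = as.numeric(pr$subnet_rates),
                    row.names = NULL)
  structure(list(subnet = tab, global_rate = pr$global_rate,
                 n_max = pr$n_max, quality = object$quality,
                 n_repetitions = object$params$n_repetitions),
            class = "summary.switch_fit")
}

#' @export
print.summary.switch_fit <- function(x, ...) {
  cat("Switching rates by subnetwork (mean over member nodes):\n")
  print(x$subnet, row.names = FALSE)
  cat(sprintf("Global rate %.4f over N = %d possible switches; mean Q = %.4f (%d repetitions)\n",
              x$global_rate, x$n_max, x$quality, x$n_repetitions))
  invisible(x)
}

#' Plot node switching rates by subnetwork
#' @param x A `switch_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the subnetwork means.
#' @export
plot.switch_fit <- function(x, ...) {
  pr <- x$profile
  m <- sort(pr$subnet_rates, decreasing = TRUE)
  graphics::barplot(m, las = 2, ylab = "switching rate",
                    main = "Subnetwork switching rates", ...)
  graphics::abline(h = pr$global_rate, lty = 2)
  invisible(m)
}
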