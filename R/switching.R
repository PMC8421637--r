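#' Synthetic node-to-subnetwork atlas
#'
#' Builds a node-to-subnetwork map over the six canonical large-scale
#' subnetworks (default-mode, occipital, cingulo-opercular, fronto-parietal,
#' sensorimotor, cerebellar). The assignment is synthetic: real atlases carry
#' anatomically defined labels, which this generator only emulates. For 160
#' nodes the subnetwork sizes follow the usual 160-region set (34, 22, 32,
#' 21, 33, 18); other sizes are filled proportionally.
#'
#' @param n_nodes Number of nodes (default 160).
#' @param node_ids Optional node identifiers (default `n1..nK`).
#' @return A data frame with columns `node_id` and `subnetwork`.
#' @export
synthetic_atlas <- function(n_nodes = 160L, node_ids = NULL) {
  n_nodes <- stop_if_not_count(n_nodes, "n_nodes", 1L)
  nets <- c("default-mode", "occipital", "cingulo-opercular",
            "fronto-parietal", "sensorimotor", "cerebellar")
  sizes160 <- c(34L, 22L, 32L, 21L, 33L, 18L)
  if (n_nodes >= length(nets)) {
    sizes <- floor(sizes160 * n_nodes / 160)
    sizes <- pmax(sizes, 1L)
    while (sum(sizes) < n_nodes) sizes[which.max(sizes160 / sizes)] <-
        sizes[which.max(sizes160 / sizes)] + 1L
    while (sum(sizes) > n_nodes) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    labels <- rep(nets, sizes)
  } else {
    labels <- nets[seq_len(n_nodes)]
  }
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n_nodes))
  data.frame(node_id = as.character(node_ids), subnetwork = labels,
             stringsAsFactors = FALSE)
}

# Unweighted subnetwork means as a plain named numeric vector.
subnet_means <- function(rates, subnet) {
  m <- tapply(rates, subnet, mean)
  stats::setNames(as.numeric(m), names(m))
}

#' Per-node switch counts
#'
#' Counts, for every node, the number of consecutive-layer transitions at
#' which its module label changes: `n_i = #\{t : g(i, t+1) != g(i, t)\}`.
#'
#' @param partition A `partition_stack` or node x layer label matrix with at
#'   least 2 layers.
#' @return Integer vector of counts in `[0, n_layers - 1]`.
#' @export
node_switch_counts <- function(partition) {
  labels <- if (inherits(partition, "partition_stack")) partition$labels
            else as.matrix(partition)
  L <- ncol(labels)
  if (L < 2L) {
    stop("need at least 2 layers to count switches (N would be 0)",
         call. = FALSE)
  }
  as.integer(rowSums(labels[, -1L, drop = FALSE] !=
                     labels[, -L, drop = FALSE]))
}

#' Node, subnetwork and global switching rates
#'
#' Converts a module-assignment matrix into switching rates
#' `f_i = n_i / N` with `N = n_layers - 1` the maximum possible number of
#' switches, then aggregates by unweighted means over each subnetwork's
#' member nodes and over all nodes (global). All rates lie in `[0, 1]`.
#'
#' @param partition A `partition_stack` or node x layer label matrix.
#' @param atlas Data frame mapping `node_id` to `subnetwork`, covering every
#'   node; `NULL` assigns all nodes to a single `"whole-brain"` subnetwork.
#' @param node_ids Node identifiers (default `n1..nK`).
#' @return An object of class `switching_profile`: `node_rates`,
#'   `subnet_rates`, `global_rate`, `n_switch`, `n_max`, `n_repetitions`,
#'   `subnetwork` (per-node labels).
#' @export
switching_rates <- function(partition, atlas = NULL, node_ids = NULL) {
  labels <- if (inherits(partition, "partition_stack")) partition$labels
            else as.matrix(partition)
  n <- nrow(labels)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (is.null(atlas)) {
    atlas <- data.frame(node_id = node_ids, subnetwork = "whole-brain",
                        stringsAsFactors = FALSE)
  }
  idx <- match(node_ids, atlas$node_id)
  if (anyNA(idx)) {
    stop(sprintf("atlas does not map node(s): %s",
                 paste(node_ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  n_switch <- node_switch_counts(labels)
  n_max <- ncol(labels) - 1L
  rates <- n_switch / n_max
  names(rates) <- node_ids
  names(n_switch) <- node_ids
  subnet <- atlas$subnetwork[idx]
  structure(list(node_rates = rates,
                 subnet_rates = subnet_means(rates, subnet),
                 global_rate = mean(rates),
                 n_switch = n_switch, n_max = n_max,
                 n_repetitions = 1L, subnetwork = subnet),
            class = "switching_profile")
}

#' Average switching profiles over repetitions
#'
#' Element-wise arithmetic mean of per-node rates and counts across
#' repeated partition optimizations; subnetwork and global aggregates are
#' recomputed from the averaged node rates (identical, by linearity, to
#' averaging the aggregates).
#'
#' @param profiles List of `switching_profile` objects sharing node set and
#'   atlas.
#' @return A single averaged `switching_profile` with `n_repetitions` set to
#'   the total.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1L]]
  for (p in profiles) {
    if (!identical(names(p$node_rates), names(ref$node_rates)) ||
        !identical(p$subnetwork, ref$subnetwork)) {
      stop("profiles have heterogeneous node sets or atlases", call. = FALSE)
    }
  }
  rates <- rowMeans(vapply(profiles, `[[`, ref$node_rates, "node_rates"))
  nsw <- rowMeans(vapply(profiles, `[[`, as.numeric(ref$n_switch), "n_switch"))
  structure(list(node_rates = rates,
                 subnet_rates = subnet_means(rates, ref$subnetwork),
                 global_rate = mean(rates),
                 n_switch = nsw, n_max = ref$n_max,
                 n_repetitions = sum(vapply(profiles, `[[`, 1L,
                                            "n_repetitions")),
                 subnetwork = ref$subnetwork),
            class = "switching_profile")
}

#' @export
print.switching_profile <- function(x, ...) {
  cat(sprintf(
    "<switching_profile> %d nodes, N = %d, global rate %.4f (averaged over %d repetition%s)\n",
    length(x$node_rates), x$n_max, x$global_rate, x$n_repetitions,
    if (x$n_repetitions == 1L) "" else "s"))
  invisible(x)
}

#' @export
as.data.frame.switching_profile <- function(x, ...) {
  data.frame(node_id = names(x$node_rates), subnetwork = x$subnetwork,
             n_switch = as.numeric(x$n_switch),
             rate = as.numeric(x$node_rates),
             row.names = NULL, stringsAsFactors = FALSE)
}
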