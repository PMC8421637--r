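#' Multilayer community-detection parameters
#'
#' Settings of the multilayer (temporal) modularity optimization: intra-layer
#' resolution `gamma`, ordinal inter-layer coupling `omega` (a weight linking
#' each node to itself in adjacent layers; larger values favour temporally
#' persistent module labels), the number of stochastic repetitions to average
#' over, and optimizer controls.
#'
#' @param gamma Intra-layer resolution, > 0. Default 1.
#' @param omega Inter-layer coupling weight, >= 0. Default 1.
#' @param coupling Coupling topology; only `"ordinal-adjacent"` (each layer
#'   coupled to its temporal neighbours) is supported.
#' @param n_repetitions Number of repeated optimizations (default 100).
#' @param seed Integer master seed for the repetitions.
#' @param max_sweeps Maximum local-move sweeps per aggregation level.
#' @param tolerance Minimum modularity improvement for accepting a move.
#' @return An object of class `multilayer_params`.
#' @export
multilayer_params <- function(gamma = 1, omega = 1,
                              coupling = "ordinal-adjacent",
                              n_repetitions = 100L, seed = 1L,
                              max_sweeps = 100L, tolerance = 1e-10) {
  if (!(gamma > 0)) stop("gamma must be > 0", call. = FALSE)
  if (!(omega >= 0)) stop("omega must be >= 0", call. = FALSE)
  coupling <- match.arg(coupling, "ordinal-adjacent")
  n_repetitions <- stop_if_not_count(n_repetitions, "n_repetitions", 1L)
  structure(list(gamma = gamma, omega = omega, coupling = coupling,
                 n_repetitions = n_repetitions, seed = as.integer(seed),
                 max_sweeps = as.integer(max_sweeps), tolerance = tolerance),
            class = "multilayer_params")
}

# Coerce a layer_stack or plain array/list into an n x n x L array and check
# nonnegativity where required.
as_layer_array <- function(stack, require_nonneg = TRUE) {
  layers <- if (inherits(stack, "layer_stack")) stack$layers
            else if (is.array(stack) && length(dim(stack)) == 3L) stack
            else if (is.list(stack)) simplify2array(stack)
            else stop("expected a layer_stack, 3-d array or list of matrices",
                      call. = FALSE)
  if (dim(layers)[1L] != dim(layers)[2L]) {
    stop("layers must be square", call. = FALSE)
  }
  if (require_nonneg && any(layers < 0)) {
    stop("layers contain negative weights; apply zero_negative() first",
         call. = FALSE)
  }
  layers
}

# Per-layer modularity blocks B_s = A_s - gamma * k k' / (2 m_s) (diagonal
# null terms included; a zero-weight layer contributes no null term), plus
# the normalization 2*mu = sum_s 2 m_s + 2 * omega * n * (L - 1).
modularity_blocks <- function(layers, gamma, omega) {
  n <- dim(layers)[1L]
  L <- dim(layers)[3L]
  B <- array(0, dim = dim(layers))
  twom_total <- 0
  for (s in seq_len(L)) {
    A <- layers[, , s]
    k <- rowSums(A)
    twom <- sum(k)
    twom_total <- twom_total + twom
    B[, , s] <- if (twom > 0) A - gamma * tcrossprod(k) / twom else A
  }
  list(B = B, twomu = twom_total + 2 * omega * n * (L - 1L))
}

#' Multilayer modularity of a partition
#'
#' Evaluates the multilayer (temporal) modularity quality
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijsr} \left[ \left(A_{ijs} -
#'   \gamma \frac{k_{is} k_{js}}{2 m_s}\right)\delta_{sr} +
#'   \delta_{ij} C_{jsr} \right] \delta(g_{is}, g_{jr})}
#' with ordinal-adjacent coupling \eqn{C_{jsr} = \omega} for \eqn{|s-r| = 1}
#' and \eqn{2\mu = \sum_s 2 m_s + 2\omega n (L-1)}. For a single layer this
#' reduces exactly to weighted Newman-Girvan modularity at resolution
#' `gamma`.
#'
#' @param stack A `layer_stack` (nonnegative), 3-d array, or list of
#'   matrices.
#' @param partition A `partition_stack` or an integer node x layer label
#'   matrix.
#' @param gamma,omega Resolution and coupling (defaults 1).
#' @return The scalar quality Q.
#' @examples
#' tri2 <- matrix(0, 6, 6)
#' tri2[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
#' tri2 <- tri2 + t(tri2)
#' multilayer_modularity(array(tri2, c(6, 6, 1)),
#'                       matrix(rep(1:2, each = 3), ncol = 1))  # 0.5
#' @export
multilayer_modularity <- function(stack, partition, gamma = 1, omega = 1) {
  layers <- as_layer_array(stack)
  labels <- if (inherits(partition, "partition_stack")) partition$labels
            else as.matrix(partition)
  n <- dim(layers)[1L]
  L <- dim(layers)[3L]
  if (nrow(labels) != n || ncol(labels) != L) {
    stop("partition shape must be n_nodes x n_layers", call. = FALSE)
  }
  bl <- modularity_blocks(layers, gamma, omega)
  q_sum <- 0
  for (s in seq_len(L)) {
    same <- outer(labels[, s], labels[, s], "==")
    q_sum <- q_sum + sum(bl$B[, , s] * same)
  }
  if (L > 1L && omega != 0) {
    for (s in seq_len(L - 1L)) {
      q_sum <- q_sum + 2 * omega * sum(labels[, s] == labels[, s + 1L])
    }
  }
  if (bl$twomu > 0) q_sum / bl$twomu else 0
}

#' Optimize a multilayer partition (generalized Louvain)
#'
#' Greedy Louvain-style optimization on the supra graph of node-layer
#' vertices: intra-layer weights are the modularity-null-adjusted entries
#' `A_ijs - gamma k_is k_js / (2 m_s)` and each node is coupled to itself in
#' adjacent layers with weight `omega`. Repeated seed-shuffled local-move
#' sweeps alternate with community aggregation until no move improves the
#' quality by more than `tolerance`. Module labels are shared across layers
#' (a label denotes the same community in every layer) and are canonicalized
#' by order of first appearance (nodes within layer 1, then layer 2, ...).
#' Deterministic given `seed`.
#'
#' @param stack A nonnegative `layer_stack`, 3-d array, or list of matrices.
#' @param params A [multilayer_params()].
#' @param seed Integer seed for this run (defaults to `params$seed`).
#' @return An object of class `partition_stack`: `labels` (node x layer
#'   integer matrix, labels `1..n_modules`), `n_modules`, `quality`
#'   (equal to [multilayer_modularity()] of the labels), `gamma`, `omega`,
#'   `seed`; attribute `q_history` traces the optimizer's per-sweep
#'   unnormalized quality (nondecreasing).
#' @export
optimize_partition <- function(stack, params = multilayer_params(),
                               seed = params$seed) {
  layers <- as_layer_array(stack)
  if (dim(layers)[3L] < 1L) stop("empty layer stack", call. = FALSE)
  bl <- modularity_blocks(layers, params$gamma, params$omega)
  tol_raw <- params$tolerance * max(bl$twomu, 1)
  n <- dim(layers)[1L]
  L <- dim(layers)[3L]
  if (params$omega == 0 && L > 1L) {
    # decoupled layers: optimize each independently under a per-layer seed,
    # so a layer's labels cannot depend on the other layers' matrices
    labels <- matrix(0L, n, L)
    qhist <- numeric(0)
    offset <- 0L
    for (s in seq_len(L)) {
      rs <- genlouvain_cpp(as.numeric(bl$B[, , s]), n, 1L, 0, tol_raw,
                           params$max_sweeps,
                           as.double(derive_seed(seed, 7000L + s)))
      labels[, s] <- rs$labels + 1L + offset
      offset <- offset + max(rs$labels) + 1L
      qhist <- c(qhist, rs$q_history)
    }
    res <- list(labels = labels - 1L, q_history = qhist)
  } else {
    res <- genlouvain_cpp(as.numeric(bl$B), n, L, params$omega, tol_raw,
                          params$max_sweeps, as.double(seed %% 2147483647))
  }
  labels <- canonicalize_labels(res$labels + 1L)
  q <- multilayer_modularity(layers, labels, params$gamma, params$omega)
  structure(list(labels = labels, n_modules = max(labels), quality = q,
                 gamma = params$gamma, omega = params$omega,
                 seed = as.integer(seed)),
            class = "partition_stack",
            q_history = res$q_history)
}

# Relabel modules 1..K by first appearance, scanning nodes within layer 1,
# then layer 2, ... so outputs are comparable across runs.
canonicalize_labels <- function(labels) {
  v <- as.vector(labels)  # column-major: node-major within each layer
  map <- match(v, unique(v))
  matrix(as.integer(map), nrow(labels), ncol(labels))
}

#' @export
print.partition_stack <- function(x, ...) {
  cat(sprintf(
    "<partition_stack> %d nodes x %d layers, %d modules, Q = %.4f (gamma %g, omega %g)\n",
    nrow(x$labels), ncol(x$labels), x$n_modules, x$quality, x$gamma, x$omega))
  invisible(x)
}

#' Repeat the stochastic partition optimization
#'
#' Runs [optimize_partition()] `params$n_repetitions` times with
#' per-repetition seeds derived from `params$seed`; community detection is
#' stochastic, so downstream switching rates are averaged over these
#' repetitions. Order-stable and deterministic given the seed.
#'
#' @param stack A nonnegative `layer_stack`.
#' @param params A [multilayer_params()].
#' @return A list of `partition_stack` objects of length `n_repetitions`.
#' @export
repeat_partitions <- function(stack, params = multilayer_params()) {
  seeds <- c(params$seed,
             vapply(seq_len(params$n_repetitions)[-1L],
                    function(r) derive_seed(params$seed, 500L + r), 1L))
  lapply(seeds, function(s) optimize_partition(stack, params, seed = s))
}
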