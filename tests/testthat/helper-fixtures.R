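# Shared fixtures and independent oracles, built in code.

# Two disconnected unit-weight triangles on 6 nodes (classic Q = 0.5 case).
two_triangles <- function() {
  A <- matrix(0, 6, 6)
  A[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
  A + t(A)
}

# Random nonnegative symmetric zero-diagonal layer stack.
random_stack <- function(n, L, seed, density = 0.6) {
  set.seed(seed)
  layers <- array(0, c(n, n, L))
  for (s in seq_len(L)) {
    A <- matrix(stats::runif(n * n), n)
    A <- (A + t(A)) / 2
    A[A < stats::quantile(A, 1 - density)] <- 0
    diag(A) <- 0
    layers[, , s] <- A
  }
  layers
}

# Independent oracle: multilayer modularity by literal quadruple summation
# over (i, j, s, r) of [(A_ijs - gamma k_is k_js / 2m_s) delta_sr +
# delta_ij C_jsr] delta(g_is, g_jr), normalized by
# 2mu = sum_s 2m_s + 2 omega n (L - 1).
direct_q <- function(layers, labels, gamma = 1, omega = 1) {
  n <- dim(layers)[1L]
  L <- dim(layers)[3L]
  q <- 0
  twomu <- 0
  for (s in seq_len(L)) {
    k <- rowSums(layers[, , s])
    twom <- sum(k)
    twomu <- twomu + twom
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (labels[i, s] == labels[j, s]) {
        null <- if (twom > 0) gamma * k[i] * k[j] / twom else 0
        q <- q + layers[i, j, s] - null
      }
    }
    for (r in seq_len(L)) {
      if (abs(s - r) == 1L) {
        for (i in seq_len(n)) {
          if (labels[i, s] == labels[i, r]) q <- q + omega
        }
      }
    }
  }
  twomu <- twomu + 2 * omega * n * (L - 1L)
  if (twomu > 0) q / twomu else 0
}

# All set partitions of n elements as restricted-growth label vectors.
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) {
      out[[length(out) + 1L]] <<- s
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-search maximum of the multilayer modularity over all joint
# partitions of the node-layer vertices (only feasible for n * L <= 8).
exhaustive_max_q <- function(layers, gamma = 1, omega = 1) {
  n <- dim(layers)[1L]
  L <- dim(layers)[3L]
  stopifnot(n * L <= 8L)
  best <- -Inf
  for (p in set_partitions(n * L)) {
    q <- multilayer_modularity(layers, matrix(p, n, L), gamma, omega)
    if (q > best) best <- q
  }
  best
}

# Benchmark design with graded planted switching: 8 of 20 nodes switch
# 1..5 times between their base module and a per-node partner module, with
# jittered, well-separated event times; strong within-module correlation.
graded_benchmark_design <- function() {
  base <- rep(1:4, each = 5)
  counts <- c(0, 0, 0, 0, 1, 0, 0, 0, 2, 3,
              0, 0, 0, 1, 4, 0, 0, 2, 3, 5)
  partner <- c(NA, NA, NA, NA, 2, NA, NA, NA, 3, 4,
               NA, NA, NA, 1, 2, NA, NA, 1, 2, 3)
  jit <- c(-4, 2, 5, -7, 7, -1, 8, 3, -6, 0,
           6, -8, 1, -2, 4, -5, 2, -3, 8, -1)
  rows <- list()
  for (i in which(counts > 0)) {
    vols <- round(seq(45, 215, length.out = counts[i] + 2))[2:(counts[i] + 1)] +
      jit[i]
    cur <- base[i]
    for (v in vols) {
      nxt <- if (cur == base[i]) partner[i] else base[i]
      rows[[length(rows) + 1L]] <- data.frame(node = i, volume = v,
                                              module = nxt)
      cur <- nxt
    }
  }
  planted_design(n_nodes = 20, n_volumes = 240, base_partition = base,
                 within_module_corr = 0.9,
                 switch_events = do.call(rbind, rows))
}

# Align a cohort's outcome values into subject-order vectors for one level,
# outcome and scan.
outcome_vector <- function(cohort, level, outcome, scan) {
  oc <- cohort$outcomes
  sel <- oc$level == level & oc$outcome == outcome & oc$scan == scan
  oc$value[sel][match(cohort$subjects$subject_id, oc$subject_id[sel])]
}
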