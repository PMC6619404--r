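# Independent oracles, deliberately written without reusing package internals.

# Boltzmann probabilities for N = 2 by explicit enumeration of the 4 states,
# in the package's index order (00, 01, 10, 11) = (--, -+, +-, ++).
boltzmann2 <- function(h1, h2, j12) {
  states <- list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  w <- vapply(states, function(s) {
    exp(h1 * s[1] + h2 * s[2] + j12 * s[1] * s[2])
  }, numeric(1))
  w / sum(w)
}

# KL divergence in bits by direct summation
kl2_oracle <- function(p, q) {
  stopifnot(length(p) == length(q))
  s <- 0
  for (k in seq_along(p)) if (p[k] > 0) s <- s + p[k] * log2(p[k] / q[k])
  s
}

# random energy landscape with all-distinct energies
random_landscape <- function(n_roi) {
  repeat {
    e <- stats::rnorm(2^n_roi, sd = 2)
    if (!anyDuplicated(e)) return(energy_landscape(e, n_roi = n_roi))
  }
}

# hypercube adjacency as an igraph object (0-based pattern ids + 1)
hypercube_graph <- function(n_roi) {
  edges <- c()
  for (k in 0:(2^n_roi - 1)) {
    for (i in seq_len(n_roi)) {
      k2 <- bitwXor(k, 2^(n_roi - i))
      if (k2 > k) edges <- c(edges, k + 1L, k2 + 1L)
    }
  }
  igraph::make_graph(edges, n = 2^n_roi, directed = FALSE)
}

# minimax path cost between two patterns: minimum over all simple paths of
# the maximum node energy en route (exhaustive enumeration)
minimax_oracle <- function(graph, energies, from, to) {
  paths <- igraph::all_simple_paths(graph, from = from + 1L, to = to + 1L)
  min(vapply(paths, function(p) max(energies[as.integer(p)]), numeric(1)))
}

# recursive steepest-descent basin oracle
descent_oracle <- function(energies, n_roi, k) {
  nbs <- vapply(seq_len(n_roi), function(i) bitwXor(k, 2^(n_roi - i)),
                integer(1))
  if (all(energies[k + 1] < energies[nbs + 1])) return(k)
  descent_oracle(energies, n_roi, nbs[which.min(energies[nbs + 1])])
}

# direct-transition oracle: within each segment, keep only the synchronized
# visits and count label changes in that subsequence
direct_count_oracle <- function(labels, boundaries = integer()) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(labels))
  total <- 0L
  for (s in seq_along(starts)) {
    seg <- labels[starts[s]:ends[s]]
    sync <- seg[seg %in% c("s+", "s-")]
    if (length(sync) >= 2) total <- total + sum(sync[-1] != sync[-length(sync)])
  }
  total
}

# consecutive b+/b- crossing oracle
basin_count_oracle <- function(labels, boundaries = integer()) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(labels))
  total <- 0L
  for (s in seq_along(starts)) {
    seg <- labels[starts[s]:ends[s]]
    if (length(seg) < 2) next
    for (t in seq_len(length(seg) - 1)) {
      if ((seg[t] == "b+" && seg[t + 1] == "b-") ||
          (seg[t] == "b-" && seg[t + 1] == "b+")) total <- total + 1L
    }
  }
  total
}

# random category label sequence
random_labels <- function(t_len) {
  sample(c("s+", "s-", "b+", "b-", "b_other"), t_len, replace = TRUE,
         prob = c(0.2, 0.2, 0.25, 0.25, 0.1))
}

# small ground-truth model with moderate couplings
toy_model <- function(n_roi, seed = 1, h_range = 0.3, j_range = 0.3) {
  set.seed(seed)
  J <- matrix(0, n_roi, n_roi)
  J[upper.tri(J)] <- stats::runif(n_roi * (n_roi - 1) / 2, -j_range, j_range)
  J <- J + t(J)
  ground_truth_model(h = stats::runif(n_roi, -h_range, h_range), J = J)
}
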