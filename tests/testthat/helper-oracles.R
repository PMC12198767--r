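# Independent brute-force oracles for the graph metrics, written directly
# from the definitions and kept free of any package code path.

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) total <- total + 1 / d[i, j]
    }
  }
  total / (n * (n - 1))
}

oracle_clustering_mean <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    cc[i] <- tri / (k * (k - 1) / 2)
  }
  mean(cc)
}

oracle_modularity <- function(adj, mem) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (s in unique(mem)) {
    nodes <- which(mem == s)
    e_s <- sum(adj[nodes, nodes, drop = FALSE]) / 2
    d_s <- sum(adj[nodes, , drop = FALSE])
    q <- q + e_s / m - (d_s / (2 * m))^2
  }
  q
}

oracle_participation <- function(adj, mem) {
  n <- nrow(adj)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ])
    if (k == 0) next
    acc <- 0
    for (s in unique(mem)) {
      kis <- sum(adj[i, mem == s])
      acc <- acc + (kis / k)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# Trapezoid rule written independently of auc_of_curve.
oracle_trapezoid <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  total
}

# Hand-executed Benjamini-Hochberg step-up procedure.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Random Erdos-Renyi-style adjacency matrix (possibly disconnected).
random_adjacency <- function(n, p_edge) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(stats::runif(sum(up)) < p_edge)
  a + t(a)
}

random_membership <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

make_graph <- function(adj) binary_graph(adj, paste0("N", seq_len(nrow(adj))))

make_part <- function(mem, ids = paste0("N", seq_along(mem))) {
  module_partition(stats::setNames(mem, ids))
}

# Small cohort used across tests; cheap but exercises every pipeline stage.
tiny_cohort_spec <- function(seed = 11, ...) {
  args <- list(n_patients = 3, n_controls = 4, n_nodes = 40, n_modules = 4,
               timepoints_patients = c("TP1", "TP2"), lesion_count = 8,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}
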