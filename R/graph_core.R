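#' Remove negative weights from a connectome
#'
#' First thresholding step of the graph pipeline: an absolute threshold w > 0
#' that zeroes all non-positive off-diagonal weights and leaves positive
#' weights untouched.
#'
#' @param conn a [connectome].
#' @return a [connectome] with non-positive off-diagonal weights set to 0.
#' @export
positive_threshold <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  w[w <= 0] <- 0
  diag(w) <- 1
  connectome(w, conn$node_ids, conn$removed_nodes)
}

# Upper-triangle edges of positive weight, in the deterministic retention
# order: weight descending, then lexicographic (i, j) node pair. Ties are
# broken stably so proportional thresholding is reproducible.
positive_edge_order <- function(conn) {
  w <- conn$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(i = integer(0), j = integer(0), w = numeric(0)))
  }
  i <- idx[, 1]; j <- idx[, 2]; wt <- w[idx]
  ord <- order(-wt, i, j)
  list(i = i[ord], j = j[ord], w = wt[ord])
}

# Internal constructor bypassing validation for adjacency matrices built by
# the thresholding code itself.
new_binary_graph <- function(adjacency, node_ids) {
  n <- length(node_ids)
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(
    list(node_ids = node_ids, adjacency = adjacency,
         density = if (n >= 2) sum(adjacency) / (n * (n - 1)) else 0),
    class = "binary_graph"
  )
}

# Retained edge count at density delta: round half away from zero.
retained_count <- function(delta, p) floor(delta * p + 0.5)

#' Proportional thresholding and binarization
#'
#' Retains the strongest positive edges of the (already positively
#' thresholded) weighted connectome so that a fraction `delta` of positive
#' weights survives, and sets them to 1. `delta = 0` keeps no connection,
#' `delta = 1` retains every positive connection. The retained edge count is
#' `delta * P` rounded half-away-from-zero, where P counts positive
#' upper-triangle weights; ties in weight are broken by lexicographic node
#' pair so results are reproducible.
#'
#' @param conn a [connectome] (negative weights are zeroed internally).
#' @param delta target density in `[0, 1]`.
#' @return a [binary_graph].
#' @export
proportional_binarize <- function(conn, delta) {
  stopifnot(inherits(conn, "connectome"))
  stop_if_not_scalar_number(delta, "delta")
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  edges <- positive_edge_order(conn)
  k <- retained_count(delta, length(edges$w))
  n <- length(conn$node_ids)
  adj <- matrix(0, n, n)
  if (k > 0) {
    keep <- seq_len(k)
    adj[cbind(edges$i[keep], edges$j[keep])] <- 1
    adj[cbind(edges$j[keep], edges$i[keep])] <- 1
  }
  new_binary_graph(adj, conn$node_ids)
}

#' Stack of binarized graphs over a density grid
#'
#' Applies [proportional_binarize()] at each density of the grid (default
#' 0.1, 0.2, ..., 1.0), yielding one binary graph per density. Edge sets are
#' nested: the graph at a lower density is a subgraph of the graph at any
#' higher density.
#'
#' @param conn a [connectome].
#' @param grid ascending densities in `(0, 1]`.
#' @return a list of [binary_graph] objects, named by density.
#' @export
density_stack <- function(conn, grid = default_density_grid()) {
  stopifnot(inherits(conn, "connectome"))
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be strictly ascending", call. = FALSE)
  if (any(grid < 0 | grid > 1)) stop("densities must lie in [0, 1]", call. = FALSE)
  # sort the positive edges once; the stacks are nested, so each graph is the
  # previous one plus the next tranche of edges
  edges <- positive_edge_order(conn)
  p <- length(edges$w)
  n <- length(conn$node_ids)
  adj <- matrix(0, n, n)
  prev_k <- 0L
  out <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    k <- retained_count(grid[gi], p)
    if (k > prev_k) {
      add <- seq.int(prev_k + 1L, k)
      adj[cbind(edges$i[add], edges$j[add])] <- 1
      adj[cbind(edges$j[add], edges$i[add])] <- 1
      prev_k <- k
    }
    out[[gi]] <- new_binary_graph(adj, conn$node_ids)
  }
  names(out) <- formatC(grid, format = "g")
  out
}

#' @rdname density_stack
#' @export
default_density_grid <- function() seq(0.1, 1, by = 0.1)

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with the
#' convention 1/Inf = 0 for disconnected pairs (Latora-Marchiori). Equals 1
#' for a complete graph and 0 for an edgeless one.
#'
#' @param g a [binary_graph].
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- length(g$node_ids)
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  if (sum(g$adjacency) == 0) return(0)
  e <- which(upper.tri(g$adjacency) & g$adjacency == 1)
  ends <- cbind((e - 1) %% n + 1, (e - 1) %/% n + 1)
  ig <- igraph::make_undirected_graph(t(ends), n = n)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Newman modularity at a fixed partition
#'
#' Q = sum_s (e_s / m - (d_s / 2m)^2) evaluated at the supplied a-priori
#' partition (no community detection), where m is the total edge count,
#' e_s the number of intra-module edges of module s and d_s its degree sum.
#' Returns 0 for an edgeless graph by convention.
#'
#' @param g a [binary_graph].
#' @param partition a [module_partition] covering all nodes of `g`.
#' @return scalar modularity Q.
#' @export
modularity_fixed <- function(g, partition) {
  stopifnot(inherits(g, "binary_graph"))
  mem <- match_partition(g, partition)
  a <- g$adjacency
  m <- sum(a) / 2
  if (m == 0) return(0)
  deg <- rowSums(a)
  q <- 0
  for (s in unique(mem)) {
    in_s <- mem == s
    e_s <- sum(a[in_s, in_s, drop = FALSE]) / 2
    d_s <- sum(deg[in_s])
    q <- q + e_s / m - (d_s / (2 * m))^2
  }
  q
}

match_partition <- function(g, partition) {
  stopifnot(inherits(partition, "module_partition"))
  mem <- unclass(partition)[g$node_ids]
  if (anyNA(mem)) {
    stop(sprintf("partition is missing nodes: %s",
                 paste(g$node_ids[is.na(mem)], collapse = ", ")), call. = FALSE)
  }
  as.integer(mem)
}

#' Mean clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' (triangles through the node) / (k (k - 1) / 2); nodes of degree < 2
#' contribute 0.
#'
#' @param g a [binary_graph] with at least 3 nodes.
#' @return scalar in `[0, 1]`.
#' @export
clustering_mean <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- length(g$node_ids)
  if (n < 3) stop("clustering coefficient needs at least 3 nodes", call. = FALSE)
  a <- g$adjacency
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2 # triangles through each node
  cc <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  mean(cc)
}

#' Nodal participation coefficient
#'
#' PC_i = 1 - sum_s (k_is / k_i)^2 where k_is counts node i's edges into
#' module s and k_i is its degree. Measures how evenly a node's connections
#' spread across modules; 0 when all edges stay within one module (and, by
#' convention, for isolated nodes). High-PC nodes are the network's hubs.
#'
#' @param g a [binary_graph].
#' @param partition a [module_partition] covering all nodes of `g`.
#' @return named numeric vector of PC values in `[0, 1]`, one per node.
#' @export
participation <- function(g, partition) {
  stopifnot(inherits(g, "binary_graph"))
  mem <- match_partition(g, partition)
  a <- g$adjacency
  deg <- rowSums(a)
  mods <- sort(unique(mem))
  # k_is: edges of node i into module s
  kis <- vapply(mods, function(s) rowSums(a[, mem == s, drop = FALSE]), numeric(nrow(a)))
  kis <- matrix(kis, nrow = nrow(a))
  pc <- ifelse(deg > 0, 1 - rowSums((kis / pmax(deg, 1))^2), 0)
  stats::setNames(pc, g$node_ids)
}

metric_names <- function() {
  c("global_efficiency", "modularity", "clustering", "participation_mean")
}

evaluate_metric <- function(g, metric_name, partition = NULL) {
  switch(metric_name,
    global_efficiency = global_efficiency(g),
    modularity = modularity_fixed(g, partition),
    clustering = clustering_mean(g),
    participation_mean = mean(participation(g, partition)),
    stop(sprintf("unknown metric `%s`", metric_name), call. = FALSE)
  )
}

#' Metric-versus-density curve and its AUC
#'
#' Computes the chosen graph metric on each binarized graph of the density
#' stack (default grid 0.1, ..., 1.0, i.e. 10 values) and summarizes the
#' curve by its area under the curve over the full density range `[0, 1]`
#' via [auc_of_curve()]. The AUC is the threshold-free proxy of the metric
#' used for all downstream statistics.
#'
#' @param conn a [connectome].
#' @param metric_name one of `"global_efficiency"`, `"modularity"`,
#'   `"clustering"`, `"participation_mean"`.
#' @param partition a [module_partition]; required for modularity and
#'   participation.
#' @param grid density grid, ascending in `(0, 1]`.
#' @return an object of class `density_curve`: list with `metric_name`,
#'   `grid`, `values` and `auc`.
#' @export
metric_curve <- function(conn, metric_name, partition = NULL,
                         grid = default_density_grid()) {
  metric_name <- match.arg(metric_name, metric_names())
  if (metric_name %in% c("modularity", "participation_mean") && is.null(partition)) {
    stop(sprintf("`partition` is required for metric `%s`", metric_name), call. = FALSE)
  }
  stack <- density_stack(conn, grid)
  values <- vapply(stack, evaluate_metric, numeric(1),
                   metric_name = metric_name, partition = partition)
  curve <- structure(
    list(metric_name = metric_name, grid = grid, values = unname(values), auc = NA_real_),
    class = "density_curve"
  )
  curve$auc <- auc_of_curve(curve)
  curve
}

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of M(delta) over delta in `[0, 1]`. If the grid does
#' not start at 0, the analytic delta = 0 endpoint is prepended: the metric
#' value of the edgeless graph, which is 0 for all four metrics (overridable
#' via `value_at_zero`).
#'
#' @param curve a `density_curve`, or a list with numeric `grid` and `values`.
#' @param value_at_zero metric value of the edgeless graph, prepended when the
#'   grid starts above 0.
#' @return scalar AUC.
#' @export
auc_of_curve <- function(curve, value_at_zero = 0) {
  grid <- curve$grid
  values <- curve$values
  if (length(grid) != length(values)) stop("grid/value length mismatch", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be sorted ascending", call. = FALSE)
  if (grid[1] > 0) {
    grid <- c(0, grid)
    values <- c(value_at_zero, values)
  }
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' @exportS3Method base::print
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> %s over %d densities, AUC = %.4f\n",
              x$metric_name, length(x$grid), x$auc))
  invisible(x)
}
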