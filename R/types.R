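#' Region-level BOLD time series
#'
#' Container for region x time signal tables as extracted from an atlased
#' functional scan: one row per retained atlas region, one column per volume.
#' An optional nuisance block (time x k matrix: motion-like drifts, spike
#' indicators, CSF-like signals) rides along and is consumed by
#' [detrend_and_regress()].
#'
#' @param samples numeric matrix, regions x time.
#' @param region_ids character vector of unique region labels, one per row.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param nuisance optional numeric matrix, time x k, of nuisance regressors.
#' @return an object of class `region_ts`.
#' @export
region_ts <- function(samples, region_ids = rownames(samples), tr_seconds = 2,
                      nuisance = NULL) {
  samples <- as.matrix(samples)
  if (is.null(region_ids)) {
    region_ids <- paste0("R", seq_len(nrow(samples)))
  }
  region_ids <- as.character(region_ids)
  if (anyNA(samples)) stop("time series must not contain missing values", call. = FALSE)
  if (ncol(samples) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (length(region_ids) != nrow(samples)) {
    stop("`region_ids` must have one entry per row of `samples`", call. = FALSE)
  }
  if (anyDuplicated(region_ids)) stop("`region_ids` must be unique", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != ncol(samples)) {
      stop("nuisance block must have one row per time point", call. = FALSE)
    }
  }
  rownames(samples) <- region_ids
  structure(
    list(region_ids = region_ids, samples = samples,
         tr_seconds = tr_seconds, nuisance = nuisance),
    class = "region_ts"
  )
}

#' @exportS3Method base::print
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d regions x %d volumes, TR = %g s, %s nuisance regressors\n",
              nrow(x$samples), ncol(x$samples), x$tr_seconds,
              if (is.null(x$nuisance)) "no" else ncol(x$nuisance)))
  invisible(x)
}

#' Weighted connectome
#'
#' Symmetric region x region connectivity matrix with unit diagonal plus a
#' ledger of removed nodes. The ledger records why each region left the
#' matrix: `"dropout"` (signal dropout), `"primary_lesion"` (the subject's own
#' index stroke) or `"attack"` (virtual lesion).
#'
#' @param weights symmetric numeric matrix with unit diagonal.
#' @param node_ids character vector of region labels, one per row/column.
#' @param removed_nodes data.frame with columns `region_id`, `reason`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, node_ids = rownames(weights),
                       removed_nodes = empty_removal_ledger()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("`weights` must be square", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("R", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("`node_ids` length must match matrix order", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("`node_ids` must be unique", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  if (n > 0 && max(abs(diag(weights) - 1)) > 1e-10) {
    stop("`weights` must have unit diagonal", call. = FALSE)
  }
  diag(weights) <- 1
  removed_nodes <- validate_removal_ledger(removed_nodes)
  if (any(removed_nodes$region_id %in% node_ids)) {
    stop("removed nodes must not appear among `node_ids`", call. = FALSE)
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(
    list(node_ids = node_ids, weights = weights, removed_nodes = removed_nodes),
    class = "connectome"
  )
}

empty_removal_ledger <- function() {
  data.frame(region_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

validate_removal_ledger <- function(ledger) {
  ledger <- as.data.frame(ledger, stringsAsFactors = FALSE)
  if (!all(c("region_id", "reason") %in% names(ledger))) {
    stop("removal ledger needs columns `region_id` and `reason`", call. = FALSE)
  }
  ok <- ledger$reason %in% c("dropout", "primary_lesion", "attack")
  if (!all(ok)) {
    stop("removal reasons must be dropout, primary_lesion or attack", call. = FALSE)
  }
  ledger[, c("region_id", "reason")]
}

#' @exportS3Method base::print
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d removed (%s)\n",
              length(x$node_ids), nrow(x$removed_nodes),
              if (nrow(x$removed_nodes) == 0) "none"
              else paste(sprintf("%s: %d", names(table(x$removed_nodes$reason)),
                                 as.integer(table(x$removed_nodes$reason))),
                         collapse = ", ")))
  invisible(x)
}

#' A-priori module partition
#'
#' Node-to-module assignment used as the fixed community structure for
#' modularity and participation-coefficient computations (by default a
#' 17-module template in the spirit of canonical cortical network
#' parcellations).
#'
#' @param modules integer vector of module indices (1-based), named by node id,
#'   or a data.frame with columns `node_id` and `module_id`.
#' @return an object of class `module_partition`: a named integer vector.
#' @export
module_partition <- function(modules) {
  if (is.data.frame(modules)) {
    m <- as.integer(modules$module_id)
    names(m) <- as.character(modules$node_id)
    modules <- m
  }
  if (is.null(names(modules)) || anyDuplicated(names(modules))) {
    stop("partition must be named by unique node ids", call. = FALSE)
  }
  modules <- stats::setNames(as.integer(modules), names(modules))
  if (anyNA(modules)) stop("module ids must be integers", call. = FALSE)
  if (length(modules) == 0L) stop("partition must not be empty", call. = FALSE)
  structure(modules, class = "module_partition")
}

#' @exportS3Method base::print
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' @export
`[.module_partition` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "module_partition"
  out
}

#' Binary graph
#'
#' Hollow symmetric 0/1 adjacency matrix produced by proportional
#' thresholding of a weighted connectome; carries its realized edge density
#' 2E / (n (n - 1)).
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param node_ids character labels, one per node.
#' @return an object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, node_ids = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("adjacency must be square", call. = FALSE)
  if (is.null(node_ids)) node_ids <- paste0("R", seq_len(n))
  node_ids <- as.character(node_ids)
  storage.mode(adjacency) <- "double"
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be 0/1", call. = FALSE)
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0)) stop("adjacency must be hollow", call. = FALSE)
  dimnames(adjacency) <- list(node_ids, node_ids)
  density <- if (n >= 2) sum(adjacency) / (n * (n - 1)) else 0
  structure(
    list(node_ids = node_ids, adjacency = adjacency, density = density),
    class = "binary_graph"
  )
}

#' @exportS3Method base::print
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, density %.3f\n",
              length(x$node_ids), sum(x$adjacency) / 2, x$density))
  invisible(x)
}
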