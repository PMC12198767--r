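#' Read and write connectomes as delimited matrix files
#'
#' The on-disk format is a TSV: node ids in the header and first column,
#' symmetric weights in the body. The removal ledger travels in a `.removed`
#' sidecar TSV when non-empty.
#'
#' @param conn a [connectome].
#' @param path file path.
#' @return `write_connectome` returns `path` invisibly; `read_connectome`
#'   returns a [connectome].
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  df <- data.frame(node_id = conn$node_ids, conn$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(conn$removed_nodes) > 0) {
    utils::write.table(conn$removed_nodes, paste0(path, ".removed"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  w <- as.matrix(df[, -1, drop = FALSE])
  ledger <- empty_removal_ledger()
  side <- paste0(path, ".removed")
  if (file.exists(side)) {
    ledger <- utils::read.table(side, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  connectome(w, ids, ledger)
}

#' Read and write module partitions as two-column TSV (node_id, module_id)
#'
#' @param partition a [module_partition].
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  utils::write.table(
    data.frame(node_id = names(partition), module_id = as.integer(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  module_partition(df)
}

#' Read region time series from TSV (regions x time, first column region_id)
#'
#' @param path file path.
#' @param tr_seconds sampling interval.
#' @return a [region_ts].
#' @export
read_region_ts <- function(path, tr_seconds = 2) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  region_ts(as.matrix(df[, -1, drop = FALSE]), as.character(df[[1]]), tr_seconds)
}

#' @rdname read_region_ts
#' @param ts a [region_ts].
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  df <- data.frame(region_id = ts$region_ids, ts$samples, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the subject table (`subjects.tsv`), the partition
#' (`partition.tsv`), the lesion library (`lesions.txt` + JSON sidecar) and
#' one connectome matrix file per subject-timepoint under `connectomes/`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "connectomes"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  write_lesion_library(cohort$lesion_library, file.path(dir, "lesions.txt"))
  for (key in names(cohort$connectomes)) {
    write_connectome(cohort$connectomes[[key]],
                     file.path(dir, "connectomes", paste0(key, ".tsv")))
  }
  invisible(dir)
}

#' Write attack-battery outcomes as TSV (plus the skip log)
#'
#' @param battery an `attack_battery`.
#' @param path outcome TSV path; the skip log gets `.skipped` appended.
#' @export
write_battery <- function(battery, path) {
  stopifnot(inherits(battery, "attack_battery"))
  utils::write.table(battery$outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(battery$skip_log) > 0) {
    utils::write.table(battery$skip_log, paste0(path, ".skipped"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
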