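#' Linear detrending and nuisance regression
#'
#' Replaces each region series by its least-squares residual after projecting
#' out an intercept, a linear trend and (if present) the nuisance block of
#' the series object. Residuals are orthogonal to every projected column.
#' A rank-deficient nuisance block triggers a warning and a pseudo-inverse
#' projection onto the span of the design.
#'
#' @param ts a [region_ts].
#' @return a [region_ts] of residual series (nuisance block dropped).
#' @export
detrend_and_regress <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  t_len <- ncol(ts$samples)
  design <- cbind(intercept = 1, trend = seq_len(t_len))
  if (!is.null(ts$nuisance)) design <- cbind(design, ts$nuisance)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("rank-deficient nuisance block; projecting with a pseudo-inverse",
            call. = FALSE)
  }
  # qr.resid projects onto the orthogonal complement of the column span,
  # which is the pseudo-inverse projection when the design is rank deficient.
  resid <- t(qr.resid(qrd, t(ts$samples)))
  region_ts(resid, ts$region_ids, ts$tr_seconds, nuisance = NULL)
}

#' Winsorize region series to percentile bounds
#'
#' Per region, values below the lower percentile are set to it and values
#' above the upper percentile are set to it; interior values are unchanged.
#' Percentiles use linear interpolation between closest ranks
#' (`stats::quantile()` type 7). A constant series is returned unchanged.
#'
#' @param ts a [region_ts].
#' @param lower_pct,upper_pct percentile bounds in `[0, 100]`, lower < upper.
#' @return a winsorized [region_ts].
#' @export
winsorize <- function(ts, lower_pct = 5, upper_pct = 95) {
  stopifnot(inherits(ts, "region_ts"))
  if (!(lower_pct < upper_pct)) stop("`lower_pct` must be below `upper_pct`", call. = FALSE)
  out <- t(apply(ts$samples, 1, function(x) {
    qs <- stats::quantile(x, c(lower_pct, upper_pct) / 100, names = FALSE, type = 7)
    pmin(pmax(x, qs[1]), qs[2])
  }))
  region_ts(out, ts$region_ids, ts$tr_seconds, ts$nuisance)
}

#' Wavelet sub-band extraction
#'
#' Decomposes each region series with a maximal-overlap discrete wavelet
#' transform (orthogonal least-asymmetric 16-tap filter by default, periodic
#' boundary) and returns the detail reconstruction of the level whose dyadic
#' band \eqn{[1/(2^{j+1} TR), 1/(2^j TR)]} covers the target frequency range
#' (default 0.03-0.06 Hz; level j = 3 for TR = 2 s). The level is computed
#' from the TR rather than hard-coded.
#'
#' @param ts a [region_ts].
#' @param band target frequency range in Hz, length 2.
#' @param wavelet filter name, `"la16"` (default), `"la8"`, `"d4"` or `"haar"`.
#' @return a [region_ts] holding the band-limited detail series.
#' @export
wavelet_band <- function(ts, band = c(0.03, 0.06), wavelet = "la16") {
  stopifnot(inherits(ts, "region_ts"))
  if (ts$tr_seconds <= 0) stop("TR must be positive", call. = FALSE)
  level <- band_to_level(band, ts$tr_seconds)
  min_len <- 2^4
  if (ncol(ts$samples) < min_len) {
    stop(sprintf("series too short for a 4-level wavelet decomposition: need >= %d volumes",
                 min_len), call. = FALSE)
  }
  out <- t(apply(ts$samples, 1, function(x) modwt_detail(x, level, wavelet)))
  region_ts(out, ts$region_ids, ts$tr_seconds, ts$nuisance)
}

# Dyadic level whose band [1/(2^(j+1) TR), 1/(2^j TR)] contains the centre
# of the target band: j = floor(log2(1 / (f0 * TR))).
band_to_level <- function(band, tr_seconds) {
  f0 <- sqrt(band[1] * band[2]) # geometric centre of the target band
  j <- floor(log2(1 / (f0 * tr_seconds)))
  max(1L, as.integer(j))
}

#' Pearson correlation connectome from region series
#'
#' @param ts a [region_ts] whose regions all have nonzero variance.
#' @return a [connectome] of Pearson correlation coefficients.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  v <- apply(ts$samples, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance regions: %s",
                 paste(ts$region_ids[v == 0], collapse = ", ")), call. = FALSE)
  }
  w <- stats::cor(t(ts$samples))
  connectome(w, ts$region_ids)
}

#' Remove dropout and primary-lesion regions from a connectome
#'
#' Deletes the rows/columns of the named regions and records each removal in
#' the connectome's ledger with its reason. Idempotent: regions already in
#' the ledger are silently skipped.
#'
#' @param conn a [connectome].
#' @param dropout_ids regions with signal dropout.
#' @param primary_lesioned regions overlapping the subject's index stroke.
#' @return the reduced [connectome].
#' @export
exclude_regions <- function(conn, dropout_ids = character(0),
                            primary_lesioned = character(0)) {
  stopifnot(inherits(conn, "connectome"))
  dropout_ids <- as.character(dropout_ids)
  primary_lesioned <- as.character(primary_lesioned)
  known <- c(conn$node_ids, conn$removed_nodes$region_id)
  unknown <- setdiff(c(dropout_ids, primary_lesioned), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown regions: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ledger <- conn$removed_nodes
  new_dropout <- setdiff(dropout_ids, ledger$region_id)
  new_primary <- setdiff(setdiff(primary_lesioned, ledger$region_id), dropout_ids)
  add <- data.frame(
    region_id = c(new_dropout, new_primary),
    reason = c(rep("dropout", length(new_dropout)),
               rep("primary_lesion", length(new_primary))),
    stringsAsFactors = FALSE)
  add <- add[add$region_id %in% conn$node_ids, , drop = FALSE]
  keep <- !(conn$node_ids %in% add$region_id)
  if (sum(keep) < 2) stop("removal would leave fewer than 2 nodes", call. = FALSE)
  connectome(conn$weights[keep, keep, drop = FALSE], conn$node_ids[keep],
             rbind(ledger, add))
}

#' Full region-series-to-connectome pipeline
#'
#' Convenience composition in the fixed order: detrend + nuisance regression,
#' winsorization, wavelet sub-band filtering, Pearson correlation and region
#' exclusion.
#'
#' @inheritParams detrend_and_regress
#' @inheritParams exclude_regions
#' @param band,wavelet passed to [wavelet_band()].
#' @param lower_pct,upper_pct passed to [winsorize()].
#' @return a [connectome].
#' @export
build_connectome <- function(ts, dropout_ids = character(0),
                             primary_lesioned = character(0),
                             band = c(0.03, 0.06), wavelet = "la16",
                             lower_pct = 5, upper_pct = 95) {
  ts <- detrend_and_regress(ts)
  ts <- winsorize(ts, lower_pct, upper_pct)
  ts <- wavelet_band(ts, band, wavelet)
  conn <- correlation_matrix(ts)
  exclude_regions(conn, dropout_ids, primary_lesioned)
}
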