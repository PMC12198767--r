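#' Per-node participation-coefficient table for a cohort
#'
#' Computes, for every subject and timepoint, the nodal participation
#' coefficient summarized over the density grid as an AUC (the same
#' threshold-free machinery as the whole-brain metrics; pass a single
#' density in `grid` for a single-density variant). Patients' matrices are
#' reduced by their primary-lesion regions first, so their tables cover the
#' surviving nodes only.
#'
#' @inheritParams run_attack_battery
#' @return data.frame with columns `subject_id`, `group`, `timepoint`,
#'   `node_id`, `pc` (one row per subject x timepoint x node).
#' @export
compute_node_pc <- function(cohort, grid = default_density_grid()) {
  subjects <- cohort$subjects
  prim <- lapply(stats::setNames(subjects$primary_removed_regions, subjects$subject_id),
                 function(s) if (is.na(s) || !nzchar(s)) character(0)
                             else strsplit(s, ",", fixed = TRUE)[[1]])
  out <- lapply(seq_len(nrow(subjects)), function(si) {
    sid <- subjects$subject_id[si]
    tp <- subjects$timepoint[si]
    conn <- cohort$connectomes[[paste0(sid, ".", tp)]]
    primary <- prim[[sid]]
    if (length(primary) > 0) conn <- exclude_regions(conn, primary_lesioned = primary)
    stack <- density_stack(conn, grid)
    pcs <- vapply(stack, participation, numeric(length(conn$node_ids)),
                  partition = cohort$partition)
    pcs <- matrix(pcs, nrow = length(conn$node_ids))
    auc <- apply(pcs, 1, function(v) auc_of_curve(list(grid = grid, values = v)))
    data.frame(subject_id = sid, group = subjects$group[si], timepoint = tp,
               node_id = conn$node_ids, pc = unname(auc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hub and anti-hub node lists from control participation coefficients
#'
#' Ranks nodes by their mean PC across control subjects at the reference
#' timepoint and returns the `k` highest-PC nodes (hubs) and `k` lowest-PC
#' nodes (anti-hubs). Ties are broken by node id, ascending, so the lists
#' are deterministic functions of the control rows.
#'
#' @param pc_table table from [compute_node_pc()].
#' @param k list length (default 10).
#' @param control_timepoint reference timepoint.
#' @return list with `top` and `bottom` character vectors and the per-node
#'   `control_means`.
#' @export
rank_nodes_by_control_pc <- function(pc_table, k = 10, control_timepoint = "TP1") {
  ctl <- pc_table[pc_table$group == "control" &
                  pc_table$timepoint == control_timepoint, , drop = FALSE]
  if (nrow(ctl) == 0) stop("no control rows at the reference timepoint", call. = FALSE)
  means <- stats::aggregate(pc ~ node_id, data = ctl, FUN = mean)
  if (k > nrow(means)) stop("`k` exceeds the number of nodes", call. = FALSE)
  ord_top <- order(-means$pc, means$node_id)
  ord_bot <- order(means$pc, means$node_id)
  list(top = means$node_id[ord_top][seq_len(k)],
       bottom = means$node_id[ord_bot][seq_len(k)],
       control_means = stats::setNames(means$pc, means$node_id))
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties. A constant vector makes the
#' statistic undefined: `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Exponentiated-Weibull distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the exponentiated Weibull with exponentiation shape `a`, Weibull
#' shape `c` and scale `scale` (location fixed at 0):
#' \eqn{F(x) = (1 - e^{-(x/\sigma)^c})^a}.
#'
#' @param x,q,p numeric vectors.
#' @param n sample size.
#' @param a,c_shape,scale positive parameters.
#' @param log,log.p,lower.tail usual conventions.
#' @return numeric vector.
#' @export
dexpweibull <- function(x, a, c_shape, scale = 1, log = FALSE) {
  z <- (x / scale)^c_shape
  ld <- log(a) + log(c_shape) - log(scale) + (c_shape - 1) * log(x / scale) -
    z + (a - 1) * log1p(-exp(-z))
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dexpweibull
#' @export
pexpweibull <- function(q, a, c_shape, scale = 1, lower.tail = TRUE, log.p = FALSE) {
  p <- (-expm1(-(pmax(q, 0) / scale)^c_shape))^a
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname dexpweibull
#' @export
qexpweibull <- function(p, a, c_shape, scale = 1) {
  scale * (-log1p(-p^(1 / a)))^(1 / c_shape)
}

#' @rdname dexpweibull
#' @export
rexpweibull <- function(n, a, c_shape, scale = 1) {
  qexpweibull(stats::runif(n), a, c_shape, scale)
}

#' Maximum-likelihood fit of an exponentiated-Weibull distribution
#'
#' Fits the three-parameter exponentiated Weibull (location fixed at 0) by
#' maximizing the log-likelihood over log-transformed parameters
#' (quasi-Newton, ordinary-Weibull starting values). The reported skewness
#' is the fitted distribution's third standardized moment, computed by
#' numerical integration of the quantile representation — i.e. the skewness
#' of the fitted curve, not of the empirical sample.
#'
#' @param pc_values sample of positive values (e.g. nodal PCs), size >= 30.
#' @return list with `shape_a`, `shape_c`, `scale`, `skewness`, `loglik`,
#'   `converged`.
#' @export
fit_exponentiated_weibull <- function(pc_values) {
  x <- pc_values[is.finite(pc_values)]
  if (length(x) < 30) stop("need at least 30 values", call. = FALSE)
  if (any(x <= 0)) stop("values must be positive", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate (constant) sample", call. = FALSE)
  start <- tryCatch({
    wb <- suppressWarnings(MASS::fitdistr(x, "weibull"))
    c(log_a = 0, log_c = log(unname(wb$estimate["shape"])),
      log_s = log(unname(wb$estimate["scale"])))
  }, error = function(e) c(log_a = 0, log_c = 0, log_s = log(mean(x))))
  nll <- function(par) {
    val <- -sum(dexpweibull(x, exp(par[1]), exp(par[2]), exp(par[3]), log = TRUE))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- exp(opt$par[[1]]); cc <- exp(opt$par[[2]]); s <- exp(opt$par[[3]])
  if (opt$convergence != 0) {
    warning("exponentiated-Weibull fit did not converge; see diagnostics", call. = FALSE)
  }
  list(shape_a = a, shape_c = cc, scale = s,
       skewness = expweibull_skewness(a, cc, s),
       loglik = -opt$value, converged = opt$convergence == 0)
}

# Third standardized moment of the fitted law, via the quantile
# representation E[X^k] = int_0^1 Q(u)^k du (numerically stable on (0,1)).
expweibull_skewness <- function(a, c_shape, scale) {
  mom <- function(k) {
    stats::integrate(function(u) qexpweibull(u, a, c_shape, scale)^k,
                     0, 1, rel.tol = 1e-10)$value
  }
  m1 <- mom(1); m2 <- mom(2); m3 <- mom(3)
  v <- m2 - m1^2
  (m3 - 3 * m1 * v - m1^3) / v^1.5
}

#' Group summaries of nodal participation coefficients
#'
#' Mean PC (with SEM) per group and timepoint for the hub list, the anti-hub
#' list and all nodes. Empty cells are flagged with a warning.
#'
#' @param pc_table table from [compute_node_pc()].
#' @param node_lists list from [rank_nodes_by_control_pc()].
#' @return data.frame with `group`, `timepoint`, `node_set`, `mean_pc`,
#'   `sem`, `n`.
#' @export
pc_group_summaries <- function(pc_table, node_lists) {
  sets <- list(top = node_lists$top, bottom = node_lists$bottom,
               all = unique(pc_table$node_id))
  out <- list()
  for (set_name in names(sets)) {
    sub <- pc_table[pc_table$node_id %in% sets[[set_name]], , drop = FALSE]
    cells <- unique(pc_table[, c("group", "timepoint")])
    for (i in seq_len(nrow(cells))) {
      v <- sub$pc[sub$group == cells$group[i] & sub$timepoint == cells$timepoint[i]]
      if (length(v) == 0) {
        warning(sprintf("empty cell: %s %s (%s nodes)", cells$group[i],
                        cells$timepoint[i], set_name), call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = cells$group[i], timepoint = cells$timepoint[i],
        node_set = set_name, mean_pc = mean(v),
        sem = stats::sd(v) / sqrt(length(v)), n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlate hub / anti-hub PC with resilience in patients
#'
#' For each metric of the battery and each node list, the per-(subject,
#' timepoint) mean PC over the list is paired with the subject-timepoint
#' mean normalized resilience, and the Spearman rank correlation is
#' computed over patients across all timepoints.
#'
#' @param pc_table from [compute_node_pc()].
#' @param battery an `attack_battery`.
#' @param node_lists from [rank_nodes_by_control_pc()].
#' @return data.frame with `node_set`, `metric`, `rho`, `p_value`, `n`.
#' @export
pc_resilience_correlations <- function(pc_table, battery, node_lists) {
  outc <- battery$outcomes
  pat <- outc[outc$group == "patient" & !outc$undefined, , drop = FALSE]
  res <- stats::aggregate(r_norm ~ subject_id + timepoint + metric, data = pat, FUN = mean)
  out <- list()
  for (set_name in c("top", "bottom")) {
    nodes <- node_lists[[set_name]]
    pcs <- pc_table[pc_table$group == "patient" & pc_table$node_id %in% nodes, ,
                    drop = FALSE]
    pc_mean <- stats::aggregate(pc ~ subject_id + timepoint, data = pcs, FUN = mean)
    for (m in unique(res$metric)) {
      sub <- merge(pc_mean, res[res$metric == m, ], by = c("subject_id", "timepoint"))
      rho <- spearman_corr(sub$pc, sub$r_norm)
      p <- tryCatch(
        suppressWarnings(stats::cor.test(sub$pc, sub$r_norm, method = "spearman")$p.value),
        error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        node_set = set_name, metric = m, rho = rho, p_value = p, n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
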