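#' Apply a virtual attack to a connectome
#'
#' Deletes the attack's regions from the matrix and records them in the
#' ledger with reason `"attack"`. Regions of the attack that were already
#' removed (dropout or primary lesion) are ignored and reported in the
#' `"ignored_regions"` attribute of the result.
#'
#' @param conn a [connectome].
#' @param attack a `lesion_region_set` (or character vector of region ids).
#' @return the attacked [connectome].
#' @export
apply_attack <- function(conn, attack) {
  stopifnot(inherits(conn, "connectome"))
  regions <- if (inherits(attack, "lesion_region_set")) attack$regions
             else as.character(attack)
  ignored <- intersect(regions, conn$removed_nodes$region_id)
  hit <- intersect(regions, conn$node_ids)
  if (length(hit) == 0) {
    out <- conn
  } else {
    keep <- !(conn$node_ids %in% hit)
    if (sum(keep) < 2) stop("attack would leave fewer than 2 nodes", call. = FALSE)
    out <- connectome(
      conn$weights[keep, keep, drop = FALSE], conn$node_ids[keep],
      rbind(conn$removed_nodes,
            data.frame(region_id = hit, reason = "attack", stringsAsFactors = FALSE))
    )
  }
  attr(out, "ignored_regions") <- ignored
  out
}

#' Raw resilience statistic
#'
#' `R(M) = M_pre - M_post`: positive when the attack degraded the metric.
#'
#' @param m_pre,m_post pre-/post-attack metric values (finite scalars).
#' @return their exact difference.
#' @export
resilience_raw <- function(m_pre, m_post) {
  stop_if_not_scalar_number(m_pre, "m_pre")
  stop_if_not_scalar_number(m_post, "m_post")
  m_pre - m_post
}

#' Normalized resilience statistic
#'
#' `R_norm = 1 - r_obs / mean(control_rs)`: the observed pre/post-attack
#' difference scaled by the average control difference. By construction the
#' control group averages 0, an undamaging attack yields 1, and larger
#' values mean more resilience. When the control mean is closer to zero
#' than `eps` the statistic is undefined: `NA` is returned with a warning
#' and callers exclude the outcome downstream.
#'
#' @param r_obs observed raw resilience.
#' @param control_rs non-empty vector of control raw resiliences.
#' @param eps guard on the denominator magnitude.
#' @return scalar `R_norm`, or `NA` if undefined.
#' @export
resilience_norm <- function(r_obs, control_rs, eps = 1e-9) {
  stop_if_not_scalar_number(r_obs, "r_obs")
  if (length(control_rs) == 0) stop("`control_rs` must be non-empty", call. = FALSE)
  denom <- mean(control_rs)
  if (!is.finite(denom) || abs(denom) < eps) {
    warning("control mean resilience is (near) zero; R_norm undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - r_obs / denom
}

# AUC of each requested metric for one connectome, sharing one density stack.
battery_aucs <- function(conn, metrics, partition, grid) {
  stack <- density_stack(conn, grid)
  vapply(metrics, function(m) {
    values <- vapply(stack, evaluate_metric, numeric(1),
                     metric_name = m, partition = partition)
    auc_of_curve(list(grid = grid, values = unname(values)))
  }, numeric(1))
}

#' Run the virtual-attack battery over a cohort
#'
#' For every subject, timepoint and lesion mask: computes the pre-attack AUC
#' metrics once per subject-timepoint (patients after exclusion of their
#' primary-lesion regions), applies the attack, recomputes the AUCs and
#' emits the raw resilience `R = M_pre - M_post`. An attack is skipped for a
#' subject iff its region set is entirely contained in that subject's
#' already-removed regions (it "fell within" the primary stroke); partial
#' overlaps proceed on the remaining regions. After all raw values,
#' normalized resilience is computed against the control outcomes at the
#' reference timepoint: per attack (default; denominator = mean control R
#' for that mask) or pooled (grand control mean). Controls enter the outcome
#' table at the reference timepoint only.
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `subjects`
#'   (data.frame with `subject_id`, `group`, `timepoint`,
#'   `primary_removed_regions`), `connectomes` (named
#'   `subject_id.timepoint`), `partition` and `lesion_library`.
#' @param metrics metric names from [metric_curve()]; default the three
#'   whole-brain resilience metrics.
#' @param normalization `"per_attack"` or `"pooled"`.
#' @param grid density grid.
#' @param control_timepoint reference timepoint for normalization.
#' @param eps denominator guard passed to the normalization.
#' @return an object of class `attack_battery`: list with `outcomes` (one
#'   row per subject x timepoint x mask x metric), `skip_log`,
#'   `denominators` and the configuration.
#' @export
run_attack_battery <- function(cohort,
                               metrics = c("global_efficiency", "modularity", "clustering"),
                               normalization = c("per_attack", "pooled"),
                               grid = default_density_grid(),
                               control_timepoint = "TP1",
                               eps = 1e-9) {
  normalization <- match.arg(normalization)
  metrics <- vapply(metrics, match.arg, character(1), choices = metric_names())
  subjects <- cohort$subjects
  if (!any(subjects$group == "control")) {
    stop("attack battery needs control subjects as normalization reference", call. = FALSE)
  }
  partition <- cohort$partition
  library <- cohort$lesion_library
  prim <- lapply(stats::setNames(subjects$primary_removed_regions, subjects$subject_id),
                 function(s) if (is.na(s) || !nzchar(s)) character(0)
                             else strsplit(s, ",", fixed = TRUE)[[1]])

  keep_row <- subjects$group == "patient" |
    (subjects$group == "control" & subjects$timepoint == control_timepoint)
  sub_use <- subjects[keep_row, , drop = FALSE]

  rows <- vector("list", nrow(sub_use) * length(library))
  skips <- list()
  ri <- 0L
  for (si in seq_len(nrow(sub_use))) {
    sid <- sub_use$subject_id[si]
    tp <- sub_use$timepoint[si]
    key <- paste0(sid, ".", tp)
    conn <- cohort$connectomes[[key]]
    if (is.null(conn)) stop(sprintf("missing connectome for %s", key), call. = FALSE)
    primary <- prim[[sid]]
    if (length(primary) > 0) {
      conn <- exclude_regions(conn, primary_lesioned = primary)
    }
    removed <- conn$removed_nodes$region_id
    pre <- battery_aucs(conn, metrics, partition, grid)
    for (mask in library) {
      if (all(mask$regions %in% removed)) {
        skips[[length(skips) + 1L]] <- data.frame(
          subject_id = sid, timepoint = tp, mask_id = mask$mask_id,
          reason = "attack within already-removed regions",
          stringsAsFactors = FALSE)
        next
      }
      post <- battery_aucs(apply_attack(conn, mask), metrics, partition, grid)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subject_id = sid, group = sub_use$group[si], timepoint = tp,
        mask_id = mask$mask_id,
        n_removed = length(intersect(mask$regions, conn$node_ids)),
        metric = metrics, m_pre = unname(pre), m_post = unname(post),
        r_raw = unname(pre - post), stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, rows[seq_len(ri)])
  rownames(outcomes) <- NULL

  ctl <- outcomes[outcomes$group == "control", , drop = FALSE]
  if (normalization == "per_attack") {
    denom <- stats::aggregate(r_raw ~ mask_id + metric, data = ctl, FUN = mean)
    names(denom)[names(denom) == "r_raw"] <- "denominator"
    key_out <- paste(outcomes$mask_id, outcomes$metric)
    outcomes$denominator <- denom$denominator[match(key_out,
                                                    paste(denom$mask_id, denom$metric))]
  } else {
    denom <- stats::aggregate(r_raw ~ metric, data = ctl, FUN = mean)
    names(denom)[names(denom) == "r_raw"] <- "denominator"
    outcomes$denominator <- denom$denominator[match(outcomes$metric, denom$metric)]
  }
  outcomes$undefined <- !is.finite(outcomes$denominator) |
    abs(outcomes$denominator) < eps
  outcomes$r_norm <- ifelse(outcomes$undefined, NA_real_,
                            1 - outcomes$r_raw / outcomes$denominator)

  structure(
    list(outcomes = outcomes,
         skip_log = if (length(skips)) do.call(rbind, skips)
                    else data.frame(subject_id = character(0), timepoint = character(0),
                                    mask_id = character(0), reason = character(0)),
         denominators = denom,
         normalization = normalization, metrics = metrics,
         control_timepoint = control_timepoint, grid = grid),
    class = "attack_battery"
  )
}

#' @exportS3Method base::print
print.attack_battery <- function(x, ...) {
  cat(sprintf("<attack_battery> %d outcome rows (%s normalization), %d skips, %d undefined\n",
              nrow(x$outcomes), x$normalization, nrow(x$skip_log),
              sum(x$outcomes$undefined)))
  invisible(x)
}

#' Pre-attack baseline AUC metrics per subject and timepoint
#'
#' @inheritParams run_attack_battery
#' @return data.frame with one row per subject x timepoint x metric.
#' @export
baseline_metrics <- function(cohort,
                             metrics = c("global_efficiency", "modularity", "clustering"),
                             grid = default_density_grid()) {
  metrics <- vapply(metrics, match.arg, character(1), choices = metric_names())
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
    aucs <- battery_aucs(conn, metrics, cohort$partition, grid)
    data.frame(subject_id = sid, group = subjects$group[si], timepoint = tp,
               metric = metrics, auc = unname(aucs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
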