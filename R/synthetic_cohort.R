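#' Specification of a synthetic cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. An identical spec
#' (including the seed) always yields a bit-identical cohort. Defaults mirror
#' the study design the generator emulates: 75 patients over three
#' timepoints (a fifth of whom lack the 1-year timepoint), 18 controls over
#' two timepoints, 246-region connectomes partitioned into 17 modules, and a
#' 122-mask virtual-lesion library whose sizes follow a discretized
#' log-normal law with median 6 regions.
#'
#' `hub_concentration_*` (kappa) is the hub-load redistribution strength of
#' [simulate_connectome()]: the fraction kappa / (1 + kappa) of each hub's
#' extra inter-module weight is moved off the hub and spread over the
#' between-module connections of non-hub nodes (weight-preserving). Setting
#' the patient kappa above the control kappa injects the post-stroke
#' redistribution the downstream analyses are designed to detect: lower hub
#' PC, higher anti-hub PC and greater attack resilience in patients.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param timepoints_patients,timepoints_controls timepoint labels.
#' @param n_nodes,n_modules connectome size and module count.
#' @param mu_within,mu_between mean edge weight inside / between modules,
#'   each in `[0, 1)`.
#' @param noise_sd SD of the Gaussian edge-weight noise.
#' @param hub_fraction fraction of nodes designated hubs.
#' @param hub_boost extra between-module weight per hub connection (see
#'   [simulate_connectome()]).
#' @param hub_concentration_control,hub_concentration_patient kappa >= 0.
#' @param lesion_count number of masks in the virtual-lesion library.
#' @param lesion_size_params list with `meanlog`, `sdlog` of the discretized
#'   log-normal lesion-size law.
#' @param missing_tp3_fraction fraction of patients lacking the last
#'   timepoint (applied when patients have 3 timepoints).
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 75, n_controls = 18,
                        timepoints_patients = c("TP1", "TP2", "TP3"),
                        timepoints_controls = c("TP1", "TP2"),
                        n_nodes = 246, n_modules = 17,
                        mu_within = 0.5, mu_between = 0.2, noise_sd = 0.1,
                        hub_fraction = 0.2, hub_boost = 0.2,
                        hub_concentration_control = 0,
                        hub_concentration_patient = 3,
                        lesion_count = 122,
                        lesion_size_params = default_lesion_size_params(),
                        missing_tp3_fraction = 0.2,
                        seed = 1L) {
  if (mu_within < 0 || mu_within >= 1 || mu_between < 0 || mu_between >= 1) {
    stop("`mu_within` and `mu_between` must lie in [0, 1)", call. = FALSE)
  }
  if (n_modules > n_nodes) stop("`n_modules` must not exceed `n_nodes`", call. = FALSE)
  if (hub_concentration_control < 0 || hub_concentration_patient < 0) {
    stop("hub concentrations (kappa) must be >= 0", call. = FALSE)
  }
  if (hub_fraction < 0 || hub_fraction > 1) {
    stop("`hub_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
         timepoints_patients = as.character(timepoints_patients),
         timepoints_controls = as.character(timepoints_controls),
         n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
         mu_within = mu_within, mu_between = mu_between, noise_sd = noise_sd,
         hub_fraction = hub_fraction, hub_boost = hub_boost,
         hub_concentration_control = hub_concentration_control,
         hub_concentration_patient = hub_concentration_patient,
         lesion_count = as.integer(lesion_count),
         lesion_size_params = lesion_size_params,
         missing_tp3_fraction = missing_tp3_fraction,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_lesion_size_params <- function() {
  # median 6 regions per mask; sdlog chosen so the continuous quartiles
  # (~3.3 and ~11.0) sit inside the interquartile bracket [2, 11]
  list(meanlog = log(6), sdlog = 0.9)
}

#' Deterministic a-priori module partition
#'
#' Assigns `n_nodes` nodes to `n_modules` modules of near-equal size, with
#' module membership shuffled by the seed. Every module is non-empty.
#'
#' @param n_nodes,n_modules counts, `1 <= n_modules <= n_nodes`.
#' @param seed integer seed.
#' @return a [module_partition] over nodes `R001 ... R<n>`.
#' @export
make_partition <- function(n_nodes, n_modules, seed = 1L) {
  if (n_modules < 1 || n_modules > n_nodes) {
    stop("need 1 <= n_modules <= n_nodes", call. = FALSE)
  }
  nodes <- node_labels(n_nodes)
  base <- rep(seq_len(n_modules), length.out = n_nodes)
  mem <- with_seed(seed, sample(base))
  module_partition(stats::setNames(as.integer(mem), nodes))
}

node_labels <- function(n_nodes) {
  sprintf("R%0*d", max(3L, nchar(as.character(n_nodes))), seq_len(n_nodes))
}

#' Simulate a modular weighted connectome
#'
#' Generates a symmetric correlation-like weight matrix with unit diagonal.
#' The base structure is a block model on the partition (mean weight
#' `mu_within` inside modules, `mu_between` between) plus Gaussian edge
#' noise. Designated hub nodes additionally receive `hub_boost` extra weight
#' on every between-module connection, which concentrates the network's
#' inter-module integration on the hubs and gives them the highest
#' participation coefficients.
#'
#' `hub_concentration` (kappa >= 0) is the strength of hub-load
#' redistribution: the fraction `kappa / (1 + kappa)` of each hub's extra
#' inter-module mass is taken off the hub and spread uniformly over the
#' between-module connections among non-hub nodes. Total connectivity mass
#' is preserved, so the whole-network mean participation coefficient barely
#' moves, but as kappa grows hub PC falls, non-hub (anti-hub) PC rises, and
#' inter-module integration spreads over many redundant paths instead of a
#' few vulnerable hubs — the architecture change probed by the attack
#' battery.
#'
#' @param partition a [module_partition].
#' @param mu_within,mu_between mean within-/between-module weight in `[0, 1)`.
#' @param hub_nodes character vector of hub node ids (subset of partition).
#' @param hub_concentration kappa >= 0; redistribution strength.
#' @param noise_sd SD of edge-weight noise.
#' @param hub_boost extra between-module weight carried by each hub before
#'   redistribution.
#' @param seed integer seed.
#' @return a [connectome]; off-diagonal weights clipped to `[-1, 1]`.
#' @export
simulate_connectome <- function(partition, mu_within = 0.5, mu_between = 0.2,
                                hub_nodes = character(0), hub_concentration = 0,
                                noise_sd = 0.1, hub_boost = 0.2, seed = 1L) {
  stopifnot(inherits(partition, "module_partition"))
  if (mu_within < 0 || mu_within >= 1 || mu_between < 0 || mu_between >= 1) {
    stop("`mu_within` and `mu_between` must lie in [0, 1)", call. = FALSE)
  }
  if (hub_concentration < 0) stop("`hub_concentration` must be >= 0", call. = FALSE)
  nodes <- names(partition)
  n <- length(nodes)
  if (n < 2) stop("partition must cover at least 2 nodes", call. = FALSE)
  hub_nodes <- as.character(hub_nodes)
  if (!all(hub_nodes %in% nodes)) stop("hub nodes must belong to the partition", call. = FALSE)
  mem <- unclass(partition)
  same <- outer(mem, mem, "==")
  w <- matrix(mu_between, n, n)
  w[same] <- mu_within
  if (length(hub_nodes) > 0 && hub_boost != 0) {
    is_hub <- nodes %in% hub_nodes
    g <- hub_concentration / (1 + hub_concentration)
    hub_edge <- !same & outer(is_hub, is_hub, "|") # between-module, >= 1 hub end
    nb_edge <- !same & !outer(is_hub, is_hub, "|") # between-module, no hub end
    # hubs keep (1 - g) of their extra inter-module weight; the removed mass
    # is spread uniformly over the non-hub between-module edges
    w[hub_edge] <- w[hub_edge] + hub_boost * (1 - g)
    n_hub_edges <- sum(hub_edge) / 2
    n_nb_edges <- sum(nb_edge) / 2
    if (g > 0 && n_nb_edges > 0) {
      w[nb_edge] <- w[nb_edge] + hub_boost * g * n_hub_edges / n_nb_edges
    }
  }
  noise <- with_seed(seed, {
    z <- matrix(0, n, n)
    z[upper.tri(z)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
    z + t(z)
  })
  w <- w + noise
  w <- pmin(pmax(w, -1), 1)
  diag(w) <- 1
  connectome(w, nodes)
}

#' Simulate BOLD-like region time series from a connectome
#'
#' Draws Gaussian series whose population correlation equals the connectome's
#' weight matrix (projected to the nearest well-conditioned correlation
#' matrix by eigenvalue clipping), then injects slow scanner-like drift and
#' outlying motion-like spikes so the preprocessing stages have realistic
#' work to do. Synthetic nuisance regressors (drift basis and spike
#' indicator) are attached for [detrend_and_regress()].
#'
#' @param conn a [connectome].
#' @param n_volumes number of volumes (>= 10).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param drift_amp amplitude of the slow drift relative to unit signal SD.
#' @param spike_rate expected spikes per volume (e.g. 0.02).
#' @param seed integer seed.
#' @return a [region_ts] with the nuisance block attached and the realized
#'   target correlation matrix in attribute `"target_cor"`.
#' @export
simulate_timeseries <- function(conn, n_volumes = 400, tr_seconds = 2,
                                drift_amp = 1, spike_rate = 0.02, seed = 1L) {
  stopifnot(inherits(conn, "connectome"))
  if (tr_seconds <= 0) stop("TR must be positive", call. = FALSE)
  if (n_volumes < 10) stop("`n_volumes` must be >= 10", call. = FALSE)
  n <- length(conn$node_ids)
  target <- nearest_correlation(conn$weights)
  ch <- chol(target)
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n)
    x <- t(z %*% ch) # regions x time, unit variance, correlation = target
    tt <- seq_len(n_volumes)
    # the linear component is left to detrending; only the slow oscillation
    # and the spike indicator are returned as nuisance regressors
    drift_basis <- cbind(
      linear = tt / n_volumes,
      slow = cos(2 * pi * tt / n_volumes)
    )
    spikes <- as.numeric(stats::runif(n_volumes) < spike_rate)
    if (drift_amp > 0) {
      coef <- matrix(stats::rnorm(n * ncol(drift_basis), sd = drift_amp), n)
      x <- x + coef %*% t(drift_basis)
    }
    if (any(spikes > 0)) {
      load <- stats::rnorm(n, mean = 4, sd = 1)
      x <- x + load %*% t(spikes)
    }
    list(x = x, nuis = cbind(slow = drift_basis[, "slow"], spike = spikes))
  })
  ts <- region_ts(out$x, conn$node_ids, tr_seconds, nuisance = out$nuis)
  attr(ts, "target_cor") <- target
  ts
}

# Nearest well-conditioned correlation matrix by eigenvalue clipping.
nearest_correlation <- function(w, eps = 1e-6) {
  e <- eigen((w + t(w)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  m <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(m)
}

#' Simulate a virtual-lesion library
#'
#' Draws `n_masks` lesioned-region sets over the partition's nodes. Mask
#' sizes follow a discretized log-normal law (default median 6 regions)
#' truncated to `[1, ceiling(0.2 n_nodes)]`; regions are sampled with
#' preference for the seed region's module (`affinity`-fold weight), to
#' mimic the spatial clustering of vascular territories.
#'
#' @param partition a [module_partition] giving the available regions and
#'   their modules.
#' @param n_masks number of masks (>= 1).
#' @param size_params list with `meanlog` and `sdlog`.
#' @param affinity preference weight for same-module regions (>= 1).
#' @param seed integer seed.
#' @return list of `lesion_region_set` objects (source `"synthetic"`).
#' @export
simulate_lesion_library <- function(partition, n_masks = 122,
                                    size_params = default_lesion_size_params(),
                                    affinity = 4, seed = 1L) {
  stopifnot(inherits(partition, "module_partition"))
  if (n_masks < 1) stop("`n_masks` must be >= 1", call. = FALSE)
  nodes <- names(partition)
  mem <- unclass(partition)
  n <- length(nodes)
  max_size <- max(1L, ceiling(0.2 * n))
  min_possible <- 1
  if (size_params$sdlog == 0 && round(exp(size_params$meanlog)) > n) {
    stop("requested lesion size exceeds available regions", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_masks), function(i) {
      size <- draw_truncated_size(size_params, max_size)
      seed_region <- sample.int(n, 1)
      m0 <- mem[seed_region]
      chosen <- seed_region
      while (length(chosen) < size) {
        pool <- setdiff(seq_len(n), chosen)
        wgt <- ifelse(mem[pool] == m0, affinity, 1)
        chosen <- c(chosen, pool[sample.int(length(pool), 1, prob = wgt)])
      }
      lesion_region_set(sprintf("vmask%03d", i), nodes[sort(chosen)],
                        source = "synthetic")
    })
  })
}

draw_truncated_size <- function(size_params, max_size, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    s <- round(stats::rlnorm(1, size_params$meanlog, size_params$sdlog))
    if (s >= 1 && s <= max_size) return(as.integer(s))
  }
  stop("could not draw a lesion size inside [1, max]; check `size_params`",
       call. = FALSE)
}

#' Build a full synthetic cohort
#'
#' Assembles everything the downstream pipeline needs: a module partition, a
#' designated hub set (shared by all subjects), one weighted connectome per
#' subject and timepoint (controls with the control kappa, patients with the
#' patient kappa), a virtual-lesion library, and a subject table with
#' clinical-style covariates. Each patient's primary lesion is drawn from
#' the library and its regions recorded in `primary_removed_regions`
#' (comma-separated in the table); controls carry no lesion fields.
#'
#' Covariate laws (documented defaults, overridable by editing the returned
#' table): age ~ Normal(53, 9) years; NIHSS ~ negative binomial with mean 6
#' (SD about 6), truncated to `[0, 42]`; lesion size log-normal with mean
#' about 29 cm^3; lesion type 85% ischaemic; location frequencies matching a
#' mixed clinical case list. When patients have three timepoints, a
#' `missing_tp3_fraction` share of them lacks the last one.
#'
#' @param spec a [cohort_spec].
#' @return an object of class `synthetic_cohort`: list with `spec`,
#'   `partition`, `hub_nodes`, `subjects` (one row per subject x timepoint),
#'   `connectomes` (named `subject_id.timepoint`), and `lesion_library`.
#' @export
build_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  partition <- make_partition(spec$n_nodes, spec$n_modules,
                              derive_seed(spec$seed, "partition"))
  nodes <- names(partition)
  n_hubs <- max(1L, round(spec$hub_fraction * spec$n_nodes))
  hub_nodes <- with_seed(derive_seed(spec$seed, "hubs"),
                         sort(sample(nodes, n_hubs)))
  library <- simulate_lesion_library(partition, spec$lesion_count,
                                     spec$lesion_size_params,
                                     seed = derive_seed(spec$seed, "lesions"))

  ids_pat <- sprintf("P%03d", seq_len(spec$n_patients))
  ids_ctl <- sprintf("C%03d", seq_len(spec$n_controls))

  covars <- with_seed(derive_seed(spec$seed, "covariates"), {
    n_p <- spec$n_patients
    lose_tp3 <- logical(n_p)
    if (length(spec$timepoints_patients) >= 3 && spec$missing_tp3_fraction > 0) {
      k <- round(spec$missing_tp3_fraction * n_p)
      lose_tp3[sample.int(n_p, k)] <- TRUE
    }
    list(
      age_p = round(stats::rnorm(n_p, 53, 9)),
      age_c = round(stats::rnorm(spec$n_controls, 55, 9)),
      sex_p = sample(c("male", "female"), n_p, TRUE, prob = c(0.57, 0.43)),
      sex_c = sample(c("male", "female"), spec$n_controls, TRUE, prob = c(0.45, 0.55)),
      nihss = pmin(stats::rnbinom(n_p, size = 1.5, mu = 6), 42L),
      lesion_size = round(stats::rlnorm(n_p, meanlog = log(29) - 1.289 / 2,
                                        sdlog = sqrt(1.289)), 1),
      lesion_type = sample(c("ischaemic", "haemorrhagic"), n_p, TRUE,
                           prob = c(0.85, 0.15)),
      lesion_location = sample(
        c("subcortical", "cortical", "cortico-subcortical", "white matter",
          "brainstem", "cerebellum"),
        n_p, TRUE, prob = c(13, 27, 15, 5, 9, 6) / 75),
      primary_idx = sample.int(length(library), n_p, replace = TRUE),
      lose_tp3 = lose_tp3
    )
  })

  subject_rows <- list()
  connectomes <- list()
  add_subject <- function(sid, group, tps, kappa, row_extra) {
    for (tp in tps) {
      conn <- simulate_connectome(
        partition, spec$mu_within, spec$mu_between,
        hub_nodes = hub_nodes, hub_concentration = kappa,
        noise_sd = spec$noise_sd, hub_boost = spec$hub_boost,
        seed = derive_seed(spec$seed, paste0("conn.", sid, ".", tp))
      )
      connectomes[[paste0(sid, ".", tp)]] <<- conn
      subject_rows[[length(subject_rows) + 1L]] <<- cbind(
        data.frame(subject_id = sid, group = group, timepoint = tp,
                   stringsAsFactors = FALSE),
        row_extra
      )
    }
  }

  for (i in seq_len(spec$n_patients)) {
    tps <- spec$timepoints_patients
    if (covars$lose_tp3[i] && length(tps) >= 3) tps <- tps[-length(tps)]
    primary <- library[[covars$primary_idx[i]]]$regions
    add_subject(ids_pat[i], "patient", tps, spec$hub_concentration_patient,
                data.frame(age = covars$age_p[i], sex = covars$sex_p[i],
                           nihss = as.integer(covars$nihss[i]),
                           lesion_size = covars$lesion_size[i],
                           lesion_type = covars$lesion_type[i],
                           lesion_location = covars$lesion_location[i],
                           primary_removed_regions = paste(primary, collapse = ","),
                           stringsAsFactors = FALSE))
  }
  for (i in seq_len(spec$n_controls)) {
    add_subject(ids_ctl[i], "control", spec$timepoints_controls,
                spec$hub_concentration_control,
                data.frame(age = covars$age_c[i], sex = covars$sex_c[i],
                           nihss = NA_integer_, lesion_size = NA_real_,
                           lesion_type = NA_character_,
                           lesion_location = NA_character_,
                           primary_removed_regions = "",
                           stringsAsFactors = FALSE))
  }

  structure(
    list(spec = spec, partition = partition, hub_nodes = hub_nodes,
         subjects = do.call(rbind, subject_rows), connectomes = connectomes,
         lesion_library = library),
    class = "synthetic_cohort"
  )
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients + %d controls, %d connectomes (%d nodes, %d modules), %d lesion masks\n",
    x$spec$n_patients, x$spec$n_controls, length(x$connectomes),
    x$spec$n_nodes, x$spec$n_modules, length(x$lesion_library)))
  invisible(x)
}

#' Primary lesioned regions of every subject
#'
#' @param cohort a `synthetic_cohort`.
#' @return named list (by subject id) of character vectors.
#' @export
primary_regions <- function(cohort) {
  sub <- cohort$subjects[!duplicated(cohort$subjects$subject_id), ]
  out <- lapply(sub$primary_removed_regions, function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  stats::setNames(out, sub$subject_id)
}
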