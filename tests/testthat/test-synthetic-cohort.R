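test_that("partitions cover all nodes, keep modules non-empty and respect the seed", {
  p1 <- make_partition(4, 1, 3)
  expect_true(all(unclass(p1) == 1))

  p <- make_partition(246, 17, 5)
  expect_length(p, 246)
  expect_equal(length(unique(unclass(p))), 17)
  expect_true(all(table(unclass(p)) >= 1))

  expect_identical(make_partition(6, 3, 42), make_partition(6, 3, 42))
  expect_false(identical(make_partition(6, 3, 1), make_partition(6, 3, 2)))
  expect_error(make_partition(3, 5), "n_modules")
})

test_that("simulated connectomes are symmetric correlation-like matrices", {
  part <- make_partition(30, 3, 1)
  conn <- simulate_connectome(part, 0.6, 0.1, seed = 9)
  expect_equal(conn$weights, t(conn$weights))
  expect_equal(unname(diag(conn$weights)), rep(1, 30))
  expect_true(all(abs(conn$weights) <= 1))
  expect_identical(simulate_connectome(part, 0.6, 0.1, seed = 9)$weights, conn$weights)
  expect_error(simulate_connectome(part, 1.2, 0.1), "mu_within")
  expect_error(
    simulate_connectome(part, 0.5, 0.2, hub_nodes = "nope", hub_concentration = 1),
    "hub nodes")
})

test_that("equal within/between weights give unstructured (near-zero) modularity", {
  part <- make_partition(24, 3, 2)
  mem <- unclass(part)
  qs <- vapply(1:60, function(s) {
    conn <- simulate_connectome(part, 0.3, 0.3, noise_sd = 0.1, seed = s)
    g <- proportional_binarize(conn, 0.2)
    oracle_modularity(g$adjacency, mem)
  }, numeric(1))
  # oracle: uniform random graphs with the same size and edge count; at this
  # finite size the expected fixed-partition Q sits slightly below 0
  set.seed(404)
  q_unif <- vapply(1:200, function(i) {
    a <- matrix(0, 24, 24)
    a[sample(which(upper.tri(a)), 55)] <- 1
    oracle_modularity(a + t(a), mem)
  }, numeric(1))
  expect_lt(abs(mean(qs) - mean(q_unif)), 0.02)
  expect_lt(abs(mean(qs)), 0.05)
})

test_that("modular weights beat degree-preserving rewired nulls on modularity", {
  part <- make_partition(30, 3, 4)
  conn <- simulate_connectome(part, 0.8, 0.1, noise_sd = 0.05, seed = 6)
  g <- proportional_binarize(conn, 0.2)
  q_obs <- modularity_fixed(g, part)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  set.seed(77)
  q_null <- vapply(1:30, function(i) {
    rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = 500))
    oracle_modularity(as.matrix(igraph::as_adjacency_matrix(rw)), unclass(part))
  }, numeric(1))
  expect_gt(q_obs, mean(q_null))
})

test_that("redistribution strength moves PC off hubs and onto non-hubs, monotonically", {
  part <- make_partition(60, 6, 8)
  hubs <- names(part)[seq(1, 60, by = 5)] # 12 hubs (default hub fraction)
  nonhubs <- setdiff(names(part), hubs)
  grid <- default_density_grid()
  pc_auc <- function(kappa, nodes) {
    mean(vapply(1:5, function(s) {
      conn <- simulate_connectome(part, hub_nodes = hubs, hub_concentration = kappa,
                                  seed = 100 + s)
      stack <- density_stack(conn, grid)
      vals <- vapply(stack, function(g) mean(participation(g, part)[nodes]), numeric(1))
      auc_of_curve(list(grid = grid, values = unname(vals)))
    }, numeric(1)))
  }
  kappas <- c(0, 0.5, 1, 2)
  hub_pc <- vapply(kappas, pc_auc, numeric(1), nodes = hubs)
  non_pc <- vapply(kappas, pc_auc, numeric(1), nodes = nonhubs)
  # hubs lose participation monotonically; the rest of the network ends up
  # with more than it started with (non-hub PC first dips slightly because
  # non-hub edges *onto* hubs weaken before the redistributed mass dominates)
  expect_true(all(diff(hub_pc) <= 1e-6))
  expect_gt(non_pc[4], non_pc[1])
  expect_true(all(diff(non_pc[2:4]) >= -1e-6))
  # at kappa = 0 the designated hubs are the clear PC leaders
  expect_gt(hub_pc[1], non_pc[1] + 0.05)
})

test_that("redistribution preserves total connectivity mass", {
  part <- make_partition(40, 4, 2)
  hubs <- names(part)[1:4]
  mass <- vapply(c(0, 1, 3), function(kappa) {
    conn <- simulate_connectome(part, hub_nodes = hubs, hub_concentration = kappa,
                                noise_sd = 0, seed = 1)
    sum(conn$weights) - 40 # off-diagonal mass
  }, numeric(1))
  expect_equal(mass[1], mass[2], tolerance = 1e-10)
  expect_equal(mass[1], mass[3], tolerance = 1e-10)
})

test_that("simulated time series converge to the target correlation", {
  part <- make_partition(12, 3, 3)
  conn <- simulate_connectome(part, 0.5, 0.15, seed = 5)
  ts <- simulate_timeseries(conn, n_volumes = 10000, drift_amp = 0, spike_rate = 0,
                            seed = 10)
  target <- attr(ts, "target_cor")
  emp <- cor(t(ts$samples))
  expect_lt(max(abs(emp - target)), 0.05)
  # identity connectome -> independent series
  id <- connectome(diag(12), paste0("R", 1:12))
  ts0 <- simulate_timeseries(id, n_volumes = 8000, drift_amp = 0, spike_rate = 0,
                             seed = 2)
  emp0 <- cor(t(ts0$samples))
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.05)
  # determinism + RNG hygiene
  a <- simulate_timeseries(conn, 50, seed = 3)
  b <- simulate_timeseries(conn, 50, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_error(simulate_timeseries(conn, 50, tr_seconds = 0), "TR")
  expect_error(simulate_timeseries(conn, 5), "n_volumes")
})

test_that("drift and spikes are injected and recoverable by preprocessing", {
  part <- make_partition(8, 2, 1)
  conn <- simulate_connectome(part, 0.5, 0.2, seed = 4)
  ts <- simulate_timeseries(conn, n_volumes = 256, drift_amp = 3, spike_rate = 0.05,
                            seed = 7)
  expect_equal(nrow(ts$nuisance), 256)
  # slow oscillation + spike indicator; the linear part is left to detrending
  expect_equal(colnames(ts$nuisance), c("slow", "spike"))
  clean <- detrend_and_regress(ts)
  # nuisance removal shrinks the variance inflated by drift/spikes
  expect_lt(mean(apply(clean$samples, 1, var)), mean(apply(ts$samples, 1, var)))
})

test_that("lesion libraries hit the documented size law", {
  part <- make_partition(246, 17, 1)
  lib <- simulate_lesion_library(part, 2000, seed = 2)
  sizes <- lengths(lapply(lib, function(l) l$regions))
  expect_equal(median(sizes), 6)
  expect_true(all(sizes >= 1 & sizes <= ceiling(0.2 * 246)))
  q <- unname(quantile(sizes, c(0.25, 0.75)))
  expect_gte(q[1], 2); expect_lte(q[2], 11)

  ones <- simulate_lesion_library(part, 50,
                                  size_params = list(meanlog = 0, sdlog = 0), seed = 3)
  expect_true(all(lengths(lapply(ones, `[[`, "regions")) == 1))
  expect_error(
    simulate_lesion_library(make_partition(5, 2, 1), 3,
                            size_params = list(meanlog = log(50), sdlog = 0)),
    "exceeds")
  l1 <- simulate_lesion_library(part, 20, seed = 9)
  l2 <- simulate_lesion_library(part, 20, seed = 9)
  expect_identical(l1, l2)
})

test_that("lesion masks cluster within modules", {
  part <- make_partition(120, 6, 3)
  lib <- simulate_lesion_library(part, 300, seed = 5)
  mem <- unclass(part)
  # fraction of each mask in its dominant module, versus the chance level 1/6
  share <- vapply(lib, function(l) {
    mods <- mem[l$regions]
    max(table(mods)) / length(mods)
  }, numeric(1))
  sizes <- lengths(lapply(lib, `[[`, "regions"))
  expect_gt(mean(share[sizes >= 4]), 0.4)
})

test_that("cohorts have the requested structure and are bit-identical under a seed", {
  spec <- tiny_cohort_spec()
  coh <- build_cohort(spec)
  subj <- coh$subjects
  expect_equal(length(unique(subj$subject_id[subj$group == "patient"])), 3)
  expect_equal(length(unique(subj$subject_id[subj$group == "control"])), 4)
  expect_length(coh$connectomes, 3 * 2 + 4 * 2)
  expect_length(coh$lesion_library, 8)

  ctl <- subj[subj$group == "control", ]
  expect_true(all(ctl$primary_removed_regions == ""))
  expect_true(all(is.na(ctl$nihss)))
  pat <- subj[subj$group == "patient", ]
  expect_true(all(nzchar(pat$primary_removed_regions)))
  expect_true(all(pat$nihss >= 0 & pat$nihss <= 42))
  expect_true(all(pat$lesion_location %in%
    c("subcortical", "cortical", "cortico-subcortical", "white matter",
      "brainstem", "cerebellum")))

  coh2 <- build_cohort(tiny_cohort_spec())
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$connectomes, coh2$connectomes)
})

test_that("a fifth of three-timepoint patients lack the final timepoint", {
  spec <- tiny_cohort_spec(n_patients = 20,
                           timepoints_patients = c("TP1", "TP2", "TP3"))
  coh <- build_cohort(spec)
  tp3 <- coh$subjects[coh$subjects$timepoint == "TP3", ]
  expect_equal(nrow(tp3), 16) # 20 - round(0.2 * 20)
})

test_that("cohorts round-trip to a directory of delimited files", {
  coh <- build_cohort(tiny_cohort_spec())
  dir <- file.path(tempdir(), "cohort-out")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  part <- read_partition(file.path(dir, "partition.tsv"))
  expect_identical(unclass(part), unclass(coh$partition))
  lib <- read_lesion_library(file.path(dir, "lesions.txt"))
  expect_equal(lib[[1]]$regions, coh$lesion_library[[1]]$regions)
  key <- names(coh$connectomes)[1]
  conn <- read_connectome(file.path(dir, "connectomes", paste0(key, ".tsv")))
  expect_equal(conn$weights, coh$connectomes[[key]]$weights, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
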