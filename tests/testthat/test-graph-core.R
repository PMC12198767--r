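test_that("positive threshold zeroes exactly the non-positive weights", {
  w <- rbind(c(1, 0.5, -0.3), c(0.5, 1, 0), c(-0.3, 0, 1))
  conn <- connectome(w, c("a", "b", "c"))
  out <- positive_threshold(conn)
  expect_equal(out$weights["a", "b"], 0.5)
  expect_equal(out$weights["a", "c"], 0)
  expect_equal(out$weights["b", "c"], 0)

  allneg <- connectome(diag(3) * 2 - 1 + diag(0, 3), c("a", "b", "c"))
  expect_equal(sum(positive_threshold(allneg)$weights) - 3, 0)

  allpos <- connectome(matrix(0.4, 3, 3) + diag(0.6, 3), c("a", "b", "c"))
  expect_equal(positive_threshold(allpos)$weights, allpos$weights)
})

test_that("proportional binarization keeps the strongest edges", {
  w <- diag(4)
  vals <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1)
  w[upper.tri(w)] <- vals
  w <- w + t(w) - diag(diag(w))
  conn <- connectome(w)
  # upper triangle fills column-major: 0.9 (1-2), 0.7 (1-3), 0.5 (2-3),
  # 0.3 (1-4), 0.2 (2-4), 0.1 (3-4); delta 0.5 keeps the 3 strongest
  g <- proportional_binarize(conn, 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)
  expect_equal(unname(c(g$adjacency[1, 2], g$adjacency[1, 3], g$adjacency[2, 3])),
               c(1, 1, 1))
  expect_equal(unname(g$adjacency[, 4]), c(0, 0, 0, 0))
  expect_equal(sum(proportional_binarize(conn, 0)$adjacency), 0)
  expect_equal(sum(proportional_binarize(conn, 1)$adjacency) / 2, 6)
})

test_that("density stack is nested, 10-deep on the default grid, with 0.1 spacing", {
  set.seed(42)
  for (rep in 1:20) {
    w <- matrix(rnorm(15 * 15, sd = 0.5), 15, 15)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    conn <- connectome(pmin(pmax(w, -1), 1))
    stack <- density_stack(conn)
    expect_length(stack, 10)
    grid <- default_density_grid()
    expect_equal(diff(grid), rep(0.1, 9))
    for (i in 1:9) {
      expect_true(all(stack[[i]]$adjacency <= stack[[i + 1]]$adjacency))
    }
  }
})

test_that("analytic spot values of the four metrics hold", {
  k4 <- make_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(global_efficiency(k4), 1.0)
  expect_equal(global_efficiency(make_graph(matrix(0, 4, 4))), 0.0)
  path3 <- make_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(global_efficiency(path3), 5 / 6)

  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
  g <- make_graph(two_tri)
  expect_equal(modularity_fixed(g, make_part(c(1, 1, 1, 2, 2, 2))), 0.5)
  expect_equal(modularity_fixed(g, make_part(rep(1, 6))), 0)
  expect_equal(modularity_fixed(make_graph(matrix(0, 3, 3)), make_part(1:3)), 0)

  expect_equal(clustering_mean(make_graph(matrix(1, 3, 3) - diag(3))), 1.0)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star[2:4, 1] <- 1
  expect_equal(clustering_mean(make_graph(star)), 0.0)

  # hub with 2 edges into each of 2 modules: PC = 1 - 2 (1/2)^2 = 0.5
  a <- matrix(0, 5, 5); a[1, 2:5] <- 1; a[2:5, 1] <- 1
  pc <- participation(make_graph(a), make_part(c(1, 1, 1, 2, 2)))
  expect_equal(unname(pc[1]), 0.5)
  expect_equal(unname(pc[2]), 0) # leaf: single edge into module 1
  iso <- matrix(0, 3, 3); iso[1, 2] <- 1; iso[2, 1] <- 1
  expect_equal(unname(participation(make_graph(iso), make_part(c(1, 2, 1)))[3]), 0)
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(4:15, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.9))
    mem <- random_membership(n, sample(2:4, 1))
    g <- make_graph(adj)
    part <- make_part(mem)
    expect_equal(global_efficiency(g), oracle_global_efficiency(adj), tolerance = 1e-12)
    expect_equal(clustering_mean(g), oracle_clustering_mean(adj), tolerance = 1e-12)
    expect_equal(modularity_fixed(g, part), oracle_modularity(adj, mem), tolerance = 1e-12)
    expect_equal(unname(participation(g, part)), oracle_participation(adj, mem),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on connected random graphs", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 12
    adj <- random_adjacency(n, 0.5)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    g <- make_graph(adj)
    mem <- random_membership(n, 3)
    expect_equal(modularity_fixed(g, make_part(mem)),
                 igraph::modularity(ig, membership = mem), tolerance = 1e-12)
    expect_equal(clustering_mean(g),
                 mean(igraph::transitivity(ig, type = "localundirected", isolates = "zero")),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(99)
  adj <- random_adjacency(10, 0.4)
  mem <- random_membership(10, 3)
  perm <- sample(10)
  g1 <- make_graph(adj); p1 <- make_part(mem)
  g2 <- binary_graph(adj[perm, perm], paste0("N", perm))
  p2 <- make_part(mem[perm], paste0("N", perm))
  expect_equal(global_efficiency(g1), global_efficiency(g2))
  expect_equal(clustering_mean(g1), clustering_mean(g2))
  expect_equal(modularity_fixed(g1, p1), modularity_fixed(g2, p2))
  expect_equal(participation(g1, p1)[g2$node_ids], participation(g2, p2))
})

test_that("PC of a node spread evenly over 17 modules equals 1 - 1/17", {
  n <- 18
  a <- matrix(0, n, n)
  a[1, 2:18] <- 1; a[2:18, 1] <- 1
  mem <- c(1, rep(1:17, length.out = 17))
  pc <- participation(make_graph(a), make_part(mem))
  # node 1 has 17 edges, one into each of the 17 modules
  expect_equal(unname(pc[1]), 1 - sum((rep(1, 17) / 17)^2))
  expect_equal(unname(pc[1]), 1 - 1 / 17)
})

test_that("efficiency curves are non-decreasing in density and AUC is trapezoidal", {
  set.seed(5)
  for (rep in 1:25) {
    w <- matrix(rnorm(12 * 12, mean = 0.2, sd = 0.4), 12, 12)
    w <- (w + t(w)) / 2; diag(w) <- 1
    conn <- connectome(pmin(pmax(w, -1), 1))
    curve <- metric_curve(conn, "global_efficiency")
    expect_true(all(diff(curve$values) >= -1e-12))
    expect_equal(curve$auc,
                 oracle_trapezoid(c(0, curve$grid), c(0, curve$values)),
                 tolerance = 1e-12)
  }
})

test_that("AUC handles analytic endpoint, flat and linear curves", {
  flat <- list(grid = c(0, default_density_grid()), values = rep(0.7, 11))
  expect_equal(auc_of_curve(flat), 0.7)
  lin <- list(grid = default_density_grid(), values = default_density_grid())
  expect_equal(auc_of_curve(lin), 0.5) # M(0) = 0 prepended analytically
  expect_error(auc_of_curve(list(grid = c(0.5, 0.1), values = c(1, 2))), "sorted")
  set.seed(3)
  y <- runif(10)
  expect_equal(auc_of_curve(list(grid = default_density_grid(), values = y)),
               oracle_trapezoid(c(0, default_density_grid()), c(0, y)),
               tolerance = 1e-12)
})

test_that("metric_curve covers trivial extremes", {
  allpos <- connectome(matrix(0.5, 5, 5) + diag(0.5, 5))
  curve <- metric_curve(allpos, "global_efficiency")
  expect_equal(curve$values[10], 1) # complete graph at full density
  zero <- connectome(diag(5))
  zc <- metric_curve(zero, "global_efficiency")
  expect_equal(zc$values, rep(0, 10))
  expect_equal(zc$auc, 0)
  expect_error(metric_curve(allpos, "modularity"), "partition")
})
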