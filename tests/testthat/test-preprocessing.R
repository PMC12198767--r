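test_that("detrending removes ramps and projects out nuisance columns", {
  tt <- 1:50
  ramp <- region_ts(rbind(a = 3 + 0.5 * tt), tr_seconds = 2)
  out <- detrend_and_regress(ramp)
  expect_lt(max(abs(out$samples)), 1e-10)

  nuis <- matrix(sin(tt / 3), ncol = 1)
  ts <- region_ts(rbind(a = 2 * sin(tt / 3)), tr_seconds = 2, nuisance = nuis)
  out <- detrend_and_regress(ts)
  expect_lt(max(abs(out$samples)), 1e-10)
})

test_that("residuals match closed-form least squares and are orthogonal to the design", {
  set.seed(21)
  tt <- 1:80
  sig <- sin(2 * pi * tt / 16)
  y <- 1.5 + 0.2 * tt + sig
  nuis <- matrix(rnorm(80), ncol = 1)
  ts <- region_ts(rbind(a = y + 0.7 * nuis[, 1]), nuisance = nuis)
  out <- detrend_and_regress(ts)
  # normal-equations oracle
  X <- cbind(1, tt, nuis)
  beta <- solve(t(X) %*% X, t(X) %*% (y + 0.7 * nuis[, 1]))
  expect_equal(as.numeric(out$samples),
               as.numeric((y + 0.7 * nuis[, 1]) - X %*% beta), tolerance = 1e-9)
  for (k in seq_len(ncol(X))) {
    expect_lt(abs(sum(out$samples[1, ] * X[, k])),
              1e-8 * sqrt(sum(out$samples^2)) * sqrt(sum(X[, k]^2)))
  }
})

test_that("rank-deficient nuisance blocks warn and still project", {
  tt <- 1:30
  nuis <- cbind(tt, 2 * tt) # collinear with the trend column
  ts <- region_ts(rbind(a = rnorm(30)), nuisance = nuis)
  expect_warning(out <- detrend_and_regress(ts), "rank-deficient")
  expect_lt(abs(sum(out$samples[1, ] * tt)), 1e-6)
})

test_that("winsorization clips to the 5th/95th percentiles and nothing else", {
  x <- 1:100
  ts <- region_ts(rbind(a = x))
  out <- winsorize(ts)
  qs <- quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  expect_equal(min(out$samples), qs[1])
  expect_equal(max(out$samples), qs[2])
  inside <- x > qs[1] & x < qs[2]
  expect_equal(out$samples[1, inside], ts$samples[1, inside])

  const <- region_ts(rbind(a = rep(4, 20)))
  expect_equal(winsorize(const)$samples, const$samples)
  narrow <- region_ts(rbind(a = c(rep(0, 50), rep(1, 50))))
  expect_equal(winsorize(narrow, 1, 99)$samples, narrow$samples)
})

test_that("winsorization preserves the rank order of interior samples", {
  set.seed(31)
  x <- rnorm(200)
  out <- winsorize(region_ts(rbind(a = x)))
  qs <- quantile(x, c(0.05, 0.95), names = FALSE)
  inside <- which(x > qs[1] & x < qs[2])
  expect_equal(order(out$samples[1, inside]), order(x[inside]))
})

test_that("wavelet band keeps in-band energy and rejects out-of-band energy", {
  tt <- seq_len(512)
  tr <- 2
  in_band <- region_ts(rbind(a = sin(2 * pi * 0.045 * tr * tt)), tr_seconds = tr)
  out <- wavelet_band(in_band)
  expect_gt(sum(out$samples^2) / sum(in_band$samples^2), 0.8)

  out_band <- region_ts(rbind(a = sin(2 * pi * 0.2 * tr * tt)), tr_seconds = tr)
  out2 <- wavelet_band(out_band)
  expect_lt(sum(out2$samples^2) / sum(out_band$samples^2), 0.1)

  zero <- region_ts(rbind(a = rep(0, 64)))
  expect_equal(wavelet_band(zero)$samples, zero$samples)
  short <- region_ts(rbind(a = rnorm(8)))
  expect_error(wavelet_band(short), "volumes")
})

test_that("white noise filtered to the band concentrates spectral energy there", {
  set.seed(8)
  tr <- 2
  x <- rnorm(4096)
  out <- wavelet_band(region_ts(rbind(a = x), tr_seconds = tr))
  spec <- Mod(stats::fft(out$samples[1, ]))^2
  freq <- (seq_along(x) - 1) / (length(x) * tr)
  half <- freq <= 1 / (2 * tr)
  ratio <- sum(spec[half & freq > 0.03 & freq < 0.06]) / sum(spec[half])
  expect_gt(ratio, 0.7)
})

test_that("the wavelet transform reconstructs its input exactly", {
  set.seed(9)
  x <- rnorm(300)
  for (wv in c("haar", "d4", "la8", "la16")) {
    mra <- connres:::modwt_mra(x, 4, wv)
    expect_equal(Reduce(`+`, mra$details) + mra$smooth, x, tolerance = 1e-9)
  }
  # dyadic level selection follows the TR
  expect_equal(connres:::band_to_level(c(0.03, 0.06), 2), 3L)
  expect_equal(connres:::band_to_level(c(0.03, 0.06), 1), 4L)
})

test_that("correlation matrices follow the definitional oracle", {
  x <- c(1, 2, 4, 3, 5)
  same <- region_ts(rbind(a = x, b = x * 2 + 1, c = -x))
  conn <- correlation_matrix(same)
  expect_equal(conn$weights["a", "b"], 1)
  expect_equal(conn$weights["a", "c"], -1)
  set.seed(4)
  m <- matrix(rnorm(3 * 30), 3)
  conn2 <- correlation_matrix(region_ts(m, c("x", "y", "z")))
  byhand <- function(u, v) {
    cu <- u - mean(u); cv <- v - mean(v)
    sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
  }
  expect_equal(conn2$weights["x", "y"], byhand(m[1, ], m[2, ]), tolerance = 1e-12)
  expect_equal(conn2$weights["x", "z"], byhand(m[1, ], m[3, ]), tolerance = 1e-12)
  flat <- region_ts(rbind(a = rep(1, 10), b = rnorm(10)))
  expect_error(correlation_matrix(flat), "zero-variance regions: a")
})

test_that("region exclusion drops rows, writes the ledger and is idempotent", {
  set.seed(2)
  w <- matrix(rnorm(8 * 8, sd = 0.2), 8); w <- (w + t(w)) / 2; diag(w) <- 1
  conn <- connectome(pmin(pmax(w, -1), 1), paste0("r", 1:8))
  expect_identical(exclude_regions(conn)$weights, conn$weights)

  out <- exclude_regions(conn, dropout_ids = c("r1", "r2"), primary_lesioned = "r5")
  expect_equal(out$node_ids, paste0("r", c(3, 4, 6, 7, 8)))
  expect_equal(nrow(out$removed_nodes), 3)
  expect_equal(out$removed_nodes$reason[out$removed_nodes$region_id == "r5"],
               "primary_lesion")
  twice <- exclude_regions(out, dropout_ids = c("r1", "r2"), primary_lesioned = "r5")
  expect_identical(twice$weights, out$weights)
  expect_identical(twice$removed_nodes, out$removed_nodes)

  expect_error(exclude_regions(conn, dropout_ids = paste0("r", 1:7)), "fewer than 2")
  expect_error(exclude_regions(conn, dropout_ids = "nope"), "unknown")
})

test_that("the pipeline's connectome is invariant to region ordering", {
  set.seed(17)
  n <- 6
  m <- matrix(rnorm(n * 64), n, dimnames = list(paste0("r", 1:n), NULL))
  ts1 <- region_ts(m, tr_seconds = 2)
  perm <- sample(n)
  ts2 <- region_ts(m[perm, ], tr_seconds = 2)
  c1 <- correlation_matrix(wavelet_band(winsorize(detrend_and_regress(ts1))))
  c2 <- correlation_matrix(wavelet_band(winsorize(detrend_and_regress(ts2))))
  expect_equal(c2$weights[c1$node_ids, c1$node_ids], c1$weights, tolerance = 1e-12)
})

test_that("region series round-trip through TSV", {
  m <- matrix(rnorm(3 * 20), 3, dimnames = list(c("a", "b", "c"), NULL))
  ts <- region_ts(m, tr_seconds = 2)
  path <- tempfile(fileext = ".tsv")
  write_region_ts(ts, path)
  back <- read_region_ts(path)
  expect_equal(unname(back$samples), unname(ts$samples), tolerance = 1e-12)
  expect_equal(back$region_ids, ts$region_ids)
})
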