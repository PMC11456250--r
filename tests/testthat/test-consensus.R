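# helper: an ensemble of M fake runs around common factors with noise
noisy_ensemble <- function(M, dims = c(6, 7, 30), rank = 3, noise = 0.05,
                           seed = 1) {
  set.seed(seed)
  base <- lapply(dims, function(d) matrix(rgamma(d * rank, 3, 1), d, rank))
  runs <- lapply(seq_len(M), function(m) {
    fake_fit(lapply(base, function(b) {
      pmax(b + matrix(rnorm(length(b), 0, noise), nrow(b)), 1e-6)
    }))
  })
  run_ensemble(runs)
}

test_that("aggregation concatenates unit-norm blocks", {
  ens <- noisy_ensemble(4)
  agg <- aggregate_runs(ens)
  expect_equal(dim(agg), c(30, 12))
  for (m in 1:4) {
    block <- agg[, (m - 1) * 3 + 1:3]
    expect_equal(sqrt(sum(block^2)), 1, tolerance = 1e-10)
  }
  # M = 1 reduces to a single normalized matrix
  e1 <- run_ensemble(ens$runs[1])
  a1 <- aggregate_runs(e1)
  m <- ens$runs[[1]]$point_estimate$factors[[3]]
  expect_equal(a1, m / sqrt(sum(m^2)), ignore_attr = TRUE)
  # paper shape check: I_k = 10, R = 9, M = 20 -> 10 x 180
  ens2 <- noisy_ensemble(20, dims = c(4, 5, 10), rank = 9)
  expect_equal(dim(aggregate_runs(ens2)), c(10, 180))
})

test_that("zero-norm factor matrices are rejected during aggregation", {
  ens <- noisy_ensemble(2)
  ens$runs[[1]]$point_estimate$factors[[3]][] <- 0
  expect_error(aggregate_runs(ens), "zero-norm")
})

test_that("k-means recovers duplicated column groups exactly", {
  u <- c(1, 0, 0, 0)
  v <- c(0, 1, 0, 0)
  agg <- cbind(u, u, u, v, v, v)
  cl <- cluster_columns(agg, K = 2, seed = 1)
  expect_true(all(cl$retained))
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_false(cl$labels[1] == cl$labels[4])
  expect_error(cluster_columns(agg, K = 7, seed = 1), "exceeds")
})

test_that("a far-off column is flagged as an outlier", {
  set.seed(2)
  u <- c(1, 0, 0, 0)
  v <- c(0, 1, 0, 0)
  jit <- function(x) x + rnorm(4, 0, 0.01)
  agg <- cbind(jit(u), jit(u), jit(u), jit(v), jit(v), jit(v),
               100 * (u + v))
  cl <- cluster_columns(agg, K = 2, seed = 3)
  expect_false(cl$retained[7])
  expect_true(all(cl$retained[1:6]))
})

test_that("column order permutation permutes labels identically", {
  set.seed(4)
  agg <- cbind(matrix(rnorm(12, 5), 4, 3), matrix(rnorm(12, -5), 4, 3))
  cl <- cluster_columns(agg, K = 2, seed = 9)
  perm <- c(4, 1, 5, 2, 6, 3)
  cl2 <- cluster_columns(agg[, perm], K = 2, seed = 9)
  # partition must match up to relabeling
  same <- outer(cl$labels[perm], cl$labels[perm], "==")
  same2 <- outer(cl2$labels, cl2$labels, "==")
  expect_equal(same, same2)
})

test_that("silhouette matches its definition and the cluster package", {
  # two tight, well-separated clusters
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
               matrix(rnorm(20, 10, 0.05), 10, 2))
  labs <- rep(1:2, each = 10)
  s <- silhouette_score(pts, labs)
  expect_gt(s, 0.9)
  expect_equal(s, mean(cluster::silhouette(labs, dist(pts))[, 3]),
               tolerance = 1e-10)

  # identical points within each cluster give exactly 1
  pts2 <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  expect_equal(silhouette_score(pts2, rep(1:2, each = 5)), 1)

  # a point equidistant between clusters contributes 0
  pts3 <- rbind(c(0, 0), c(0, 0), c(2, 0), c(4, 0), c(4, 0))
  labs3 <- c(1, 1, 1, 2, 2)
  s3 <- silhouette_score(pts3, labs3)
  manual <- mean(cluster::silhouette(labs3, dist(pts3))[, 3])
  expect_equal(s3, manual, tolerance = 1e-10)

  expect_error(silhouette_score(pts, rep(1, 20)), "2 clusters")
})

test_that("consensus factors take entrywise medians per cluster", {
  agg <- cbind(c(1, 0), c(1, 0), c(3, 0), c(0, 2), c(4, 2), c(2, 8))
  labels <- c(1, 1, 1, 2, 2, 2)
  cons <- consensus_factors(agg, labels)
  expect_equal(cons[, 1], c(1, 0))
  expect_equal(cons[, 2], c(2, 2))
  # identical columns return themselves
  agg2 <- cbind(c(5, 6), c(5, 6), c(1, 1))
  expect_equal(consensus_factors(agg2, c(1, 1, 2))[, 1], c(5, 6))
  # a label gap means a cluster lost all members to pruning
  expect_error(consensus_factors(agg[, 1:4], c(1, 1, 3, 3)), "cluster 2")
})

test_that("consensus factors ignore run and column order", {
  ens <- noisy_ensemble(5, noise = 0.01)
  agg <- aggregate_runs(ens)
  cl <- cluster_columns(agg, K = 3, seed = 2)
  cons <- consensus_factors(agg, cl$labels)
  perm <- sample(ncol(agg))
  cons2 <- consensus_factors(agg[, perm], cl$labels[perm])
  expect_equal(cons, cons2)
})

test_that("cophenetic correlation is 1 for identical assignments and drops with noise", {
  set.seed(6)
  rank <- 3
  base <- matrix(rgamma(60, 2), 20, rank)
  base[cbind(1:20, rep(1:3, length.out = 20))] <- 10  # clear argmax
  make_run <- function(flip_n) {
    m <- base
    if (flip_n > 0) {
      rows <- sample(20, flip_n)
      for (r in rows) {
        m[r, ] <- m[r, sample(rank)]
      }
    }
    fake_fit(list(matrix(1, 4, rank), matrix(1, 5, rank), m))
  }
  ens_same <- run_ensemble(lapply(1:4, function(i) make_run(0)))
  expect_equal(cophenetic_correlation(ens_same), 1)

  vals <- vapply(c(2, 6, 12), function(fn) {
    set.seed(100 + fn)
    cophenetic_correlation(run_ensemble(lapply(1:6, function(i)
      make_run(fn))))
  }, numeric(1))
  expect_true(all(diff(vals) < 0.05))  # monotone trend, small slack
  expect_lt(vals[3], 1)

  # invariant to per-run column permutations
  ens_perm <- run_ensemble(lapply(1:4, function(i) {
    f <- make_run(0)
    perm <- sample(rank)
    f$point_estimate$factors <- lapply(f$point_estimate$factors,
                                       function(m) m[, perm, drop = FALSE])
    f
  }))
  expect_equal(cophenetic_correlation(ens_perm), 1)
  expect_error(cophenetic_correlation(run_ensemble(ens_same$runs[1])),
               "2 runs")
})

test_that("random assignments give cophenetic correlation well below 1", {
  set.seed(8)
  runs <- lapply(1:8, function(i) {
    m <- matrix(runif(300), 100, 3)  # argmax uniform across factors
    fake_fit(list(matrix(1, 4, 3), matrix(1, 5, 3), m))
  })
  expect_lt(cophenetic_correlation(run_ensemble(runs)), 0.9)
})

test_that("refitting from a consensus of identical runs preserves fit quality", {
  sim <- simulate_zip_tensor(c(5, 6, 20), 2, phi = 0.2, seed = 13)
  one <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 5,
                      max_iter = 400)
  ens <- run_ensemble(list(one, one, one))
  cons <- refit_consensus(sim$tensor, ens, seed = 9, max_iter = 400)
  expect_gte(cons$final_fit$explained_variance,
             one$explained_variance - 0.02)
  # seeded: identical ensemble and seed give identical final fits
  cons2 <- refit_consensus(sim$tensor, ens, seed = 9, max_iter = 400)
  expect_identical(cons$final_fit$point_estimate$factors,
                   cons2$final_fit$point_estimate$factors)
})

test_that("rank selection flags an exact low-rank tensor at rank 1", {
  f <- rand_factors(c(5, 6, 7), 1, seed = 31)
  x <- reconstruct(f)
  report <- select_rank(x, ranks = c(1, 2), M = 2,
                        spec_for = model_spec("gamma_poisson", rank = 1),
                        seed = 3, max_iter = 400)
  expect_equal(attr(report, "selected_rank"), 1)
  expect_gte(report$ev_mean[1], 0.9)
  expect_true(all(diff(report$rank) > 0))
})
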