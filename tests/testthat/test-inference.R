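test_that("zip log-pmf matches direct evaluation and handles both branches", {
  expect_equal(zip_log_pmf(0, 1, 0), -1)
  expect_equal(zip_log_pmf(0, 2, 0.3), log(0.3 + 0.7 * exp(-2)))
  expect_equal(zip_log_pmf(1, 1, 0.5), log(0.5 * exp(-1)))
  expect_error(zip_log_pmf(1, -1, 0.5), "positive")
  expect_error(zip_log_pmf(1, 1, 1.2), "0, 1")
})

test_that("zip log-pmf with p = 0 equals the Poisson log-pmf", {
  for (lam in c(0.1, 1, 5, 20)) {
    x <- 0:20
    expect_equal(zip_log_pmf(x, lam, 0), dpois(x, lam, log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("zip pmf sums to one over its support", {
  for (lam in c(0.5, 3, 12)) {
    for (p in c(0, 0.2, 0.8, 1)) {
      total <- sum(exp(zip_log_pmf(0:300, lam, p)))
      expect_equal(total, 1, tolerance = 1e-6)
    }
  }
})

test_that("log joint decomposes into prior and likelihood terms", {
  spec <- model_spec("zip", rank = 1, prior_shape = 2, prior_rate = 0.5)
  f <- cp_factors(list(matrix(1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1)))
  x0 <- count_tensor(array(0, c(1, 1, 1)))
  p <- 0.3
  lj <- log_joint(f, gate = p, x = x0, spec = spec)
  manual <- 3 * dgamma(1, 2, rate = 0.5, log = TRUE) +
    dnorm(qlogis(p), 0, 1, log = TRUE) + zip_log_pmf(0, 1, p)
  expect_equal(lj, manual, tolerance = 1e-12)

  spec_gp <- model_spec("gamma_poisson", rank = 1, prior_shape = 2,
                        prior_rate = 0.5)
  lj_gp <- log_joint(f, x = x0, spec = spec_gp)
  expect_equal(lj_gp - 3 * dgamma(1, 2, rate = 0.5, log = TRUE), -1,
               tolerance = 1e-12)

  # additivity term-by-term on a 2x2x2 rank-1 instance
  f2 <- rand_factors(c(2, 2, 2), 1, seed = 3)
  x2 <- count_tensor(array(rpois(8, 4), c(2, 2, 2)))
  lam <- as.double(reconstruct(f2)$data)
  manual2 <- sum(vapply(seq_along(f2$factors), function(k) {
    sum(dgamma(f2$factors[[k]], 2, rate = 0.5, log = TRUE))
  }, numeric(1))) + sum(dpois(as.double(x2$data), lam, log = TRUE))
  expect_equal(log_joint(f2, x = x2, spec = spec_gp), manual2,
               tolerance = 1e-10)
})

test_that("point estimate returns arithmetic and geometric expectations", {
  st <- variational_state(gamma = list(matrix(2, 1, 1), matrix(2, 1, 1)),
                          delta = list(matrix(4, 1, 1), matrix(4, 1, 1)))
  expect_equal(point_estimate(st)$factors[[1]][1, 1], 0.5)
  st2 <- variational_state(gamma = list(matrix(3, 1, 1), matrix(3, 1, 1)),
                           delta = list(matrix(3, 1, 1), matrix(3, 1, 1)))
  expect_equal(point_estimate(st2)$factors[[1]][1, 1], 1)
  st3 <- variational_state(gamma = list(matrix(1, 1, 1), matrix(1, 1, 1)),
                           delta = list(matrix(2, 1, 1), matrix(2, 1, 1)))
  expect_equal(point_estimate(st3, type = "geometric")$factors[[1]][1, 1],
               exp(digamma(1)) / 2, tolerance = 1e-12)
})

test_that("ELBO estimate is seeded and tightens with more samples", {
  x <- count_tensor(array(rpois(8, 3), c(2, 2, 2)))
  spec <- model_spec("gamma_poisson", rank = 1)
  st <- variational_state(
    gamma = list(matrix(40, 2, 1), matrix(40, 2, 1), matrix(40, 2, 1)),
    delta = list(matrix(20, 2, 1), matrix(20, 2, 1), matrix(20, 2, 1)))
  e1 <- elbo_estimate(st, x, spec, n_samples = 20, seed = 7)
  e2 <- elbo_estimate(st, x, spec, n_samples = 20, seed = 7)
  expect_identical(e1, e2)

  reps <- function(n) vapply(1:12, function(s)
    elbo_estimate(st, x, spec, n_samples = n, seed = 100 + s), numeric(1))
  expect_lt(sd(reps(400)), sd(reps(10)))
})

test_that("ELBO approaches the point-mass value as variances shrink", {
  x <- count_tensor(array(rpois(8, 5), c(2, 2, 2)))
  spec <- model_spec("gamma_poisson", rank = 1)
  m <- 2  # variational mean for every entry
  f <- cp_factors(lapply(1:3, function(k) matrix(m, 2, 1)))
  logp_mode <- log_joint(f, x = x, spec = spec)
  st_big <- variational_state(
    gamma = lapply(1:3, function(k) matrix(1e6, 2, 1)),
    delta = lapply(1:3, function(k) matrix(1e6 / m, 2, 1)))
  ent <- sum(vapply(1:3, function(k) {
    g <- 1e6; d <- 1e6 / m
    2 * (g - log(d) + lgamma(g) + (1 - g) * digamma(g))
  }, numeric(1)))
  # ELBO = E[log p] + H(q); H is negative for a near-point-mass q
  e <- elbo_estimate(st_big, x, spec, n_samples = 400, seed = 11)
  expect_equal(e - ent, logp_mode, tolerance = 1e-2 * abs(logp_mode))
})

test_that("fit recovers an easy rank-1 Poisson tensor", {
  sim <- simulate_zip_tensor(c(5, 5, 5), 1, phi = 0, seed = 42)
  fit <- fit_bayes_cp(sim$tensor, model_spec("gamma_poisson", rank = 1),
                      seed = 1, max_iter = 600)
  expect_gte(fit$explained_variance, 0.95)
  expect_true(all(vapply(fit$point_estimate$factors,
                         function(m) all(m >= 0), logical(1))))
})

test_that("fit is reproducible under a fixed seed", {
  sim <- simulate_zip_tensor(c(4, 4, 6), 2, phi = 0.2, seed = 9)
  f1 <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 3,
                     max_iter = 120)
  f2 <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 3,
                     max_iter = 120)
  expect_identical(f1$point_estimate$factors, f2$point_estimate$factors)
  expect_identical(f1$state$elbo_trace, f2$state$elbo_trace)
  expect_identical(f1$gate, f2$gate)
})

test_that("fit validates arguments and honors a mode initialization", {
  sim <- simulate_zip_tensor(c(4, 4, 6), 2, phi = 0, seed = 9)
  expect_error(fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2),
                            max_iter = 0), "max_iter")
  init <- vector("list", 3)
  init[[3]] <- matrix(5, 6, 2)
  f <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 1,
                    max_iter = 1, init = init, init_concentration = 1e5)
  # after a single step, the mode-3 variational means are still near 5
  expect_equal(unname(f$point_estimate$factors[[3]]),
               matrix(5, 6, 2), tolerance = 0.2)
  init_bad <- vector("list", 3)
  init_bad[[1]] <- matrix(1, 2, 2)
  expect_error(fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2),
                            seed = 1, init = init_bad), "wrong shape")
})

test_that("variational parameters stay strictly positive through a fit", {
  sim <- simulate_zip_tensor(c(4, 5, 6), 2, phi = 0.4, seed = 21)
  f <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 2,
                    max_iter = 150)
  for (k in 1:3) {
    expect_true(all(f$state$gamma[[k]] > 0))
    expect_true(all(f$state$delta[[k]] > 0))
  }
  expect_true(all(f$state$gate_sd > 0))
  expect_true(all(is.finite(f$state$elbo_trace)))
})

test_that("zip fit beats gamma-poisson on factor recovery once zeros inflate", {
  for (phi in c(0, 0.3, 0.6)) {
    sim <- simulate_zip_tensor(c(6, 8, 40), 3, phi = phi, seed = 30 + phi * 10)
    fz <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 3),
                       seed = 4, max_iter = 500)
    fg <- fit_bayes_cp(sim$tensor, model_spec("gamma_poisson", rank = 3),
                       seed = 4, max_iter = 500)
    cz <- cosine_score(fz$point_estimate, sim$true_factors)
    cg <- cosine_score(fg$point_estimate, sim$true_factors)
    if (phi >= 0.3) {
      expect_gt(cz, cg)
    } else {
      expect_gt(cz, 0.9)
      expect_gt(cg, 0.9)
    }
  }
})

test_that("score-function gradient path runs and improves the ELBO", {
  sim <- simulate_zip_tensor(c(3, 3, 4), 1, phi = 0, seed = 5)
  f <- fit_bayes_cp(sim$tensor, model_spec("gamma_poisson", rank = 1),
                    seed = 2, max_iter = 300, gradient = "score",
                    n_particles = 8)
  tr <- f$state$elbo_trace
  expect_gt(mean(tail(tr, 20)), mean(head(tr, 20)))
})

test_that("fit results serialize and reload", {
  dir <- withr::local_tempdir()
  sim <- simulate_zip_tensor(c(3, 4, 5), 2, phi = 0.1, seed = 8)
  f <- fit_bayes_cp(sim$tensor, model_spec("zip", rank = 2), seed = 6,
                    max_iter = 80)
  write_fit_result(f, file.path(dir, "fit"))
  g <- read_fit_result(file.path(dir, "fit"))
  expect_equal(g$point_estimate$factors, f$point_estimate$factors,
               tolerance = 1e-8)
  expect_equal(g$explained_variance, f$explained_variance, tolerance = 1e-12)
  expect_equal(g$spec$noise_model, "zip")
})
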