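#' Model specification for Bayesian CP factorization
#'
#' Bundles the observation model, rank, and prior hyperparameters. Factor
#' entries carry independent Gamma(shape, rate) priors per mode; the
#' zero-inflated Poisson (ZIP) model additionally places a Normal prior on the
#' logit of the global excess-zero probability (the "gate").
#'
#' Two Gamma prior conventions are in use in Bayesian Poisson factorization:
#' the stochastic (black-box) solver reads `prior_shape`/`prior_rate` directly
#' as Gamma(shape, rate) with mean shape/rate; the coordinate-ascent
#' Gamma-Poisson solver ([cavi_gptf_fit()]) uses the sparsity-prior convention
#' Gamma(shape, shape * rate) with mean 1/rate and updates the per-mode rates
#' by empirical Bayes.
#'
#' @param noise_model one of `"zip"`, `"gamma_poisson"`, `"truncated_gaussian"`.
#' @param rank decomposition rank R >= 1.
#' @param n_modes number of tensor modes (default 3).
#' @param prior_shape,prior_rate positive Gamma hyperparameters, scalar or one
#'   per mode.
#' @param gate_prior_mean,gate_prior_sd Normal prior on the gate logit
#'   (ZIP only).
#' @param gate_mode `"global"` for a single shared gate, or `"feature"` for
#'   one gate per index of the last mode (e.g. per gene).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(noise_model = c("zip", "gamma_poisson",
                                       "truncated_gaussian"),
                       rank, n_modes = 3L,
                       prior_shape = 1, prior_rate = 0.3,
                       gate_prior_mean = 0, gate_prior_sd = 1,
                       gate_mode = c("global", "feature")) {
  noise_model <- match.arg(noise_model)
  gate_mode <- match.arg(gate_mode)
  stop_if_not_scalar_number(rank, "rank")
  if (rank < 1) stop("`rank` must be >= 1", call. = FALSE)
  n_modes <- as.integer(n_modes)
  if (n_modes < 2L) stop("`n_modes` must be >= 2", call. = FALSE)
  prior_shape <- rep_len(as.double(prior_shape), n_modes)
  prior_rate <- rep_len(as.double(prior_rate), n_modes)
  if (any(prior_shape <= 0) || any(prior_rate <= 0)) {
    stop("prior shape and rate must be positive", call. = FALSE)
  }
  if (gate_prior_sd <= 0) stop("`gate_prior_sd` must be positive",
                               call. = FALSE)
  structure(
    list(noise_model = noise_model, rank = as.integer(rank),
         n_modes = n_modes, prior_shape = prior_shape,
         prior_rate = prior_rate, gate_prior_mean = gate_prior_mean,
         gate_prior_sd = gate_prior_sd, gate_mode = gate_mode),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, rank %d, %d modes\n", x$noise_model, x$rank,
              x$n_modes))
  invisible(x)
}

#' Zero-inflated Poisson log-probability
#'
#' Log of `p * 1[x == 0] + (1 - p) * exp(-lam) * lam^x / x!`. The factorial is
#' evaluated through `lgamma(x + 1)`, so non-integer `x` (e.g. CPM-normalized
#' counts) is accepted as a continuous extension of the pmf.
#'
#' @param x non-negative observation(s).
#' @param lam positive Poisson mean(s).
#' @param p probability of extra zeros in `[0, 1]`.
#' @return log-probabilities, vectorized over the inputs.
#' @export
zip_log_pmf <- function(x, lam, p) {
  if (any(lam <= 0)) stop("`lam` must be positive", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  n <- max(length(x), length(lam), length(p))
  x <- rep_len(x, n); lam <- rep_len(lam, n); p <- rep_len(p, n)
  pois <- x * log(lam) - lam - lgamma(x + 1)
  out <- log1p(-p) + pois
  iz <- x == 0
  if (any(iz)) {
    # log(p + (1-p) e^{-lam}) computed stably via log-sum-exp
    a <- log(p[iz])
    b <- log1p(-p[iz]) - lam[iz]
    m <- pmax(a, b)
    lz <- m + log(exp(a - m) + exp(b - m))
    lz[p[iz] == 0] <- b[p[iz] == 0]
    lz[p[iz] == 1] <- 0
    out[iz] <- lz
  }
  out
}

# Continuous-extension Poisson log-pmf (lgamma factorial).
pois_log_pmf <- function(x, lam) {
  x * log(lam) - lam - lgamma(x + 1)
}

# log-density of Normal(mean, sd) truncated to [0, Inf).
truncnorm_log_pdf <- function(x, mean, sd) {
  stats::dnorm(x, mean, sd, log = TRUE) -
    stats::pnorm(mean / sd, log.p = TRUE)
}

obs_loglik <- function(x, lam, spec, gate = NULL, scale = NULL) {
  switch(spec$noise_model,
    zip = {
      if (is.null(gate)) stop("zip model requires a gate probability",
                              call. = FALSE)
      sum(zip_log_pmf(x, lam, expand_gate(gate, x)))
    },
    gamma_poisson = sum(pois_log_pmf(x, lam)),
    truncated_gaussian = {
      if (is.null(scale)) stop("truncated_gaussian model requires `scale`",
                               call. = FALSE)
      sum(truncnorm_log_pdf(x, lam, scale))
    }
  )
}

# Broadcast a gate (scalar, or one value per last-mode index) over vec(x).
expand_gate <- function(gate, x) {
  if (length(gate) == 1L) return(gate)
  dims <- dim(x)
  if (is.null(dims)) stop("feature gate requires array data", call. = FALSE)
  ng <- dims[length(dims)]
  if (length(gate) != ng) {
    stop("feature gate length must match the last mode size", call. = FALSE)
  }
  rep(gate, each = prod(dims[-length(dims)]))
}

#' Log joint density of factors, gate and data
#'
#' Sum of the Gamma prior log-densities of every factor entry, the Normal
#' prior log-density of the gate's logit (ZIP only), and the observation
#' log-likelihood of every tensor entry under the chosen noise model with CP
#' mean \eqn{\lambda_I = \sum_r \prod_k a^{(k)}_{i_k r}}.
#'
#' @param factors a `cp_factors` object with strictly positive entries.
#' @param gate excess-zero probability in (0, 1) (scalar, or per-feature for
#'   `gate_mode = "feature"`); `NULL` for non-ZIP models.
#' @param x a `count_tensor` matching the factor shapes.
#' @param spec a `model_spec`.
#' @param scale observation scale (truncated Gaussian model only).
#' @return the scalar log joint.
#' @export
log_joint <- function(factors, gate = NULL, x, spec, scale = NULL) {
  stopifnot(inherits(factors, "cp_factors"), inherits(spec, "model_spec"))
  a <- as_tensor_array(x)
  dims <- vapply(factors$factors, nrow, integer(1))
  if (!identical(as.integer(dim(a)), as.integer(dims))) {
    stop("tensor and factor shapes are inconsistent", call. = FALSE)
  }
  lp <- 0
  for (k in seq_along(factors$factors)) {
    pk <- sum(stats::dgamma(factors$factors[[k]], shape = spec$prior_shape[k],
                            rate = spec$prior_rate[k], log = TRUE))
    if (!is.finite(pk)) {
      stop(sprintf("non-finite prior term for mode %d", k), call. = FALSE)
    }
    lp <- lp + pk
  }
  if (spec$noise_model == "zip") {
    if (is.null(gate) || any(gate <= 0) || any(gate >= 1)) {
      stop("zip model requires gate in (0, 1)", call. = FALSE)
    }
    zeta <- stats::qlogis(gate)
    gp <- sum(stats::dnorm(zeta, spec$gate_prior_mean, spec$gate_prior_sd,
                           log = TRUE))
    if (!is.finite(gp)) stop("non-finite gate prior term", call. = FALSE)
    lp <- lp + gp
  }
  lam <- rowSums(kr_prod(factors$factors))
  ll <- obs_loglik(as.double(a), lam, spec, gate = gate, scale = scale)
  if (!is.finite(ll)) stop("non-finite observation likelihood term",
                           call. = FALSE)
  lp + ll
}

#' Variational state of a fitted model
#'
#' Per-mode Gamma variational shapes/rates, gate parameters (ZIP), the
#' observation scale (truncated Gaussian), and the recorded ELBO trace.
#'
#' @param gamma,delta lists of positive matrices (one `I_k x R` pair per mode).
#' @param gate_mean,gate_sd variational Normal parameters of the gate logit
#'   (ZIP only); `gate_sd > 0`.
#' @param scale positive observation scale (truncated Gaussian only).
#' @param elbo_trace numeric vector of ELBO estimates per iteration.
#' @return an object of class `variational_state`.
#' @export
variational_state <- function(gamma, delta, gate_mean = NULL, gate_sd = NULL,
                              scale = NULL, elbo_trace = numeric(0)) {
  stopifnot(is.list(gamma), is.list(delta), length(gamma) == length(delta))
  for (k in seq_along(gamma)) {
    if (any(gamma[[k]] <= 0) || any(delta[[k]] <= 0)) {
      stop("variational shapes and rates must be strictly positive",
           call. = FALSE)
    }
  }
  if (!is.null(gate_sd) && any(gate_sd <= 0)) {
    stop("gate_sd must be positive", call. = FALSE)
  }
  structure(
    list(gamma = gamma, delta = delta, gate_mean = gate_mean,
         gate_sd = gate_sd, scale = scale, elbo_trace = elbo_trace),
    class = "variational_state"
  )
}

#' Point estimate from a variational state
#'
#' Entrywise arithmetic mean `gamma / delta` of the Gamma variational
#' marginals (the default point estimate), or the geometric expectation
#' `exp(digamma(gamma)) / delta` used by the coordinate-ascent solver's
#' multinomial responsibilities.
#'
#' @param state a `variational_state`.
#' @param type `"arithmetic"` or `"geometric"`.
#' @param mode_names,axis_labels passed through to the returned factors.
#' @return a `cp_factors` object.
#' @export
point_estimate <- function(state, type = c("arithmetic", "geometric"),
                           mode_names = NULL, axis_labels = NULL) {
  stopifnot(inherits(state, "variational_state"))
  type <- match.arg(type)
  factors <- mapply(function(g, d) {
    if (type == "arithmetic") g / d else exp(digamma(g)) / d
  }, state$gamma, state$delta, SIMPLIFY = FALSE)
  cp_factors(factors, mode_names = mode_names, axis_labels = axis_labels)
}

# Draw one sample of all latent variables from q.
draw_from_q <- function(state, spec) {
  z <- mapply(function(g, d) {
    matrix(stats::rgamma(length(g), shape = g, rate = d), nrow(g), ncol(g))
  }, state$gamma, state$delta, SIMPLIFY = FALSE)
  zeta <- NULL
  if (spec$noise_model == "zip") {
    zeta <- stats::rnorm(length(state$gate_mean), state$gate_mean,
                         state$gate_sd)
  }
  list(z = z, zeta = zeta)
}

# log q(z) under the mean-field variational family.
log_q_density <- function(draw, state, spec) {
  lq <- 0
  for (k in seq_along(draw$z)) {
    lq <- lq + sum(stats::dgamma(draw$z[[k]], shape = state$gamma[[k]],
                                 rate = state$delta[[k]], log = TRUE))
  }
  if (spec$noise_model == "zip") {
    lq <- lq + sum(stats::dnorm(draw$zeta, state$gate_mean, state$gate_sd,
                                log = TRUE))
  }
  lq
}

#' Monte-Carlo ELBO estimate
#'
#' Averages `log p(x, z) - log q(z)` over `n_samples` draws `z ~ q`. A fixed
#' seed yields an identical estimate; the standard error of the estimator
#' shrinks as `1/sqrt(n_samples)`.
#'
#' @param state a `variational_state`.
#' @param x a `count_tensor`.
#' @param spec a `model_spec`.
#' @param n_samples number of Monte-Carlo draws (>= 1).
#' @param seed integer seed.
#' @return scalar ELBO estimate.
#' @export
elbo_estimate <- function(state, x, spec, n_samples = 8L, seed = 1L) {
  stopifnot(inherits(state, "variational_state"), n_samples >= 1L)
  vals <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      dr <- draw_from_q(state, spec)
      f <- cp_factors(dr$z)
      gate <- if (!is.null(dr$zeta)) stats::plogis(dr$zeta) else NULL
      log_joint(f, gate = gate, x = x, spec = spec, scale = state$scale) -
        log_q_density(dr, state, spec)
    }, numeric(1))
  })
  est <- mean(vals)
  if (!is.finite(est)) stop("non-finite ELBO estimate", call. = FALSE)
  est
}
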