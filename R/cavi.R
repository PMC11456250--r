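# Coordinate-ascent variational inference for the Gamma-Poisson CP model
# (Bayesian Poisson tensor factorization). Uses the sparsity-prior convention
# Gamma(shape, shape * rate) with prior mean 1/rate per mode, the
# Poisson-Multinomial auxiliary bound for the likelihood, and an optional
# empirical-Bayes update of the per-mode rate hyperparameters.

# ELBO surrogate under the multinomial auxiliary bound with optimal
# responsibilities: sum_I [X_I log Ghat_I - E[lambda_I] - lgamma(X_I + 1)]
# + Gamma prior cross-entropy + Gamma entropy.
cavi_elbo <- function(xv, lgx, Emats, Gmats, gam, del, alpha, beta) {
  ghat <- rowSums(kr_prod(Gmats))
  elam <- rowSums(kr_prod(Emats))
  ll <- sum(xv[xv > 0] * log(ghat[xv > 0])) - sum(elam) - sum(lgx)
  pr <- 0
  for (k in seq_along(Emats)) {
    elog <- digamma(gam[[k]]) - log(del[[k]])
    pr <- pr +
      sum(alpha * log(alpha * beta[k]) - lgamma(alpha) +
            (alpha - 1) * elog - alpha * beta[k] * Emats[[k]]) +
      sum(gam[[k]] - log(del[[k]]) + lgamma(gam[[k]]) +
            (1 - gam[[k]]) * digamma(gam[[k]]))
  }
  ll + pr
}

#' Gamma-Poisson CP factorization by coordinate ascent (deterministic oracle)
#'
#' Closed-form coordinate-ascent updates of the Gamma variational shapes
#' (multinomial responsibilities with geometric expectations), rates, and
#' optionally the per-mode prior rate hyperparameters by empirical Bayes.
#' Deterministic given the seeded initialization; its ELBO surrogate is
#' non-decreasing across sweeps, which makes it a useful cross-check for the
#' stochastic solver.
#'
#' The prior here is `Gamma(alpha, alpha * beta_k)` with mean `1 / beta_k`;
#' `alpha = spec$prior_shape[1]` and `beta_k = spec$prior_rate[k]`.
#'
#' @param x a `count_tensor` with non-negative integer entries.
#' @param spec a `model_spec` with `noise_model = "gamma_poisson"`.
#' @param max_iter maximum number of full coordinate sweeps.
#' @param tol relative ELBO change below which the sweep loop stops.
#' @param seed integer seed for the initialization.
#' @param empirical_bayes update the prior rates per sweep via
#'   `beta_k = 1 / sum(E[a^(k)])`.
#' @return a `fit_result` (see [fit_bayes_cp()]); `state$elbo_trace` holds the
#'   per-sweep ELBO surrogate.
#' @export
cavi_gptf_fit <- function(x, spec, max_iter = 200L, tol = 1e-6, seed = 1L,
                          empirical_bayes = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$noise_model != "gamma_poisson") {
    stop("CAVI solver requires `noise_model = \"gamma_poisson\"`",
         call. = FALSE)
  }
  xt <- if (inherits(x, "count_tensor")) x else count_tensor(as.array(x))
  a <- xt$data
  xv <- as.double(a)
  if (any(xv < 0) || any(xv != round(xv))) {
    stop("CAVI path requires non-negative integer counts", call. = FALSE)
  }
  dims <- dim(a)
  n_modes <- length(dims)
  R <- spec$rank
  alpha <- spec$prior_shape[1]
  beta <- rep_len(spec$prior_rate, n_modes)
  lgx <- lgamma(xv + 1)

  gam <- del <- vector("list", n_modes)
  with_seed(seed, {
    for (k in seq_len(n_modes)) {
      gam[[k]] <- matrix(alpha * (1 + stats::runif(dims[k] * R)),
                         dims[k], R)
      del[[k]] <- matrix(alpha * beta[k] *
                           (1 + stats::runif(dims[k] * R)), dims[k], R)
    }
  })

  elbo_trace <- numeric(max_iter)
  converged <- FALSE
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    for (k in seq_len(n_modes)) {
      Gm <- mapply(function(g, d) exp(digamma(g)) / d, gam, del,
                   SIMPLIFY = FALSE)
      ghat <- pmax(rowSums(kr_prod(Gm)), 1e-300)
      ratio <- array(xv / ghat, dim = dims)
      gam[[k]] <- alpha + Gm[[k]] * (unfold(ratio, k) %*% kr_prod(Gm[-k]))
      Em <- mapply(`/`, gam, del, SIMPLIFY = FALSE)
      cs <- vapply(Em[-k], colSums, numeric(R))
      prod_cs <- if (is.matrix(cs)) apply(cs, 1, prod) else cs
      del[[k]] <- matrix(alpha * beta[k] + prod_cs, dims[k], R, byrow = TRUE)
    }
    Em <- mapply(`/`, gam, del, SIMPLIFY = FALSE)
    if (empirical_bayes) {
      for (k in seq_len(n_modes)) beta[k] <- 1 / sum(Em[[k]])
    }
    Gm <- mapply(function(g, d) exp(digamma(g)) / d, gam, del,
                 SIMPLIFY = FALSE)
    elbo_trace[it] <- cavi_elbo(xv, lgx, Em, Gm, gam, del, alpha, beta)
    if (it > 1L) {
      rel <- abs(elbo_trace[it] - elbo_trace[it - 1L]) /
        (abs(elbo_trace[it - 1L]) + 1e-12)
      if (rel < tol) {
        converged <- TRUE
        iters <- it
        break
      }
    }
  }

  state <- variational_state(gamma = gam, delta = del,
                             elbo_trace = elbo_trace[seq_len(iters)])
  pe <- point_estimate(state, mode_names = xt$mode_names,
                       axis_labels = xt$axis_labels)
  ev <- if (all(xv == 0)) NA_real_ else
    explained_variance(xt, reconstruct(pe))
  spec$prior_rate <- beta  # report the (possibly updated) rates
  structure(
    list(point_estimate = pe, state = state, spec = spec,
         explained_variance = ev, gate = NULL, seed = seed,
         converged = converged, iterations = iters),
    class = "fit_result"
  )
}
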