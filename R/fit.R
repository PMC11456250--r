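# Stochastic variational inference for Bayesian CP factorization.
#
# The latent factor entries carry mean-field Gamma(gamma, delta) variational
# marginals, the ZIP gate logit a Normal(gate_mean, gate_sd) marginal. The
# ELBO is maximized by Adam on the unconstrained parameters (log gamma,
# log delta, gate_mean, log gate_sd, log scale) using Monte-Carlo gradient
# estimates. Two estimators are available:
#
#  * "pathwise" (default): implicit reparameterization for the Gamma draws --
#    d z / d rate is closed form, d z / d shape is obtained from the implicit
#    function theorem applied to the Gamma CDF, with the shape derivative of
#    pgamma computed by central differencing on the log scale. Low variance;
#    one or two particles suffice.
#  * "score": the classic score-function (REINFORCE) estimator with a running
#    mean baseline. Model-agnostic but high-variance; kept for reference and
#    for models without a differentiable density.

# d u / d shape for u ~ Gamma(shape, 1), via the implicit function theorem:
# du/da = -(dF/da) / f. The CDF shape-derivative is computed by central
# differences of log pgamma on whichever tail is numerically dominant.
gamma_shape_grad <- function(u, shape) {
  h <- pmax(shape * 1e-4, 1e-7)
  lower <- stats::pgamma(u, shape, lower.tail = TRUE) <= 0.5
  lf1 <- lf2 <- numeric(length(u))
  if (any(lower)) {
    lf1[lower] <- stats::pgamma(u[lower], shape[lower] + h[lower],
                                log.p = TRUE)
    lf2[lower] <- stats::pgamma(u[lower], shape[lower] - h[lower],
                                log.p = TRUE)
  }
  if (any(!lower)) {
    lf1[!lower] <- stats::pgamma(u[!lower], shape[!lower] + h[!lower],
                                 log.p = TRUE, lower.tail = FALSE)
    lf2[!lower] <- stats::pgamma(u[!lower], shape[!lower] - h[!lower],
                                 log.p = TRUE, lower.tail = FALSE)
  }
  # dF/da = F * d(logF)/da on the lower tail; = -S * d(logS)/da on the upper.
  dlog <- (lf1 - lf2) / (2 * h)
  lmag <- (lf1 + lf2) / 2
  dF <- exp(lmag) * dlog
  dF[!lower] <- -dF[!lower]
  lpdf <- stats::dgamma(u, shape, log = TRUE)
  du <- -dF / exp(lpdf)
  du[!is.finite(du)] <- 0
  # positivity + a loose magnitude guard against numerical blow-ups
  pmin(pmax(du, 0), 100 * (u / shape + 1))
}

# dloglik/dlambda for each tensor entry, as a vector in array order.
d_loglik_d_lambda <- function(xv, lam, spec, gate = NULL, scale = NULL) {
  switch(spec$noise_model,
    gamma_poisson = xv / lam - 1,
    zip = {
      p <- expand_gate(gate, NULL)  # already expanded by caller
      d <- xv / lam - 1
      iz <- xv == 0
      if (any(iz)) {
        pz <- if (length(p) == 1L) p else p[iz]
        d[iz] <- -stats::plogis(-(lam[iz] + stats::qlogis(pz)))
      }
      d
    },
    truncated_gaussian = {
      zr <- lam / scale
      haz <- exp(stats::dnorm(zr, log = TRUE) -
                 stats::pnorm(zr, log.p = TRUE))
      (xv - lam) / scale^2 - haz / scale
    }
  )
}

adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (i in seq_along(par)) {
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * grad[[i]]
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * grad[[i]]^2
    mhat <- st$m[[i]] / (1 - beta1^st$t)
    vhat <- st$v[[i]] / (1 - beta2^st$t)
    par[[i]] <- par[[i]] + lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

#' Fit a Bayesian CP factorization by stochastic variational inference
#'
#' Maximizes a Monte-Carlo estimate of the ELBO over the mean-field
#' variational family (Gamma marginals per factor entry; logit-Normal gate for
#' the ZIP model) by adaptive stochastic gradient ascent. The returned point
#' estimate is the entrywise variational mean `gamma / delta`.
#'
#' @param x a `count_tensor` (non-negative; non-integer values are handled
#'   through the continuous extension of the Poisson/ZIP likelihood).
#' @param spec a `model_spec`.
#' @param max_iter maximum number of gradient steps.
#' @param seed integer seed; fixes initialization and all Monte-Carlo draws.
#' @param init optional initialization of the variational means: a
#'   `cp_factors` object or a list with one matrix or `NULL` per mode.
#'   Modes given a matrix start with variational mean equal to it (the
#'   consensus refit path); `NULL` modes start from prior draws.
#' @param n_particles Monte-Carlo samples per gradient step.
#' @param learning_rate Adam step size on the unconstrained parameters.
#' @param tol relative change of the 25-iteration moving-average ELBO below
#'   which optimization stops early.
#' @param gradient `"pathwise"` (implicit reparameterization, default) or
#'   `"score"` (score-function estimator).
#' @param init_concentration variational shape used at initialization; larger
#'   values start the approximate posterior tighter around its mean.
#' @return a `fit_result`: list with elements `point_estimate`
#'   (`cp_factors`), `state` (`variational_state`), `spec`,
#'   `explained_variance` (vs `x`), `gate` (posterior mean excess-zero
#'   probability, ZIP only), `seed`, `converged`, `iterations`.
#' @export
fit_bayes_cp <- function(x, spec, max_iter = 1000L, seed = 1L, init = NULL,
                         n_particles = 2L, learning_rate = 0.2, tol = 1e-5,
                         gradient = c("pathwise", "score"),
                         init_concentration = 10) {
  stopifnot(inherits(spec, "model_spec"))
  gradient <- match.arg(gradient)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  xt <- if (inherits(x, "count_tensor")) x else count_tensor(as.array(x))
  a <- xt$data
  dims <- dim(a)
  n_modes <- length(dims)
  if (n_modes != spec$n_modes) {
    spec$n_modes <- n_modes
    spec$prior_shape <- rep_len(spec$prior_shape, n_modes)
    spec$prior_rate <- rep_len(spec$prior_rate, n_modes)
  }
  R <- spec$rank
  xv <- as.double(a)
  lgx <- lgamma(xv + 1)
  # fixed index structure of the data, hoisted out of the iteration loop
  iz <- xv == 0
  inz <- which(!iz)
  izw <- which(iz)
  xnz <- xv[inz]
  lgx_sum <- sum(lgx)
  n_nz <- length(inz)
  n_gate <- if (spec$noise_model == "zip") {
    if (spec$gate_mode == "feature") dims[n_modes] else 1L
  } else 0L
  if (n_gate > 1L) gate_rep <- prod(dims[-n_modes])

  init_means <- vector("list", n_modes)
  if (!is.null(init)) {
    fl <- if (inherits(init, "cp_factors")) init$factors else init
    if (length(fl) != n_modes) stop("`init` must supply one entry per mode",
                                    call. = FALSE)
    for (k in seq_len(n_modes)) {
      if (!is.null(fl[[k]])) {
        m <- as.matrix(fl[[k]])
        if (!identical(as.integer(dim(m)), c(dims[k], R))) {
          stop(sprintf("init for mode %d has the wrong shape", k),
               call. = FALSE)
        }
        init_means[[k]] <- pmax(m, 1e-6)
      }
    }
  }

  # scale-aware initialization: prior draws rescaled per mode so the initial
  # reconstruction matches the data mean (cuts the distance the optimizer
  # must travel in log space; the prior itself is unchanged)
  prior_mean_lam <- R * prod(spec$prior_shape / spec$prior_rate)
  init_scale <- (max(mean(xv), 1e-8) / prior_mean_lam)^(1 / n_modes)

  run <- with_seed(seed, {
    # unconstrained parameters: per mode, log concentration (Gamma shape) and
    # log mean of each variational marginal. The (mean, concentration)
    # parameterization decouples point-estimate movement from posterior
    # uncertainty, which conditions the adaptive gradient steps much better
    # than (shape, rate).
    par <- list()
    for (k in seq_len(n_modes)) {
      mk <- init_means[[k]]
      if (is.null(mk)) {
        mk <- matrix(stats::rgamma(dims[k] * R, shape = spec$prior_shape[k],
                                   rate = spec$prior_rate[k]),
                     dims[k], R) * init_scale
        mk <- pmax(mk, 1e-3)
      }
      par[[k]] <- matrix(log(init_concentration), dims[k], R)
      par[[n_modes + k]] <- log(mk)
    }
    idx_gmu <- idx_gsd <- idx_tau <- NULL
    if (spec$noise_model == "zip") {
      idx_gmu <- length(par) + 1L
      par[[idx_gmu]] <- rep(spec$gate_prior_mean, n_gate)
      idx_gsd <- length(par) + 1L
      par[[idx_gsd]] <- rep(log(0.5), n_gate)
    }
    if (spec$noise_model == "truncated_gaussian") {
      idx_tau <- length(par) + 1L
      par[[idx_tau]] <- log(stats::sd(xv) + 1)
    }
    opt <- adam_new(par)
    elbo_trace <- numeric(max_iter)
    converged <- FALSE
    iter_done <- max_iter
    window <- 25L
    # The run ends with a polish phase: the step size drops and the
    # variational means are Polyak-averaged, removing the stationary noise of
    # the stochastic steps. The phase starts at 80% of max_iter, or as soon
    # as the moving-average ELBO flattens, whichever comes first.
    polish <- min(max(50L, floor(0.2 * max_iter)), max(1L, max_iter %/% 2L))
    phase2_at <- max_iter - polish + 1L
    avg_mu <- lapply(seq_len(n_modes), function(k) matrix(0, dims[k], R))
    avg_extra <- list(gmu = 0, gsd = 0, tau = 0)
    avg_n <- 0L

    for (iter in seq_len(max_iter)) {
      grad <- lapply(par, function(p) p * 0)
      elbo_acc <- 0
      msr_acc <- 0  # mean squared residual, drives the TG scale update
      for (s in seq_len(n_particles)) {
        gam <- lapply(par[seq_len(n_modes)], exp)
        mu_q <- lapply(par[n_modes + seq_len(n_modes)], exp)
        del <- mapply(`/`, gam, mu_q, SIMPLIFY = FALSE)
        z <- vector("list", n_modes)
        for (k in seq_len(n_modes)) {
          zz <- stats::rgamma(dims[k] * R, shape = gam[[k]], rate = del[[k]])
          z[[k]] <- matrix(pmax(zz, 1e-12), dims[k], R)
        }
        gate <- zeta <- epsg <- NULL
        if (spec$noise_model == "zip") {
          epsg <- stats::rnorm(n_gate)
          zeta <- par[[idx_gmu]] + exp(par[[idx_gsd]]) * epsg
          gate <- stats::plogis(zeta)
        }
        tau <- if (!is.null(idx_tau)) exp(par[[idx_tau]]) else NULL

        kr_rest <- kr_prod(z[-1])                      # prod(dims[-1]) x R
        lam_mat <- z[[1]] %*% t(kr_rest)               # dims[1] x rest
        lam <- pmax(as.double(lam_mat), 1e-10)

        # observation log-likelihood and dloglik/dlambda, specialized per
        # noise model (shares exp(-lam) between ELBO and gradient terms)
        dll_gate <- NULL
        if (spec$noise_model == "gamma_poisson") {
          lam_nz <- lam[inz]
          ll <- sum(xnz * log(lam_nz)) - sum(lam) - lgx_sum
          dld <- xv / lam - 1
        } else if (spec$noise_model == "zip") {
          pz <- if (n_gate > 1L) rep(gate, each = gate_rep)[izw] else gate
          pnzv <- if (n_gate > 1L) rep(gate, each = gate_rep)[inz] else gate
          lam_nz <- lam[inz]
          el <- exp(-lam[izw])
          denom <- pz + (1 - pz) * el
          ll <- sum(log(denom)) + sum(log1p(-pnzv)) +
            sum(xnz * log(lam_nz) - lam_nz) - lgx_sum
          dld <- numeric(length(xv))
          dld[inz] <- xnz / lam_nz - 1
          dld[izw] <- -(1 - pz) * el / denom
          dllp <- numeric(length(xv))
          dllp[izw] <- (1 - el) / denom
          dllp[inz] <- -1 / (1 - pnzv)
          dll_gate <- if (n_gate > 1L) {
            colSums(matrix(dllp, gate_rep, n_gate))
          } else sum(dllp)
        } else {
          ll <- sum(truncnorm_log_pdf(xv, lam, tau))
          dld <- d_loglik_d_lambda(xv, lam, spec, scale = tau)
        }
        dlam <- array(dld, dim = dims)
        lp <- ll
        lq <- 0
        for (k in seq_len(n_modes)) {
          lp <- lp + sum(stats::dgamma(z[[k]], spec$prior_shape[k],
                                       rate = spec$prior_rate[k], log = TRUE))
          lq <- lq + sum(stats::dgamma(z[[k]], shape = gam[[k]],
                                       rate = del[[k]], log = TRUE))
        }
        if (!is.null(zeta)) {
          lp <- lp + sum(stats::dnorm(zeta, spec$gate_prior_mean,
                                      spec$gate_prior_sd, log = TRUE))
          lq <- lq + sum(stats::dnorm(zeta, par[[idx_gmu]],
                                      exp(par[[idx_gsd]]), log = TRUE))
        }
        if (!is.finite(lp) || !is.finite(lq)) {
          stop(sprintf("non-finite ELBO term at iteration %d", iter),
               call. = FALSE)
        }
        elbo_acc <- elbo_acc + (lp - lq)

        if (gradient == "pathwise") {
          for (k in seq_len(n_modes)) {
            gk <- if (k == 1L) {
              matrix(dld, dims[1]) %*% kr_rest
            } else {
              unfold(dlam, k) %*% kr_prod(z[-k])
            }
            # d log joint / d z  minus  d log q / d z
            gz <- gk + (spec$prior_shape[k] - 1) / z[[k]] - spec$prior_rate[k] -
              ((gam[[k]] - 1) / z[[k]] - del[[k]])
            u <- z[[k]] * del[[k]]
            du <- matrix(gamma_shape_grad(as.double(u), as.double(gam[[k]])),
                         dims[k], R)
            # z = u * mean / conc: dz/dlog(conc) = mean*du - z,
            # dz/dlog(mean) = z
            grad[[k]] <- grad[[k]] + gz * (mu_q[[k]] * du - z[[k]])
            grad[[n_modes + k]] <- grad[[n_modes + k]] + gz * z[[k]]
          }
          if (!is.null(zeta)) {
            gzeta <- dll_gate * gate * (1 - gate) -
              (zeta - spec$gate_prior_mean) / spec$gate_prior_sd^2 +
              (zeta - par[[idx_gmu]]) / exp(par[[idx_gsd]])^2
            grad[[idx_gmu]] <- grad[[idx_gmu]] + gzeta
            grad[[idx_gsd]] <- grad[[idx_gsd]] +
              gzeta * epsg * exp(par[[idx_gsd]])
          }
          if (!is.null(idx_tau)) {
            msr_acc <- msr_acc + mean((xv - lam)^2)
          }
        } else {
          # score-function estimator with running-mean baseline
          f <- lp - lq
          if (!exists("sf_baseline", inherits = FALSE)) sf_baseline <- f
          w <- f - sf_baseline
          sf_baseline <- 0.9 * sf_baseline + 0.1 * f
          for (k in seq_len(n_modes)) {
            dlq_dg <- log(del[[k]]) - digamma(gam[[k]]) + log(z[[k]])
            dlq_dd <- gam[[k]] / del[[k]] - z[[k]]
            # chain rule through conc = gam, delta = conc / mean
            slc <- dlq_dg * gam[[k]] + dlq_dd * del[[k]]
            slm <- -dlq_dd * del[[k]]
            grad[[k]] <- grad[[k]] + w * slc
            grad[[n_modes + k]] <- grad[[n_modes + k]] + w * slm
          }
          if (!is.null(zeta)) {
            sd_g <- exp(par[[idx_gsd]])
            smu <- (zeta - par[[idx_gmu]]) / sd_g^2
            ssd <- ((zeta - par[[idx_gmu]])^2 / sd_g^2 - 1)
            grad[[idx_gmu]] <- grad[[idx_gmu]] + w * smu
            grad[[idx_gsd]] <- grad[[idx_gsd]] + w * ssd
          }
          if (!is.null(idx_tau)) {
            msr_acc <- msr_acc + mean((xv - lam)^2)
          }
        }
      }
      for (i in seq_along(grad)) {
        grad[[i]] <- grad[[i]] / n_particles
        if (anyNA(grad[[i]]) || any(!is.finite(grad[[i]]))) {
          stop(sprintf("non-finite gradient at iteration %d", iter),
               call. = FALSE)
        }
      }
      elbo_trace[iter] <- elbo_acc / n_particles
      # diminishing step schedule within the polish phase
      lr_t <- if (iter < phase2_at) {
        learning_rate
      } else if (iter - phase2_at < polish %/% 2L) {
        learning_rate / 3
      } else {
        learning_rate / 10
      }
      up <- adam_step(par, grad, opt, lr = lr_t)
      par <- up$par
      opt <- up$st
      if (!is.null(idx_tau)) {
        # coordinate-style scale update: tau tracks the RMS residual
        par[[idx_tau]] <- 0.5 * log(max(msr_acc / n_particles, 1e-12))
      }

      if (iter >= phase2_at + polish %/% 2L) {
        for (k in seq_len(n_modes)) {
          avg_mu[[k]] <- avg_mu[[k]] + exp(par[[n_modes + k]])
        }
        if (!is.null(idx_gmu)) {
          avg_extra$gmu <- avg_extra$gmu + par[[idx_gmu]]
          avg_extra$gsd <- avg_extra$gsd + exp(par[[idx_gsd]])
        }
        if (!is.null(idx_tau)) {
          avg_extra$tau <- avg_extra$tau + exp(par[[idx_tau]])
        }
        avg_n <- avg_n + 1L
      }

      if (iter >= phase2_at + polish - 1L) {
        iter_done <- iter
        break
      }
      if (iter < phase2_at && iter >= 2L * window && tol > 0) {
        m1 <- mean(elbo_trace[(iter - window + 1L):iter])
        m2 <- mean(elbo_trace[(iter - 2L * window + 1L):(iter - window)])
        if (abs(m1 - m2) / (abs(m2) + 1e-12) < tol) {
          converged <- TRUE
          phase2_at <- iter + 1L  # enter the polish phase early
        }
      }
    }
    if (avg_n > 0L) {
      mu_fin <- lapply(avg_mu, function(m) m / avg_n)
      gmu_fin <- if (!is.null(idx_gmu)) avg_extra$gmu / avg_n else NULL
      gsd_fin <- if (!is.null(idx_gmu)) avg_extra$gsd / avg_n else NULL
      tau_fin <- if (!is.null(idx_tau)) avg_extra$tau / avg_n else NULL
    } else {
      mu_fin <- lapply(par[n_modes + seq_len(n_modes)], exp)
      gmu_fin <- if (!is.null(idx_gmu)) par[[idx_gmu]] else NULL
      gsd_fin <- if (!is.null(idx_gmu)) exp(par[[idx_gsd]]) else NULL
      tau_fin <- if (!is.null(idx_tau)) exp(par[[idx_tau]]) else NULL
    }
    list(par = par, mu = mu_fin, gmu = gmu_fin, gsd = gsd_fin,
         tau = tau_fin, elbo_trace = elbo_trace[seq_len(iter_done)],
         converged = converged, iterations = iter_done,
         idx_gmu = idx_gmu, idx_gsd = idx_gsd, idx_tau = idx_tau)
  })

  gam <- lapply(run$par[seq_len(n_modes)], exp)
  del <- mapply(function(g, m) g / m, gam, run$mu, SIMPLIFY = FALSE)
  state <- variational_state(
    gamma = gam, delta = del,
    gate_mean = run$gmu, gate_sd = run$gsd, scale = run$tau,
    elbo_trace = run$elbo_trace)
  pe <- point_estimate(state, mode_names = xt$mode_names,
                       axis_labels = xt$axis_labels)
  ev <- if (all(xv == 0)) NA_real_ else
    explained_variance(xt, reconstruct(pe))
  structure(
    list(point_estimate = pe, state = state, spec = spec,
         explained_variance = ev,
         gate = if (spec$noise_model == "zip")
           stats::plogis(state$gate_mean) else NULL,
         seed = seed, converged = run$converged,
         iterations = run$iterations),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s rank %d | EV vs input %.4f | %d iterations%s\n",
    x$spec$noise_model, x$spec$rank, x$explained_variance, x$iterations,
    if (x$converged) " (converged)" else ""))
  if (!is.null(x$gate)) {
    cat(sprintf("  posterior mean excess-zero probability: %.3f\n",
                mean(x$gate)))
  }
  invisible(x)
}

#' Serialize / load a fit result
#'
#' Factor matrices are written as one delimited table per mode via
#' [write_cp_factors()]; the model spec, seed, ELBO trace and convergence
#' information go to a JSON sidecar.
#'
#' @param fit a `fit_result`.
#' @param dir output directory.
#' @return `dir` invisibly for the writer; a reduced `fit_result` (point
#'   estimate + metadata) for the reader.
#' @export
write_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "fit_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cp_factors(fit$point_estimate, file.path(dir, "factors"))
  meta <- list(spec = unclass(fit$spec), seed = fit$seed,
               explained_variance = fit$explained_variance,
               gate = fit$gate, converged = fit$converged,
               iterations = fit$iterations, elbo_trace = fit$state$elbo_trace)
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  pe <- read_cp_factors(file.path(dir, "factors"))
  spec <- meta$spec
  sp <- model_spec(spec$noise_model, rank = spec$rank, n_modes = spec$n_modes,
                   prior_shape = spec$prior_shape,
                   prior_rate = spec$prior_rate,
                   gate_prior_mean = spec$gate_prior_mean,
                   gate_prior_sd = spec$gate_prior_sd,
                   gate_mode = spec$gate_mode)
  structure(
    list(point_estimate = pe, state = NULL, spec = sp,
         explained_variance = meta$explained_variance, gate = meta$gate,
         seed = meta$seed, converged = meta$converged,
         iterations = meta$iterations),
    class = "fit_result"
  )
}
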