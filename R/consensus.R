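# Consensus meta-analysis over repeated factorization runs: aggregate and
# normalize factor matrices, cluster their columns, prune outliers, take
# cluster medians, and refit with the consensus matrix as initialization.
# Also hosts the rank-selection diagnostics (explained variance, cophenetic
# correlation, silhouette).

#' Bundle repeated factorization runs at a common rank
#'
#' @param runs list of `fit_result` objects sharing rank, tensor shape and
#'   model spec.
#' @param mode_of_interest the mode whose factors are aggregated for
#'   consensus (defaults to the last mode, typically genes).
#' @return an object of class `run_ensemble`.
#' @export
run_ensemble <- function(runs, mode_of_interest = NULL) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  ranks <- vapply(runs, function(f) f$spec$rank, integer(1))
  if (length(unique(ranks)) != 1L) {
    stop("all runs must share the same rank", call. = FALSE)
  }
  shapes <- lapply(runs, function(f)
    vapply(f$point_estimate$factors, nrow, integer(1)))
  if (length(unique(vapply(shapes, paste, character(1),
                           collapse = "x"))) != 1L) {
    stop("all runs must share the tensor shape", call. = FALSE)
  }
  n_modes <- length(runs[[1]]$point_estimate$factors)
  k <- mode_of_interest %||% n_modes
  if (k < 1L || k > n_modes) stop("invalid `mode_of_interest`", call. = FALSE)
  structure(list(runs = runs, rank = ranks[1],
                 mode_of_interest = as.integer(k)),
            class = "run_ensemble")
}

#' Aggregate and Frobenius-normalize factor matrices across runs
#'
#' Horizontally concatenates each run's mode-of-interest factor matrix after
#' dividing it by its own Frobenius norm, giving an `I_k x (R * M)` matrix
#' whose M blocks each have unit Frobenius norm.
#'
#' @param ens a `run_ensemble`.
#' @return the aggregated matrix; column attribute `run` records block
#'   membership.
#' @export
aggregate_runs <- function(ens) {
  stopifnot(inherits(ens, "run_ensemble"))
  k <- ens$mode_of_interest
  blocks <- lapply(ens$runs, function(f) {
    m <- f$point_estimate$factors[[k]]
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) stop("a run has a zero-norm factor matrix", call. = FALSE)
    m / nrm
  })
  agg <- do.call(cbind, blocks)
  attr(agg, "run") <- rep(seq_along(blocks), each = ens$rank)
  agg
}

# Classic k-NN Local Outlier Factor. Returns LOF scores (~1 for inliers).
local_outlier_factor <- function(points, k) {
  n <- nrow(points)
  if (n < 3L || k < 1L) return(rep(1, n))
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  knn_idx <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) d[i, knn_idx[i, k]], numeric(1))
  lrd <- vapply(seq_len(n), function(i) {
    nb <- knn_idx[i, ]
    reach <- pmax(kdist[nb], d[i, nb])
    1 / max(mean(reach), 1e-12)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    mean(lrd[knn_idx[i, ]]) / lrd[i]
  }, numeric(1))
}

#' Cluster aggregated factor columns and prune outliers
#'
#' K-means (Euclidean, 10 restarts, seeded) on the columns of the aggregated
#' factor matrix, followed by per-cluster Local Outlier Factor pruning:
#' within each cluster, points whose LOF exceeds both 1.5 and the
#' `1 - contamination` LOF quantile are masked out. Singleton clusters are
#' masked entirely (a lone column cannot form a consensus).
#'
#' @param agg aggregated matrix from [aggregate_runs()] (columns are points).
#' @param K number of clusters (the rank).
#' @param seed integer seed for the K-means restarts.
#' @param lof_neighbors LOF neighborhood size; default `min(20, size - 1)`
#'   per cluster.
#' @param contamination assumed outlier fraction per cluster.
#' @return list with `labels` (integer per column, `NA` for outliers) and
#'   `retained` (logical mask).
#' @export
cluster_columns <- function(agg, K, seed = 1L, lof_neighbors = 20L,
                            contamination = 0.05) {
  pts <- t(agg)
  if (K < 2L) stop("`K` must be >= 2", call. = FALSE)
  if (K > nrow(pts)) stop("`K` exceeds the number of columns", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(pts, centers = K, nstart = 10L,
                                      iter.max = 50L))
  labels <- km$cluster
  retained <- rep(TRUE, length(labels))
  for (cl in seq_len(K)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      retained[idx] <- FALSE
      next
    }
    kk <- min(lof_neighbors, length(idx) - 1L)
    lof <- local_outlier_factor(pts[idx, , drop = FALSE], kk)
    thr <- max(1.5, stats::quantile(lof, 1 - contamination, names = FALSE))
    retained[idx[lof > thr]] <- FALSE
  }
  out_labels <- labels
  out_labels[!retained] <- NA_integer_
  attr(out_labels, "kmeans_labels") <- labels
  list(labels = out_labels, retained = retained)
}

#' Mean silhouette coefficient of a clustering
#'
#' For each point, `(b - a) / max(a, b)` with `a` the mean distance to the
#' other members of its cluster and `b` the smallest mean distance to another
#' cluster; returns the mean over points. Euclidean distance.
#'
#' @param points numeric matrix, one row per point.
#' @param labels cluster labels (>= 2 distinct, all clusters non-empty).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette requires >= 2 clusters", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(cl, labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    if (!any(own)) s[i] <- 0  # singleton convention
  }
  mean(s)
}

#' Silhouette sweep over cluster counts
#'
#' For each candidate K, K-means on the columns of the aggregated factor
#' matrix (all columns, no outlier pruning -- this is the rank diagnostic,
#' not the consensus pipeline) and the mean silhouette of the clustering.
#'
#' @param agg aggregated matrix from [aggregate_runs()].
#' @param ks integer vector of candidate cluster counts.
#' @param seed integer seed for the K-means restarts.
#' @return data frame with columns `k` and `silhouette` (`NA` where K-means
#'   is infeasible, e.g. K exceeding the distinct columns).
#' @export
silhouette_sweep <- function(agg, ks, seed = 1L) {
  pts <- t(agg)
  sil <- vapply(ks, function(K) {
    tryCatch({
      km <- with_seed(derive_seed(seed, "sweep", K),
                      stats::kmeans(pts, centers = K, nstart = 10L,
                                    iter.max = 50L))
      silhouette_score(pts, km$cluster)
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(k = as.integer(ks), silhouette = sil)
}

#' Entrywise-median consensus factors
#'
#' Column `i` of the result is the entrywise median of the retained aggregated
#' columns assigned to cluster `i`.
#'
#' @param agg aggregated matrix from [aggregate_runs()].
#' @param labels per-column integer labels in `1..R` with `NA` for pruned
#'   outliers (as returned by [cluster_columns()]).
#' @return an `I_k x R` non-negative matrix.
#' @export
consensus_factors <- function(agg, labels) {
  R <- max(labels, na.rm = TRUE)
  out <- matrix(0, nrow(agg), R)
  for (cl in seq_len(R)) {
    idx <- which(!is.na(labels) & labels == cl)
    if (length(idx) == 0L) {
      stop(sprintf("cluster %d is empty after outlier pruning", cl),
           call. = FALSE)
    }
    out[, cl] <- apply(agg[, idx, drop = FALSE], 1, stats::median)
  }
  out
}

#' Cophenetic correlation of max-loading assignments across runs
#'
#' Each run assigns every feature (row of the mode-of-interest factor matrix)
#' to its maximum-loading factor, after normalizing factor columns to unit
#' norm (CP factors carry an arbitrary scale split across modes; without
#' normalization the assignment would reflect that arbitrary scale rather
#' than factor shape). The M-run average connectivity matrix over
#' features is turned into a distance (1 - connectivity), hierarchically
#' clustered with average linkage, and the correlation between the input
#' distances and the dendrogram's cophenetic distances is returned. A value
#' near 1 indicates stable factor assignment across runs.
#'
#' @param ens a `run_ensemble` with at least 2 runs.
#' @param max_features connectivity is computed on a seeded subsample of at
#'   most this many features (large gene modes).
#' @param seed subsampling seed.
#' @return scalar in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(ens, max_features = 2000L, seed = 1L) {
  stopifnot(inherits(ens, "run_ensemble"))
  if (length(ens$runs) < 2L) stop("need at least 2 runs", call. = FALSE)
  k <- ens$mode_of_interest
  n_feat <- nrow(ens$runs[[1]]$point_estimate$factors[[k]])
  if (n_feat < 2L) stop("need at least 2 features", call. = FALSE)
  keep <- if (n_feat > max_features) {
    with_seed(seed, sort(sample.int(n_feat, max_features)))
  } else seq_len(n_feat)
  conn <- matrix(0, length(keep), length(keep))
  for (f in ens$runs) {
    m <- f$point_estimate$factors[[k]][keep, , drop = FALSE]
    # CP factors carry an arbitrary scale split across modes; normalize the
    # columns so the max-loading assignment reflects shape, not scale
    nrm <- sqrt(colSums(m^2))
    m <- sweep(m, 2, pmax(nrm, 1e-300), "/")
    assign <- max.col(m, ties.method = "first")
    conn <- conn + outer(assign, assign, "==")
  }
  conn <- conn / length(ens$runs)
  d <- stats::as.dist(1 - conn)
  if (stats::sd(d) == 0) return(1)  # all runs fully agree
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

# Rescale the consensus matrix back to the typical factor scale of the runs
# (aggregation normalizes each run's matrix to unit Frobenius norm).
rescale_consensus <- function(cons, ens) {
  k <- ens$mode_of_interest
  norms <- vapply(ens$runs, function(f) {
    sqrt(sum(f$point_estimate$factors[[k]]^2))
  }, numeric(1))
  cn <- sqrt(sum(cons^2))
  if (cn == 0) return(cons)
  cons / cn * mean(norms)
}

#' Consensus refit: aggregate, cluster, prune, median, refit
#'
#' Runs the consensus pipeline over an ensemble of factorization runs and
#' refits the model with the consensus matrix as the initial variational mean
#' of the mode of interest (other modes initialize from the prior under
#' `seed`). Setting `freeze = TRUE` keeps the consensus mode fixed instead of
#' optimizing it (sensitivity checks).
#'
#' @param x the `count_tensor` the runs were fitted to.
#' @param ens a `run_ensemble` (M >= 2 runs).
#' @param spec the `model_spec` for the refit (defaults to the runs' spec).
#' @param seed integer seed for clustering and the refit.
#' @param freeze keep the consensus mode fixed during the refit.
#' @param ... further arguments passed to [fit_bayes_cp()].
#' @return a `consensus_model`: list with `aggregated`, `cluster_labels`,
#'   `retained`, `silhouette`, `consensus_factors`, `final_fit`.
#' @export
refit_consensus <- function(x, ens, spec = NULL, seed = 1L, freeze = FALSE,
                            ...) {
  stopifnot(inherits(ens, "run_ensemble"))
  if (length(ens$runs) < 2L) stop("consensus requires M >= 2 runs",
                                  call. = FALSE)
  spec <- spec %||% ens$runs[[1]]$spec
  agg <- aggregate_runs(ens)
  cl <- cluster_columns(agg, K = ens$rank,
                        seed = derive_seed(seed, "cluster"))
  # a consensus needs every cluster represented: if pruning emptied one
  # (e.g. a singleton cluster), restore its members
  km_labels <- attr(cl$labels, "kmeans_labels") %||% cl$labels
  for (g in seq_len(ens$rank)) {
    if (!any(!is.na(cl$labels) & cl$labels == g)) {
      members <- which(km_labels == g)
      cl$labels[members] <- g
      cl$retained[members] <- TRUE
    }
  }
  sil <- silhouette_score(t(agg)[cl$retained, , drop = FALSE],
                          cl$labels[cl$retained])
  cons <- consensus_factors(agg, cl$labels)
  cons_scaled <- rescale_consensus(cons, ens)
  k <- ens$mode_of_interest
  init <- vector("list", spec$n_modes)
  init[[k]] <- cons_scaled
  fit <- fit_bayes_cp(x, spec, seed = derive_seed(seed, "refit"),
                      init = init, ...)
  if (freeze) {
    pe <- fit$point_estimate
    pe$factors[[k]] <- cons_scaled
    fit$point_estimate <- pe
    fit$explained_variance <- explained_variance(x, reconstruct(pe))
  }
  structure(
    list(aggregated = agg, cluster_labels = cl$labels,
         retained = cl$retained, silhouette = sil,
         consensus_factors = cons, final_fit = fit),
    class = "consensus_model"
  )
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf(
    "<consensus_model> %d runs, rank %d | silhouette %.3f | final EV %.4f\n",
    length(unique(attr(x$aggregated, "run"))),
    max(x$cluster_labels, na.rm = TRUE), x$silhouette,
    x$final_fit$explained_variance))
  invisible(x)
}

#' One-call consensus factorization (e.g. C-ZIPTF)
#'
#' Convenience wrapper: M independently seeded fits, then [refit_consensus()].
#'
#' @param x a `count_tensor`.
#' @param spec a `model_spec`.
#' @param M number of random restarts.
#' @param seed root seed; run m uses `derive_seed(seed, "run", m)`.
#' @param mode_of_interest consensus mode (default last).
#' @param ... passed to [fit_bayes_cp()].
#' @return a `consensus_model`; the input runs are attached as `$ensemble`.
#' @export
consensus_fit <- function(x, spec, M = 10L, seed = 1L,
                          mode_of_interest = NULL, ...) {
  runs <- lapply(seq_len(M), function(m) {
    fit_bayes_cp(x, spec, seed = derive_seed(seed, "run", m), ...)
  })
  ens <- run_ensemble(runs, mode_of_interest = mode_of_interest)
  out <- refit_consensus(x, ens, spec = spec, seed = seed, ...)
  out$ensemble <- ens
  out
}

#' Rank-selection scan with consensus diagnostics
#'
#' For each candidate rank: M seeded fits, mean/SD explained variance (vs the
#' input tensor), cophenetic correlation of max-loading assignments, and a
#' silhouette sweep over cluster counts of the aggregated columns. The
#' selected rank is the smallest one whose mean explained variance and
#' cophenetic correlation both reach `threshold`; each row also records
#' whether the silhouette peaks at K = rank.
#'
#' @param x a `count_tensor`.
#' @param ranks increasing integer vector of candidate ranks.
#' @param M restarts per rank (>= 2).
#' @param spec_for function(rank) returning the `model_spec` at that rank, or
#'   a `model_spec` template whose rank is overwritten.
#' @param seed root seed.
#' @param threshold selection threshold for both criteria.
#' @param cluster_counts candidate K values for the silhouette sweep
#'   (default `2 .. min(2 * rank, R * M - 1)`).
#' @param ... passed to [fit_bayes_cp()].
#' @return a `rank_selection_report`: data frame of per-rank metrics plus
#'   attribute `selected_rank` (`NA` if no rank qualifies, with a warning).
#' @export
select_rank <- function(x, ranks, M = 5L, spec_for, seed = 1L,
                        threshold = 0.9, cluster_counts = NULL, ...) {
  stopifnot(length(ranks) >= 1L, M >= 2L)
  if (any(diff(ranks) <= 0)) stop("`ranks` must be strictly increasing",
                                  call. = FALSE)
  make_spec <- if (is.function(spec_for)) {
    spec_for
  } else {
    template <- spec_for
    function(r) { template$rank <- as.integer(r); template }
  }
  rows <- lapply(ranks, function(r) {
    sp <- make_spec(r)
    runs <- lapply(seq_len(M), function(m) {
      fit_bayes_cp(x, sp, seed = derive_seed(seed, paste0("rank", r), m), ...)
    })
    evs <- vapply(runs, function(f) f$explained_variance, numeric(1))
    ens <- run_ensemble(runs)
    coph <- cophenetic_correlation(ens, seed = derive_seed(seed, "coph", r))
    agg <- aggregate_runs(ens)
    ks <- cluster_counts %||% seq(2L, max(2L, min(2L * r, ncol(agg) - 1L)))
    sil <- silhouette_sweep(agg, ks,
                            seed = derive_seed(seed, "sil", r))$silhouette
    best <- if (all(is.na(sil))) NA_integer_ else which.max(sil)
    data.frame(rank = r, ev_mean = mean(evs), ev_sd = stats::sd(evs),
               cophenetic = coph,
               silhouette_peak_k = if (is.na(best)) NA_integer_ else ks[best],
               silhouette = if (is.na(best)) NA_real_ else sil[best])
  })
  report <- do.call(rbind, rows)
  ok <- report$ev_mean >= threshold & report$cophenetic >= threshold
  sel <- if (any(ok)) report$rank[which(ok)[1]] else NA_integer_
  if (is.na(sel)) {
    warning("no rank satisfies both explained-variance and cophenetic ",
            "thresholds", call. = FALSE)
  }
  attr(report, "selected_rank") <- sel
  class(report) <- c("rank_selection_report", class(report))
  report
}

#' Write a rank-selection report
#'
#' Delimited table of the per-rank metrics plus a JSON summary with the
#' selected rank.
#'
#' @param report a `rank_selection_report`.
#' @param path output path stem; writes `<path>.tsv` and `<path>.json`.
#' @return `path` invisibly.
#' @export
write_rank_report <- function(report, path) {
  utils::write.table(as.data.frame(report), paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(selected_rank = attr(report, "selected_rank"),
         ranks = report$rank),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
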