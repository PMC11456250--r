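# Scoring recovered factors against ground-truth gene expression programs and
# measuring run-to-run consistency.

# Kuhn-Munkres (Hungarian) algorithm for the square min-cost assignment
# problem. O(n^3) shortest-augmenting-path formulation with potentials.
# Returns, for each row, the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(n) + 1L) {
    if (p[j] > 0L) match_col[p[j]] <- j - 1L
  }
  match_col
}

# Maximum-total-score one-to-one assignment on a (possibly rectangular)
# score matrix; unmatched rows/columns (rectangular case) get 0 via padding.
assign_max <- function(score) {
  r <- nrow(score)
  p <- ncol(score)
  n <- max(r, p)
  cost <- matrix(0, n, n)
  cost[seq_len(r), seq_len(p)] <- -score
  m <- hungarian(cost)
  out <- m[seq_len(r)]
  out[out > p] <- NA_integer_
  out
}

#' Align recovered factors to ground-truth programs
#'
#' Computes the full Pearson correlation matrix between factor columns and
#' truth columns over a shared gene axis, then establishes a one-to-one
#' alignment maximizing the total correlation (optimal bipartite assignment,
#' not greedy). Columns with zero variance get correlation 0 with a warning.
#'
#' @param gene_factors genes x R matrix of recovered gene loadings.
#' @param truth genes x P matrix of ground-truth program weights (same gene
#'   order).
#' @return an `alignment_result`: list with `matching` (per factor, the
#'   matched truth column or `NA`), `per_pair_r`, `mean_r`,
#'   `correlation_matrix`.
#' @export
align_factors <- function(gene_factors, truth) {
  gene_factors <- as.matrix(gene_factors)
  truth <- as.matrix(truth)
  if (nrow(gene_factors) != nrow(truth)) {
    stop("factor and truth matrices must share the gene axis", call. = FALSE)
  }
  const_f <- apply(gene_factors, 2, stats::sd) == 0
  const_t <- apply(truth, 2, stats::sd) == 0
  if (any(const_f) || any(const_t)) {
    warning("constant columns found; their correlations are set to 0",
            call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(gene_factors, truth))
  cm[!is.finite(cm)] <- 0
  matching <- assign_max(cm)
  pairs <- which(!is.na(matching))
  per_pair <- cm[cbind(pairs, matching[pairs])]
  structure(
    list(matching = matching, per_pair_r = per_pair,
         mean_r = mean(per_pair), correlation_matrix = cm),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d matched pairs, mean r = %.3f\n",
              length(x$per_pair_r), x$mean_r))
  invisible(x)
}

#' Recovery score of a method over repeated runs
#'
#' Applies [align_factors()] to the gene-mode factors of each run and
#' aggregates the matched mean correlations, giving the method's overall
#' accuracy at recovering the ground-truth programs.
#'
#' @param method_runs list of `fit_result` (or `consensus_model`) objects.
#' @param truth genes x P ground-truth program matrix.
#' @param mode gene mode index (default last).
#' @return list with `mean`, `sd`, `per_run` mean correlations.
#' @export
recovery_score <- function(method_runs, truth, mode = NULL) {
  stopifnot(length(method_runs) >= 1L)
  per_run <- vapply(method_runs, function(f) {
    if (inherits(f, "consensus_model")) f <- f$final_fit
    k <- mode %||% length(f$point_estimate$factors)
    align_factors(f$point_estimate$factors[[k]], truth)$mean_r
  }, numeric(1))
  list(mean = mean(per_run),
       sd = if (length(per_run) > 1L) stats::sd(per_run) else NA_real_,
       per_run = per_run)
}

#' Pairwise cosine-score consistency of repeated runs
#'
#' [cosine_score()] for every unordered pair of runs; the distribution of
#' scores measures run-to-run stability of the factorization.
#'
#' @param runs list of >= 2 `fit_result` (or `consensus_model`) objects at a
#'   common rank.
#' @return numeric vector of pairwise scores.
#' @export
run_consistency <- function(runs) {
  stopifnot(length(runs) >= 2L)
  fac <- lapply(runs, function(f) {
    if (inherits(f, "consensus_model")) f <- f$final_fit
    f$point_estimate
  })
  ranks <- vapply(fac, function(f) f$rank, integer(1))
  if (length(unique(ranks)) != 1L) stop("rank mismatch across runs",
                                        call. = FALSE)
  pairs <- utils::combn(length(fac), 2)
  apply(pairs, 2, function(ij) cosine_score(fac[[ij[1]]], fac[[ij[2]]]))
}

#' Write an evaluation report
#'
#' Per-run matched correlations as a delimited table, the correlation matrix
#' of the first run as a delimited matrix, and a JSON summary.
#'
#' @param score result of [recovery_score()].
#' @param path output path stem (`<path>.tsv`, `<path>.json`).
#' @param correlation_matrix optional matrix to write as `<path>_cor.tsv`.
#' @return `path` invisibly.
#' @export
write_evaluation <- function(score, path, correlation_matrix = NULL) {
  utils::write.table(
    data.frame(run = seq_along(score$per_run), mean_r = score$per_run),
    paste0(path, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(mean = score$mean, sd = score$sd),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(correlation_matrix)) {
    utils::write.table(correlation_matrix, paste0(path, "_cor.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
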