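# Shared in-code fixtures and independent oracles for the test suite.

# tiny deterministic 2x2x2 tensor with entries 1..8
tiny_tensor <- function() count_tensor(array(1:8, c(2, 2, 2)))

# rank-1 factor set a = (1, 2), b = (1, 1), c = (1, 0)
tiny_rank1 <- function() {
  cp_factors(list(matrix(c(1, 2), 2, 1), matrix(c(1, 1), 2, 1),
                  matrix(c(1, 0), 2, 1)))
}

# random non-negative factor set
rand_factors <- function(dims, rank, seed = 1) {
  set.seed(seed)
  cp_factors(lapply(dims, function(d) {
    matrix(rgamma(d * rank, 2, 0.5), d, rank)
  }))
}

# brute-force maximum-assignment oracle (for small matrices)
brute_force_assign <- function(score) {
  n <- nrow(score)
  stopifnot(ncol(score) == n, n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_val <- -Inf
  for (p in perms(seq_len(n))) {
    val <- sum(score[cbind(seq_len(n), p)])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(assignment = best, value = best_val)
}

# wrap plain factor matrices as a minimal fit_result for ensemble helpers
fake_fit <- function(factors, rank = ncol(factors[[1]]),
                     noise_model = "zip") {
  structure(
    list(point_estimate = cp_factors(factors),
         state = NULL,
         spec = model_spec(noise_model, rank = rank,
                           n_modes = length(factors)),
         explained_variance = NA_real_, gate = NULL, seed = 0L,
         converged = TRUE, iterations = 0L),
    class = "fit_result")
}

# small annotated cell matrix: 4 cells, 2 samples x 2 types x 3 genes
tiny_cells <- function() {
  counts <- rbind(c(1, 2, 3),    # s1 tA
                  c(4, 0, 1),    # s1 tB
                  c(2, 2, 2),    # s2 tA
                  c(0, 5, 0))    # s2 tB
  meta <- data.frame(barcode = paste0("c", 1:4),
                     sample = c("s1", "s1", "s2", "s2"),
                     cell_type = c("tA", "tB", "tA", "tB"))
  cell_count_matrix(counts, meta, c("g1", "g2", "g3"))
}
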