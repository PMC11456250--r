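#' Count tensor container
#'
#' A dense N-way array of non-negative values (raw or normalized counts) with
#' named modes and optional per-mode axis labels (sample IDs, cell-type names,
#' gene symbols). This is the basic data container consumed by the
#' factorization, consensus and pseudobulk machinery.
#'
#' @param data numeric array of order N >= 2 with non-negative finite entries.
#' @param mode_names character vector of length N naming the modes; defaults
#'   to `mode1..modeN`.
#' @param axis_labels optional list of length N of character vectors labelling
#'   each axis; each must match the corresponding dimension.
#' @return an object of class `count_tensor`.
#' @export
count_tensor <- function(data, mode_names = NULL, axis_labels = NULL) {
  if (!is.array(data) || length(dim(data)) < 2L) {
    stop("`data` must be an array of order >= 2", call. = FALSE)
  }
  if (length(data) == 0L) stop("tensor must be non-empty", call. = FALSE)
  if (!is.numeric(data)) stop("tensor entries must be numeric", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("tensor entries must be finite", call. = FALSE)
  }
  if (any(data < 0)) stop("tensor entries must be non-negative", call. = FALSE)
  n <- length(dim(data))
  if (is.null(mode_names)) mode_names <- paste0("mode", seq_len(n))
  if (length(mode_names) != n) {
    stop("`mode_names` must have one name per mode", call. = FALSE)
  }
  if (!is.null(axis_labels)) {
    if (!is.list(axis_labels) || length(axis_labels) != n) {
      stop("`axis_labels` must be a list with one element per mode", call. = FALSE)
    }
    for (k in seq_len(n)) {
      if (!is.null(axis_labels[[k]]) &&
          length(axis_labels[[k]]) != dim(data)[k]) {
        stop(sprintf("axis labels for mode %d do not match its size", k),
             call. = FALSE)
      }
    }
  }
  structure(
    list(data = data, mode_names = as.character(mode_names),
         axis_labels = axis_labels),
    class = "count_tensor"
  )
}

#' @export
print.count_tensor <- function(x, ...) {
  dims <- paste(dim(x$data), collapse = " x ")
  cat(sprintf("<count_tensor> %s (%s)\n", dims,
              paste(x$mode_names, collapse = ", ")))
  cat(sprintf("  sum = %.4g, zeros = %.1f%%\n", sum(x$data),
              100 * mean(x$data == 0)))
  invisible(x)
}

#' @export
dim.count_tensor <- function(x) dim(x$data)

as_tensor_array <- function(x) {
  if (inherits(x, "count_tensor")) x$data else x
}

#' Frobenius norm of a tensor
#'
#' Square root of the sum of squared entries, the direct tensor analogue of
#' the matrix Frobenius norm.
#'
#' @param x a `count_tensor` or numeric array.
#' @return a non-negative scalar.
#' @export
frobenius_norm <- function(x) {
  a <- as_tensor_array(x)
  if (length(a) == 0L) stop("tensor must be non-empty", call. = FALSE)
  sqrt(sum(as.double(a)^2))
}

#' Non-negative CP factor set
#'
#' Holds the per-mode factor matrices \eqn{A^{(k)} \in R_+^{I_k \times R}} of a
#' rank-R CP (Candecomp/Parafac) decomposition.
#'
#' @param factors list of N >= 2 non-negative matrices sharing a common column
#'   count R.
#' @param mode_names optional character vector of mode names.
#' @param axis_labels optional list of row labels per mode.
#' @return an object of class `cp_factors`.
#' @export
cp_factors <- function(factors, mode_names = NULL, axis_labels = NULL) {
  if (!is.list(factors) || length(factors) < 2L) {
    stop("`factors` must be a list of at least two matrices", call. = FALSE)
  }
  factors <- lapply(factors, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  ranks <- vapply(factors, ncol, integer(1))
  if (length(unique(ranks)) != 1L) {
    stop("all factor matrices must share the same column count (rank)",
         call. = FALSE)
  }
  if (ranks[1] < 1L) stop("rank must be >= 1", call. = FALSE)
  for (m in factors) {
    if (anyNA(m) || any(!is.finite(m))) {
      stop("factor entries must be finite", call. = FALSE)
    }
    if (any(m < 0)) stop("factor entries must be non-negative", call. = FALSE)
  }
  if (is.null(mode_names)) mode_names <- paste0("mode", seq_along(factors))
  structure(
    list(factors = factors, rank = ranks[1],
         mode_names = as.character(mode_names), axis_labels = axis_labels),
    class = "cp_factors"
  )
}

#' @export
print.cp_factors <- function(x, ...) {
  cat(sprintf("<cp_factors> rank %d, modes %s\n", x$rank,
              paste(vapply(x$factors, nrow, integer(1)), collapse = " x ")))
  invisible(x)
}

# Khatri-Rao style product over a list of matrices, with the *first* matrix's
# row index varying fastest. With factors supplied in mode order 1..N this
# makes rowSums(kr_prod(factors)) equal to vec() of the CP reconstruction
# (column-major, mode 1 fastest), matching R's array layout.
kr_prod <- function(mats) {
  out <- mats[[1]]
  if (length(mats) > 1L) {
    for (s in 2:length(mats)) {
      m <- mats[[s]]
      out <- out[rep.int(seq_len(nrow(out)), nrow(m)), , drop = FALSE] *
        m[rep(seq_len(nrow(m)), each = nrow(out)), , drop = FALSE]
    }
  }
  out
}

# Mode-k matricization: rows indexed by mode k, columns by the remaining
# modes in increasing order with the smallest remaining mode varying fastest
# (consistent with kr_prod over factors[-k]).
unfold <- function(a, k) {
  dims <- dim(a)
  n <- length(dims)
  perm <- c(k, setdiff(seq_len(n), k))
  m <- aperm(a, perm)
  dim(m) <- c(dims[k], prod(dims[-k]))
  m
}

# CP mean tensor as a plain array.
cp_reconstruct_array <- function(factors) {
  dims <- vapply(factors, nrow, integer(1))
  v <- rowSums(kr_prod(factors))
  array(v, dim = dims)
}

#' Reconstruct the CP approximation
#'
#' Expands a factor set into the dense tensor
#' \eqn{\tilde{X}_{i_1 \ldots i_N} = \sum_r \prod_k A^{(k)}[i_k, r]}.
#'
#' @param f a `cp_factors` object.
#' @return a `count_tensor` with the shape implied by the factors.
#' @export
reconstruct <- function(f) {
  stopifnot(inherits(f, "cp_factors"))
  count_tensor(cp_reconstruct_array(f$factors), mode_names = f$mode_names,
               axis_labels = f$axis_labels)
}

#' Explained variance of a tensor approximation
#'
#' Computes `1 - ||x - xhat||_F / ||x||_F` (a ratio of norms, not of squared
#' norms). The value is at most 1, and can be negative for approximations
#' worse than the zero tensor. `squared = TRUE` exposes the conventional
#' squared-norm variant.
#'
#' @param x reference tensor (`count_tensor` or array).
#' @param xhat approximation with the same shape.
#' @param squared if `TRUE`, use squared Frobenius norms.
#' @return a scalar `<= 1`.
#' @export
explained_variance <- function(x, xhat, squared = FALSE) {
  a <- as_tensor_array(x)
  b <- as_tensor_array(xhat)
  if (!identical(dim(a), dim(b))) {
    stop("`x` and `xhat` must have identical shapes", call. = FALSE)
  }
  nx <- sqrt(sum(as.double(a)^2))
  if (nx == 0) stop("`x` has zero Frobenius norm", call. = FALSE)
  nd <- sqrt(sum((as.double(a) - as.double(b))^2))
  if (squared) 1 - (nd / nx)^2 else 1 - nd / nx
}

cosine_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- Inf  # zero-norm columns contribute cosine 0
  sweep(m, 2, nrm, "/")
}

#' Cosine similarity score between two CP factorizations
#'
#' For factor sets \eqn{[[A,B,C,\ldots]]} and \eqn{[[D,E,F,\ldots]]} of common
#' rank R, returns
#' \deqn{\frac{1}{R}\sum_i \max_j \prod_k \cos(a^{(k)}_i, d^{(k)}_j),}
#' i.e. for each component i of the first factorization, the best-matching
#' component j of the second under the product of per-mode cosines. The max is
#' taken independently per i (a j may be reused), so the score is not a
#' one-to-one matching; use [align_factors()] for bijective alignment.
#' Non-negative factors give values in [0, 1]; zero-norm columns contribute 0.
#'
#' @param f1,f2 `cp_factors` objects with equal rank and mode shapes.
#' @return a scalar similarity.
#' @export
cosine_score <- function(f1, f2) {
  stopifnot(inherits(f1, "cp_factors"), inherits(f2, "cp_factors"))
  if (f1$rank != f2$rank) stop("rank mismatch", call. = FALSE)
  if (length(f1$factors) != length(f2$factors)) {
    stop("factorizations must have the same number of modes", call. = FALSE)
  }
  r <- f1$rank
  prodmat <- matrix(1, r, r)  # [i, j] = prod_k cos(a_i^{(k)}, d_j^{(k)})
  for (k in seq_along(f1$factors)) {
    a <- f1$factors[[k]]
    d <- f2$factors[[k]]
    if (nrow(a) != nrow(d)) {
      stop(sprintf("mode %d sizes differ", k), call. = FALSE)
    }
    prodmat <- prodmat * crossprod(cosine_cols(a), cosine_cols(d))
  }
  mean(apply(prodmat, 1, max))
}

#' Write / read a tensor as a directory of delimited slices
#'
#' Serializes a 2- or 3-way `count_tensor` as one tab-delimited matrix per
#' mode-3 slice (`slice_<i>.tsv`) plus a `meta.json` with mode names and axis
#' labels; 2-way tensors are written as a single slice. An optional compact
#' binary copy (`tensor.bin`, doubles in native order) speeds up round-trips
#' but the text slices alone fully determine the tensor.
#'
#' @param x a `count_tensor` of order 2 or 3.
#' @param dir output directory (created if missing).
#' @param binary also write the compact binary container.
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(x, dir, binary = FALSE) {
  stopifnot(inherits(x, "count_tensor"))
  dims <- dim(x$data)
  if (length(dims) > 3L) {
    stop("directory serialization supports order 2 or 3 tensors", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nsl <- if (length(dims) == 3L) dims[3] else 1L
  for (i in seq_len(nsl)) {
    sl <- if (length(dims) == 3L) x$data[, , i] else x$data
    utils::write.table(sl, file.path(dir, sprintf("slice_%04d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(dims = dims, mode_names = x$mode_names,
               axis_labels = x$axis_labels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (binary) {
    con <- file(file.path(dir, "tensor.bin"), "wb")
    writeBin(as.double(x$data), con)
    close(con)
  }
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  bin <- file.path(dir, "tensor.bin")
  if (file.exists(bin)) {
    con <- file(bin, "rb")
    v <- readBin(con, "double", n = prod(dims))
    close(con)
    a <- array(v, dim = dims)
  } else {
    files <- sort(list.files(dir, pattern = "^slice_\\d+\\.tsv$",
                             full.names = TRUE))
    slices <- lapply(files, function(f) {
      as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    })
    a <- array(unlist(slices, use.names = FALSE),
               dim = c(dim(slices[[1]]), length(slices)))
    if (length(dims) == 2L) a <- array(a, dim = dims)
  }
  labs <- meta$axis_labels
  if (!is.null(labs) && !is.list(labs)) labs <- as.list(labs)
  count_tensor(a, mode_names = meta$mode_names, axis_labels = labs)
}

#' Write / read CP factors as delimited matrices
#'
#' One tab-delimited matrix per mode (`mode<k>_<name>.tsv`, columns = factors,
#' rows optionally labelled) plus a `meta.json` sidecar.
#'
#' @param f a `cp_factors` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cp_factors <- function(f, dir) {
  stopifnot(inherits(f, "cp_factors"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(f$factors)) {
    m <- f$factors[[k]]
    df <- as.data.frame(m)
    names(df) <- paste0("factor_", seq_len(ncol(m)))
    labs <- if (!is.null(f$axis_labels)) f$axis_labels[[k]] else NULL
    if (!is.null(labs)) df <- cbind(label = labs, df)
    utils::write.table(df, file.path(dir, sprintf("mode%d_%s.tsv", k,
                                                  f$mode_names[k])),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(rank = f$rank, mode_names = f$mode_names,
         has_labels = !is.null(f$axis_labels)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cp_factors
#' @export
read_cp_factors <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n <- length(meta$mode_names)
  factors <- vector("list", n)
  labels <- if (isTRUE(meta$has_labels)) vector("list", n) else NULL
  for (k in seq_len(n)) {
    fpath <- list.files(dir, pattern = sprintf("^mode%d_.*\\.tsv$", k),
                        full.names = TRUE)[1]
    df <- utils::read.table(fpath, sep = "\t", header = TRUE,
                            check.names = FALSE)
    if ("label" %in% names(df)) {
      if (!is.null(labels)) labels[[k]] <- as.character(df$label)
      df$label <- NULL
    }
    factors[[k]] <- as.matrix(df)
    dimnames(factors[[k]]) <- NULL
  }
  cp_factors(factors, mode_names = meta$mode_names, axis_labels = labels)
}
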