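# Pseudobulk tensor construction from annotated single-cell count matrices:
# gene/group filters, (sample x cell type x gene) aggregation, and per-fiber
# counts-per-million normalization.

#' Annotated cell-by-gene count matrix
#'
#' @param counts cells x genes matrix of non-negative integers (dense or a
#'   `Matrix` sparse matrix).
#' @param cell_meta data frame with one row per cell carrying at least
#'   `sample` and `cell_type` columns (a `barcode` column and extra columns
#'   such as `condition` are preserved).
#' @param gene_ids character vector of unique gene identifiers (one per
#'   column of `counts`).
#' @return an object of class `cell_counts`.
#' @export
cell_count_matrix <- function(counts, cell_meta, gene_ids) {
  if (!inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (nrow(cell_meta) != nrow(counts)) {
    stop("`cell_meta` must have one row per cell", call. = FALSE)
  }
  if (!all(c("sample", "cell_type") %in% names(cell_meta))) {
    stop("`cell_meta` requires `sample` and `cell_type` columns",
         call. = FALSE)
  }
  if (length(gene_ids) != ncol(counts)) {
    stop("`gene_ids` must have one entry per gene column", call. = FALSE)
  }
  gid <- gene_ids[!is.na(gene_ids) & gene_ids != ""]
  if (anyDuplicated(gid)) stop("gene identifiers must be unique",
                               call. = FALSE)
  v <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = counts, cell_meta = as.data.frame(cell_meta),
                 gene_ids = as.character(gene_ids)),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d cells x %d genes, %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample)),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' Filter genes by total count and symbol presence
#'
#' Removes genes whose total count across all cells is below `min_total`
#' (strictly: a gene at exactly the threshold is kept) and, when
#' `require_symbol` is set, genes with an empty/missing identifier or one
#' absent from `symbol_table` (a user-supplied vector of valid symbols; no
#' live lookup is performed). Gene order is otherwise preserved.
#'
#' @param m a `cell_counts`.
#' @param min_total minimum total count to keep a gene.
#' @param require_symbol drop genes without a valid symbol.
#' @param symbol_table optional character vector of accepted symbols.
#' @return the filtered `cell_counts`; attribute `n_removed` records the
#'   number of genes dropped.
#' @export
filter_genes <- function(m, min_total = 50, require_symbol = FALSE,
                         symbol_table = NULL) {
  stopifnot(inherits(m, "cell_counts"))
  totals <- Matrix::colSums(m$counts)
  keep <- totals >= min_total
  if (require_symbol) {
    valid <- !is.na(m$gene_ids) & m$gene_ids != ""
    if (!is.null(symbol_table)) valid <- valid & m$gene_ids %in% symbol_table
    keep <- keep & valid
  }
  if (!any(keep)) stop("all genes removed by the filters", call. = FALSE)
  out <- cell_count_matrix(m$counts[, keep, drop = FALSE], m$cell_meta,
                           m$gene_ids[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop rare samples and cell types
#'
#' Iteratively removes samples and cell-type labels whose share of the
#' remaining cells is below `min_frac` (strictly: a group at exactly the
#' threshold is kept), together with their cells, recomputing shares after
#' each pass until stable. Dropping a sample can push a cell type below the
#' threshold on the next pass, and vice versa.
#'
#' @param m a `cell_counts`.
#' @param min_frac minimum cell-share to keep a group, in `[0, 1)`.
#' @return the filtered `cell_counts`.
#' @export
filter_rare_groups <- function(m, min_frac = 0.02) {
  stopifnot(inherits(m, "cell_counts"))
  if (min_frac < 0 || min_frac >= 1) stop("`min_frac` must be in [0, 1)",
                                          call. = FALSE)
  keep <- rep(TRUE, nrow(m$counts))
  repeat {
    meta <- m$cell_meta[keep, , drop = FALSE]
    n <- nrow(meta)
    if (n == 0L) stop("all cells removed by the group filter", call. = FALSE)
    bad_s <- names(which(table(meta$sample) / n < min_frac))
    bad_c <- names(which(table(meta$cell_type) / n < min_frac))
    if (length(bad_s) == 0L && length(bad_c) == 0L) break
    keep <- keep & !(m$cell_meta$sample %in% bad_s) &
      !(m$cell_meta$cell_type %in% bad_c)
    if (!any(keep)) stop("all cells removed by the group filter",
                         call. = FALSE)
  }
  cell_count_matrix(m$counts[keep, , drop = FALSE],
                    m$cell_meta[keep, , drop = FALSE], m$gene_ids)
}

#' Build the sample x cell type x gene pseudobulk tensor
#'
#' Entry (s, c, g) is the sum of counts over all cells with sample `s` and
#' cell type `c`. The tensor conserves the total count of the input matrix.
#' Missing (sample, cell type) combinations yield all-zero gene fibers and
#' are flagged via the `empty_fibers` attribute (and a warning).
#'
#' @param m a `cell_counts` with complete sample/cell-type labels.
#' @return a 3-way `count_tensor` with modes `sample`, `cell_type`, `gene`.
#' @export
build_tensor <- function(m) {
  stopifnot(inherits(m, "cell_counts"))
  meta <- m$cell_meta
  unlabeled <- which(is.na(meta$sample) | is.na(meta$cell_type) |
                       meta$sample == "" | meta$cell_type == "")
  if (length(unlabeled) > 0L) {
    stop(sprintf("unlabeled cells at rows: %s",
                 paste(utils::head(unlabeled, 10), collapse = ", ")),
         call. = FALSE)
  }
  samples <- sort(unique(as.character(meta$sample)))
  types <- sort(unique(as.character(meta$cell_type)))
  genes <- m$gene_ids
  grp <- factor(paste(meta$sample, meta$cell_type, sep = "\r"),
                levels = as.vector(outer(samples, types, paste,
                                         sep = "\r")))
  # group cells by (sample, cell type) with an indicator matrix so sparse
  # counts never densify per group
  ind <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_len(nrow(meta)),
                              x = 1, dims = c(nlevels(grp), nrow(meta)))
  agg <- as.matrix(ind %*% m$counts)  # (S*C) x G, sample varying fastest
  arr <- array(agg, dim = c(length(samples), length(types), length(genes)))
  empty <- which(matrix(tabulate(as.integer(grp), nlevels(grp)),
                        length(samples), length(types)) == 0L,
                 arr.ind = TRUE)
  tens <- count_tensor(arr, mode_names = c("sample", "cell_type", "gene"),
                       axis_labels = list(samples, types, genes))
  if (nrow(empty) > 0L) {
    warning(sprintf("%d (sample, cell type) combinations have no cells",
                    nrow(empty)), call. = FALSE)
    attr(tens, "empty_fibers") <- data.frame(
      sample = samples[empty[, 1]], cell_type = types[empty[, 2]])
  }
  tens
}

#' Counts-per-million normalization of a pseudobulk tensor
#'
#' Rescales each (sample, cell type) gene fiber to a total of 1e6. All-zero
#' fibers are left at zero and reported with a warning. Idempotent.
#'
#' @param t a 3-way `count_tensor`.
#' @param total target fiber total (1e6 for CPM).
#' @return the normalized `count_tensor`.
#' @export
cpm_normalize <- function(t, total = 1e6) {
  stopifnot(inherits(t, "count_tensor"))
  dims <- dim(t$data)
  if (length(dims) != 3L) stop("CPM normalization expects a 3-way tensor",
                               call. = FALSE)
  arr <- t$data
  fiber_tot <- apply(arr, c(1, 2), sum)
  nzero <- sum(fiber_tot == 0)
  if (nzero > 0L) {
    warning(sprintf("%d all-zero gene fibers left unnormalized", nzero),
            call. = FALSE)
  }
  scl <- ifelse(fiber_tot > 0, total / fiber_tot, 0)
  out <- arr * as.vector(scl)  # (s, c) scaling recycles over the gene mode
  count_tensor(out, mode_names = t$mode_names, axis_labels = t$axis_labels)
}

#' Read single-cell counts from 10x-style or dense files
#'
#' Accepts either a Matrix Market triple (`counts.mtx` cells x genes or genes
#' x cells with `genes.tsv`/`barcodes.tsv`) or a single dense delimited
#' cells x genes table with gene columns; cell metadata comes from a
#' delimited table keyed by barcode.
#'
#' @param counts path to the `.mtx` or dense table.
#' @param genes,barcodes paths to the annotation files (mtx input).
#' @param cell_meta path to the metadata table (columns `barcode`, `sample`,
#'   `cell_type`, ...).
#' @param sep field separator for the delimited files.
#' @return a `cell_counts`.
#' @export
read_cell_counts <- function(counts, genes = NULL, barcodes = NULL,
                             cell_meta, sep = "\t") {
  meta <- utils::read.table(cell_meta, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  if (grepl("\\.mtx$", counts)) {
    mm <- Matrix::readMM(counts)
    gid <- utils::read.table(genes, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
    bc <- utils::read.table(barcodes, sep = sep, header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    if (nrow(mm) == length(gid) && ncol(mm) == length(bc) &&
        length(gid) != length(bc)) {
      mm <- Matrix::t(mm)  # genes x cells on disk
    }
    rownames(mm) <- bc
  } else {
    tab <- utils::read.table(counts, sep = sep, header = TRUE,
                             check.names = FALSE)
    gid <- colnames(tab)
    mm <- as.matrix(tab)
    bc <- rownames(tab)
  }
  if ("barcode" %in% names(meta)) {
    ord <- match(rownames(mm), meta$barcode)
    if (anyNA(ord)) stop("metadata is missing barcodes present in counts",
                         call. = FALSE)
    meta <- meta[ord, , drop = FALSE]
  }
  cell_count_matrix(mm, meta, gid)
}

#' Write a pseudobulk tensor with provenance
#'
#' Tensor directory format from [write_tensor()] plus a `provenance.json`
#' recording the filters applied and counts before/after.
#'
#' @param tens a `count_tensor`.
#' @param dir output directory.
#' @param provenance named list (filters, before/after dimensions, ...).
#' @return `dir` invisibly.
#' @export
write_pseudobulk <- function(tens, dir, provenance = list()) {
  write_tensor(tens, dir)
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
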