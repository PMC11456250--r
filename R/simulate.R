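# Synthetic data generators: (i) low-rank count tensors with zero-inflated
# Poisson noise and known Gamma factors; (ii) Splatter-style multi-donor
# scRNA-seq counts with embedded identity and activity gene expression
# programs, expression outliers, logistic dropout and doublets.

#' Simulate a low-rank tensor with zero-inflated Poisson noise
#'
#' Draws per-mode factor matrices entrywise from Gamma(`alpha`, `rate`)
#' (defaults 3 and 0.3, factor mean 10), forms the mean tensor
#' `T = [[A, B, C, ...]]`, samples each entry from Poisson(T) and then zeroes
#' it independently with probability `phi` (the excess-zero probability).
#'
#' @param shape integer vector of mode sizes (length >= 2).
#' @param rank true rank R.
#' @param alpha,rate Gamma parameters of the factor entries.
#' @param phi probability of extra zeros in `[0, 1]`.
#' @param seed integer seed.
#' @return a `zip_tensor_sim`: list with `tensor` (`count_tensor` of integer
#'   counts), `true_factors` (`cp_factors`), `mean_tensor` (the noiseless
#'   `count_tensor` T), `phi`, `seed`.
#' @export
simulate_zip_tensor <- function(shape, rank, alpha = 3, rate = 0.3, phi,
                                seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || any(shape < 1L)) stop("invalid `shape`",
                                                  call. = FALSE)
  if (rank < 1L) stop("invalid `rank`", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    factors <- lapply(shape, function(ik) {
      matrix(stats::rgamma(ik * rank, shape = alpha, rate = rate), ik, rank)
    })
    f <- cp_factors(factors)
    mean_arr <- cp_reconstruct_array(factors)
    counts <- stats::rpois(length(mean_arr), as.double(mean_arr))
    keep <- stats::rbinom(length(counts), 1L, 1 - phi)
    arr <- array(as.double(counts * keep), dim = shape)
    structure(
      list(tensor = count_tensor(arr),
           true_factors = f,
           mean_tensor = count_tensor(mean_arr),
           phi = phi, seed = seed),
      class = "zip_tensor_sim")
  })
}

# Deterministic donor subsets for the activity programs: program j is active
# in `n_active_donors` consecutive donors starting at donor j. The shift-by-1
# layout keeps the donor signatures distinct *and* the total program coverage
# uneven across donors (a layout whose indicator vectors sum to a constant
# would make the summed activity signal indistinguishable from baseline).
default_activity_donors <- function(n_activity, n_donors, n_active_donors) {
  lapply(seq_len(n_activity), function(j) {
    sort(unique((j - 1L + seq_len(n_active_donors) - 1L) %% n_donors + 1L))
  })
}

#' Simulate Splatter-style multi-donor scRNA-seq counts
#'
#' Gamma-Poisson counts with lognormal library sizes, expression-outlier
#' genes, multiplicative identity/activity gene expression programs (GEPs),
#' logistic dropout and doublets:
#'
#' * library sizes ~ Lognormal(7.64, 0.78);
#' * gene means ~ Gamma(mean 7.68, shape 0.34), resampled from
#'   Lognormal(6.15, 0.49) with probability 0.00286 (outliers);
#' * each program (identity or activity) has its own spectrum: the shared
#'   baseline gene means diverged gene-wise by a lognormal factor
#'   (`profile_divergence`) plus marker-gene fold changes on a disjoint
#'   `program_frac` gene subset, normalized to sum 1 -- programs share the
#'   expression backbone but are mutually distinguishable;
#' * every singlet cell expresses exactly one identity program (its cell
#'   type); activity programs apply to all cells of their designated donors
#'   at a per-cell usage drawn from `activity_usage` and scaled by
#'   `mean_de_log2fc / 0.75` (the activity-intensity knob), and the
#'   per-cell rate profile is the usage-weighted additive mixture of the
#'   spectra;
#' * counts ~ Poisson(library size x mixed rate profile);
#' * dropout: per-gene zero probability from a logistic function of the log
#'   mean rate, applied as Bernoulli masking;
#' * doublets: a `doublet_rate` fraction of cells is replaced by the combined
#'   counts of the cell and a random partner, downsampled so the total equals
#'   the larger of the two; doublets keep the higher-count parent's identity
#'   label and are flagged.
#'
#' @param n_cells,n_genes,n_donors simulation dimensions.
#' @param n_identity,n_activity number of identity / activity programs.
#' @param mean_de_log2fc activity-signal intensity knob (the study grid is
#'   0.25/0.5/0.75); it scales the activity usage relative to the reference
#'   intensity 0.75.
#' @param de_log2fc_sd retained for configs; SD of activity marker draws is
#'   currently tied to `identity_log2fc_sd`.
#' @param identity_log2fc,identity_log2fc_sd mean/SD of the marker-gene
#'   log2 fold changes that distinguish each program's spectrum.
#' @param program_frac fraction of genes marked by each program.
#' @param profile_divergence log-scale SD of the gene-wise divergence of a
#'   program's spectrum from the shared baseline.
#' @param activity_usage range of the per-cell activity usage weights
#'   (before intensity scaling).
#' @param activity_donors list of donor index vectors, one per activity
#'   program; default: staggered subsets of `n_active_donors` donors.
#' @param n_active_donors donors per activity program for the default layout.
#' @param lib_meanlog,lib_sdlog library-size lognormal parameters.
#' @param gene_mean,gene_shape gene-mean Gamma parameters (mean and shape).
#' @param outlier_prob,outlier_meanlog,outlier_sdlog expression-outlier
#'   parameters.
#' @param dropout enable logistic dropout.
#' @param dropout_mid,dropout_shape logistic midpoint `x0` and slope `k` of
#'   `1 / (1 + exp(-k (ln mu - x0)))`.
#' @param doublet_rate fraction of cells converted to doublets.
#' @param seed integer seed.
#' @return a `scrnaseq_sim`: list with `counts` (cells x genes integer
#'   matrix), `cell_meta` (donor, cell_type, doublet flag), `gene_ids`,
#'   `gep_matrix` (genes x programs ground truth), `usage` (cells x programs
#'   0/1), `lib_size`, `params`.
#' @export
simulate_scrnaseq <- function(n_cells = 3000L, n_genes = 1000L,
                              n_donors = 6L, n_identity = 5L,
                              n_activity = 3L, mean_de_log2fc = 0.75,
                              de_log2fc_sd = 0.2,
                              identity_log2fc = 1.0,
                              identity_log2fc_sd = 0.5,
                              program_frac = 0.1,
                              profile_divergence = 0.75,
                              activity_usage = c(0.25, 0.55),
                              activity_donors = NULL, n_active_donors = 3L,
                              lib_meanlog = 7.64, lib_sdlog = 0.78,
                              gene_mean = 7.68, gene_shape = 0.34,
                              outlier_prob = 0.00286, outlier_meanlog = 6.15,
                              outlier_sdlog = 0.49, dropout = TRUE,
                              dropout_mid = 0, dropout_shape = -1,
                              doublet_rate = 0.05, seed = 1L) {
  n_prog <- n_identity + n_activity
  gene_per_prog <- round(program_frac * n_genes)
  if (n_prog * gene_per_prog > n_genes) {
    stop("program gene sets exceed the gene count", call. = FALSE)
  }
  if (is.null(activity_donors)) {
    activity_donors <- default_activity_donors(n_activity, n_donors,
                                               n_active_donors)
  }
  with_seed(seed, {
    donor <- rep_len(seq_len(n_donors), n_cells)
    cell_type <- sample(rep_len(seq_len(n_identity), n_cells))
    lib <- stats::rlnorm(n_cells, lib_meanlog, lib_sdlog)

    mu <- stats::rgamma(n_genes, shape = gene_shape,
                        rate = gene_shape / gene_mean)
    outlier <- stats::runif(n_genes) < outlier_prob
    mu[outlier] <- stats::rlnorm(sum(outlier), outlier_meanlog, outlier_sdlog)

    # disjoint seeded gene sets: identity programs first, then activity
    pool <- sample.int(n_genes)
    gene_sets <- split(pool[seq_len(n_prog * gene_per_prog)],
                       rep(seq_len(n_prog), each = gene_per_prog))
    # Program spectra (genes x programs), normalized to probability vectors.
    # Each program shares the expression backbone (the baseline gene means:
    # housekeeping structure common to all cell states) but diverges from it
    # gene-wise by a lognormal factor, plus stronger marker-gene fold
    # changes on its designated gene set. `profile_divergence` (log-scale
    # SD) sets how far programs drift apart: at the default 0.75 two
    # spectra correlate about exp(-0.75^2) ~ 0.57 -- distinct but sharing
    # the backbone, as real cell types do.
    spectra <- matrix(0, n_genes, n_prog)
    for (p in seq_len(n_prog)) {
      mp <- mu * exp(stats::rnorm(n_genes, 0, profile_divergence))
      boost <- rep(1, n_genes)
      g <- gene_sets[[p]]
      boost[g] <- exp(stats::rnorm(length(g), identity_log2fc * log(2),
                                   identity_log2fc_sd))
      spectra[, p] <- mp * boost
    }
    spectra <- sweep(spectra, 2, colSums(spectra), "/")

    # usage: each singlet cell expresses its identity program plus the
    # activity programs of its donor at a random usage level; the identity
    # share is the remainder, so per-cell rate profiles stay normalized
    # (additive mixture of spectra). The activity-signal intensity knob
    # `mean_de_log2fc` scales the usage level relative to the reference
    # intensity 0.75, so weaker settings make the activity programs
    # proportionally harder to recover.
    intensity <- mean_de_log2fc / 0.75
    usage <- matrix(0, n_cells, n_prog)
    for (j in seq_len(n_activity)) {
      aff <- donor %in% activity_donors[[j]]
      usage[aff, n_identity + j] <- intensity *
        stats::runif(sum(aff), activity_usage[1], activity_usage[2])
    }
    act_tot <- rowSums(usage)
    over <- act_tot > 0.8
    if (any(over)) {
      usage[over, ] <- usage[over, , drop = FALSE] * (0.8 / act_tot[over])
      act_tot[over] <- 0.8
    }
    usage[cbind(seq_len(n_cells), cell_type)] <- 1 - act_tot

    rate_norm <- usage %*% t(spectra)   # rows sum to 1
    lam <- rate_norm * lib
    counts <- matrix(stats::rpois(n_cells * n_genes, as.double(lam)),
                     n_cells, n_genes)
    pre_dropout_total <- rowSums(counts)

    if (dropout) {
      mean_rate <- colMeans(lam)
      pi_g <- stats::plogis(dropout_shape * (log(mean_rate) - dropout_mid))
      mask <- matrix(stats::rbinom(n_cells * n_genes, 1L,
                                   rep(pi_g, each = n_cells)),
                     n_cells, n_genes)
      counts <- counts * (1L - mask)
    }

    is_doublet <- rep(FALSE, n_cells)
    n_doub <- round(doublet_rate * n_cells)
    if (n_doub > 0L) {
      hosts <- sample.int(n_cells, n_doub)
      is_doublet[hosts] <- TRUE
      for (h in hosts) {
        partner <- sample(setdiff(seq_len(n_cells), h), 1L)
        combined <- counts[h, ] + counts[partner, ]
        target <- max(sum(counts[h, ]), sum(counts[partner, ]))
        tot <- sum(combined)
        if (tot > target && tot > 0) {
          combined <- as.integer(stats::rmultinom(1L, target,
                                                  combined / tot))
        }
        if (sum(counts[partner, ]) > sum(counts[h, ])) {
          cell_type[h] <- cell_type[partner]
        }
        counts[h, ] <- combined
      }
    }

    # ground-truth GEPs over genes are the program spectra themselves (the
    # normalized expression profiles the generator mixes)
    gep <- spectra
    colnames(gep) <- c(paste0("identity_", seq_len(n_identity)),
                       paste0("activity_", seq_len(n_activity)))

    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    meta <- data.frame(
      barcode = sprintf("cell_%05d", seq_len(n_cells)),
      sample = paste0("donor_", donor),
      cell_type = paste0("type_", cell_type),
      doublet = is_doublet)
    params <- list(
      n_cells = n_cells, n_genes = n_genes, n_donors = n_donors,
      n_identity = n_identity, n_activity = n_activity,
      mean_de_log2fc = mean_de_log2fc, de_log2fc_sd = de_log2fc_sd,
      identity_log2fc = identity_log2fc,
      identity_log2fc_sd = identity_log2fc_sd,
      program_frac = program_frac,
      profile_divergence = profile_divergence,
      activity_usage = activity_usage,
      activity_donors = activity_donors,
      lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
      gene_mean = gene_mean, gene_shape = gene_shape,
      outlier_prob = outlier_prob, outlier_meanlog = outlier_meanlog,
      outlier_sdlog = outlier_sdlog, dropout = dropout,
      dropout_mid = dropout_mid, dropout_shape = dropout_shape,
      doublet_rate = doublet_rate, seed = seed)
    structure(
      list(counts = counts, cell_meta = meta, gene_ids = gene_ids,
           gep_matrix = gep, usage = usage, lib_size = lib,
           pre_dropout_total = pre_dropout_total, params = params),
      class = "scrnaseq_sim")
  })
}

#' @export
print.scrnaseq_sim <- function(x, ...) {
  cat(sprintf(
    "<scrnaseq_sim> %d cells x %d genes | %d donors | %d programs | %.1f%% zeros\n",
    nrow(x$counts), ncol(x$counts), x$params$n_donors,
    ncol(x$gep_matrix), 100 * mean(x$counts == 0)))
  invisible(x)
}

#' Export a simulated dataset as a plain-text fixture
#'
#' Writes `counts.mtx` (Matrix Market, cells x genes), `genes.tsv`,
#' `barcodes.tsv`, `cell_meta.tsv`, `gep_truth.tsv` and `params.json`.
#' Deterministic given the simulation seed.
#'
#' @param sim a `scrnaseq_sim`.
#' @param path output directory.
#' @return `path` invisibly.
#' @export
export_fixture <- function(sim, path) {
  stopifnot(inherits(sim, "scrnaseq_sim"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE),
                  file.path(path, "counts.mtx"))
  writeLines(sim$gene_ids, file.path(path, "genes.tsv"))
  writeLines(sim$cell_meta$barcode, file.path(path, "barcodes.tsv"))
  utils::write.table(sim$cell_meta, file.path(path, "cell_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gep <- data.frame(gene = sim$gene_ids, sim$gep_matrix,
                    check.names = FALSE)
  utils::write.table(gep, file.path(path, "gep_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$params, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname export_fixture
#' @param path fixture directory written by [export_fixture()].
#' @return `read_fixture`: a list with `counts`, `cell_meta`, `gene_ids`,
#'   `gep_matrix`, `params`.
#' @export
read_fixture <- function(path) {
  counts <- as.matrix(Matrix::readMM(file.path(path, "counts.mtx")))
  gene_ids <- readLines(file.path(path, "genes.tsv"))
  meta <- utils::read.table(file.path(path, "cell_meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  gep <- utils::read.table(file.path(path, "gep_truth.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  gm <- as.matrix(gep[, -1, drop = FALSE])
  rownames(gm) <- gep$gene
  params <- jsonlite::read_json(file.path(path, "params.json"),
                                simplifyVector = TRUE)
  list(counts = counts, cell_meta = meta, gene_ids = gene_ids,
       gep_matrix = gm, params = params)
}

#' Pseudobulk a simulation into the donor x cell type x gene tensor
#'
#' Convenience wrapper: drops doublets (optional), wraps the counts in a
#' `cell_counts`, sums per (donor, cell type) and optionally CPM-normalizes.
#'
#' @param sim a `scrnaseq_sim`.
#' @param drop_doublets remove flagged doublets first.
#' @param cpm apply [cpm_normalize()].
#' @return a 3-way `count_tensor`.
#' @export
pseudobulk_sim <- function(sim, drop_doublets = TRUE, cpm = TRUE) {
  stopifnot(inherits(sim, "scrnaseq_sim"))
  keep <- if (drop_doublets) !sim$cell_meta$doublet else
    rep(TRUE, nrow(sim$counts))
  m <- cell_count_matrix(sim$counts[keep, , drop = FALSE],
                         sim$cell_meta[keep, , drop = FALSE], sim$gene_ids)
  tens <- build_tensor(m)
  if (cpm) tens <- cpm_normalize(tens)
  tens
}
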