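test_that("gene filtering applies the strict count threshold", {
  counts <- cbind(g_lo = c(20, 29), g_at = c(25, 25), g_hi = c(100, 100))
  m <- cell_count_matrix(counts,
                         data.frame(sample = c("s1", "s1"),
                                    cell_type = c("a", "b")),
                         c("g_lo", "g_at", "g_hi"))
  out <- filter_genes(m, min_total = 50)
  expect_equal(out$gene_ids, c("g_at", "g_hi"))  # 49 dropped, 50 kept
  expect_equal(attr(out, "n_removed"), 1L)

  # blank symbol removed regardless of abundance when required
  m2 <- cell_count_matrix(cbind(1e6, 100),
                          data.frame(sample = "s", cell_type = "a"),
                          c("", "GENE1"))
  out2 <- filter_genes(m2, min_total = 0, require_symbol = TRUE)
  expect_equal(out2$gene_ids, "GENE1")

  # symbol table restricts further
  m3 <- cell_count_matrix(cbind(100, 100),
                          data.frame(sample = "s", cell_type = "a"),
                          c("REAL", "FAKE"))
  out3 <- filter_genes(m3, min_total = 0, require_symbol = TRUE,
                       symbol_table = "REAL")
  expect_equal(out3$gene_ids, "REAL")

  # identity when nothing triggers
  expect_equal(filter_genes(m, min_total = 10)$gene_ids, m$gene_ids)
  expect_error(filter_genes(m, min_total = 1e9), "all genes")
})

test_that("rare-group filtering is strict at the boundary and cascades", {
  # 1000 cells; a type at 19 cells (1.9%) dropped, at 20 cells (2%) kept
  n <- 1000
  types <- c(rep("big", 961), rep("at", 20), rep("below", 19))
  m <- cell_count_matrix(matrix(1L, n, 2),
                         data.frame(sample = rep("s1", n),
                                    cell_type = types),
                         c("g1", "g2"))
  out <- filter_rare_groups(m, 0.02)
  expect_setequal(unique(out$cell_meta$cell_type), c("big", "at"))

  # cascade: dropping a rare sample pushes a type below threshold next pass
  meta <- data.frame(
    sample = c(rep("sA", 97), rep("sB", 2), "sA"),
    cell_type = c(rep("t1", 97), rep("t2", 3)))
  mc <- cell_count_matrix(matrix(1L, 100, 1), meta, "g")
  out2 <- filter_rare_groups(mc, 0.02)
  # sB (2%) is kept at first glance? 2/100 = 2% -> kept; construct < 2%:
  meta3 <- data.frame(
    sample = c(rep("sA", 98), "sB", "sA"),
    cell_type = c(rep("t1", 98), "t2", "t2"))
  m3 <- cell_count_matrix(matrix(1L, 100, 1), meta3, "g")
  out3 <- filter_rare_groups(m3, 0.02)
  # sB (1%) dropped; t2 then has 1/99 < 2% and is dropped in pass 2
  expect_equal(unique(out3$cell_meta$sample), "sA")
  expect_equal(unique(out3$cell_meta$cell_type), "t1")
  expect_equal(nrow(out3$counts), 98)

  # identity when all groups are at or above the threshold
  expect_equal(nrow(filter_rare_groups(mc, 0.02)$counts), 100)
})

test_that("pseudobulk tensor equals the hand-computed sums", {
  m <- tiny_cells()
  tens <- build_tensor(m)
  expect_equal(dim(tens$data), c(2, 2, 3))
  # hand summation: single cell per (sample, type)
  expect_equal(tens$data[1, 1, ], c(1, 2, 3))  # s1 tA
  expect_equal(tens$data[1, 2, ], c(4, 0, 1))  # s1 tB
  expect_equal(tens$data[2, 1, ], c(2, 2, 2))  # s2 tA
  expect_equal(tens$data[2, 2, ], c(0, 5, 0))  # s2 tB
  expect_equal(tens$axis_labels[[3]], c("g1", "g2", "g3"))

  # count conservation and cell-order invariance
  expect_equal(sum(tens$data), sum(m$counts))
  perm <- c(3, 1, 4, 2)
  m2 <- cell_count_matrix(m$counts[perm, ], m$cell_meta[perm, ], m$gene_ids)
  expect_equal(build_tensor(m2)$data, tens$data)

  # aggregation over multiple cells in one group
  m3 <- cell_count_matrix(rbind(m$counts, c(10, 10, 10)),
                          rbind(m$cell_meta,
                                data.frame(barcode = "c5", sample = "s1",
                                           cell_type = "tA")),
                          m$gene_ids)
  expect_equal(build_tensor(m3)$data[1, 1, ], c(11, 12, 13))

  # unlabeled cells are reported
  meta_bad <- m$cell_meta
  meta_bad$cell_type[2] <- NA
  expect_error(build_tensor(cell_count_matrix(m$counts, meta_bad,
                                              m$gene_ids)), "unlabeled")

  # missing (sample, type) combinations produce flagged zero fibers
  m4 <- cell_count_matrix(m$counts[-2, ], m$cell_meta[-2, ], m$gene_ids)
  expect_warning(t4 <- build_tensor(m4), "no cells")
  expect_equal(t4$data[1, 2, ], c(0, 0, 0))
  expect_equal(attr(t4, "empty_fibers")$sample, "s1")
})

test_that("CPM normalization rescales fibers to one million and is idempotent", {
  arr <- array(0, c(1, 2, 3))
  arr[1, 1, ] <- c(10, 30, 60)
  arr[1, 2, ] <- c(0, 0, 0)
  x <- count_tensor(arr)
  expect_warning(y <- cpm_normalize(x), "all-zero")
  expect_equal(y$data[1, 1, ], c(1e5, 3e5, 6e5))
  expect_equal(y$data[1, 2, ], c(0, 0, 0))

  tens <- build_tensor(tiny_cells())
  z <- cpm_normalize(tens)
  sums <- apply(z$data, c(1, 2), sum)
  expect_true(all(abs(sums - 1e6) < 1e-3))
  expect_equal(cpm_normalize(z)$data, z$data, tolerance = 1e-9)
})

test_that("documented filter order (groups first, then genes) matters", {
  # a gene carried mostly by a rare group: filtering groups first removes
  # the cells and then the gene; genes first would keep the gene
  n <- 100
  counts <- matrix(0L, n, 2)
  counts[, 1] <- 1L
  rare <- 100
  counts[rare, 2] <- 60L
  meta <- data.frame(sample = rep("s", n),
                     cell_type = c(rep("t1", 99), "t2"))
  m <- cell_count_matrix(counts, meta, c("gA", "gB"))
  groups_then_genes <- filter_genes(filter_rare_groups(m, 0.02),
                                    min_total = 50)
  genes_then_groups <- filter_rare_groups(filter_genes(m, min_total = 50),
                                          0.02)
  expect_equal(groups_then_genes$gene_ids, "gA")
  expect_equal(genes_then_groups$gene_ids, c("gA", "gB"))
})

test_that("matrix-market fixtures round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_scrnaseq(n_cells = 60, n_genes = 40, n_donors = 3,
                           n_identity = 2, n_activity = 1, seed = 19)
  export_fixture(sim, dir)
  m <- read_cell_counts(counts = file.path(dir, "counts.mtx"),
                        genes = file.path(dir, "genes.tsv"),
                        barcodes = file.path(dir, "barcodes.tsv"),
                        cell_meta = file.path(dir, "cell_meta.tsv"))
  expect_equal(unname(as.matrix(m$counts)), unname(sim$counts))
  expect_equal(m$gene_ids, sim$gene_ids)
  expect_equal(m$cell_meta$sample, sim$cell_meta$sample)
})
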