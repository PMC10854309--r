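test_that("QC removes low-feature cells, high-mito cells and rare genes", {
  # 210 genes so a cell can clear the 200-feature threshold; cell2 detects
  # only 199 of them
  n_genes <- 210
  m <- matrix(1, nrow = n_genes, ncol = 3)
  m[1:11, 2] <- 0 # cell2: 199 detected features
  ex <- toy_expression(m, genes = sprintf("G%03d", 1:n_genes))
  res <- qc_filter(ex, min_cells_per_gene = 1,
                   min_features_per_cell = 200)
  expect_equal(ncol(res$matrix$counts), 2)
  expect_false("cell02" %in% colnames(res$matrix$counts))

  # mito fraction strictly over 0.10 removed, exactly 0.10 retained
  m2 <- matrix(1, nrow = 100, ncol = 2,
               dimnames = list(c(sprintf("G%02d", 1:99), "MT-ND1"),
                               c("at_thresh", "over_thresh")))
  m2["MT-ND1", "at_thresh"] <- 11     # 11/110 = 0.10
  m2["MT-ND1", "over_thresh"] <- 12.4 # 12.4/111.4 > 0.10
  res <- qc_filter(expression_matrix(m2), min_cells_per_gene = 1,
                   min_features_per_cell = 10)
  expect_equal(colnames(res$matrix$counts), "at_thresh")

  # gene detected in 2 cells removed, in 3 cells retained
  m3 <- matrix(0, nrow = 2, ncol = 3,
               dimnames = list(c("rare", "common"), paste0("c", 1:3)))
  m3["rare", 1:2] <- 1
  m3["common", ] <- 1
  res <- qc_filter(expression_matrix(m3), min_cells_per_gene = 3,
                   min_features_per_cell = 1)
  expect_equal(rownames(res$matrix$counts), "common")
})

test_that("QC filtering is idempotent and survives emptying the matrix", {
  withr::with_seed(21, {
    m <- matrix(rpois(300 * 40, 1.5), nrow = 300,
                dimnames = list(c(sprintf("G%03d", 1:295),
                                  paste0("MT-", 1:5)),
                                sprintf("c%02d", 1:40)))
  })
  res1 <- qc_filter(toy_expression(m, genes = rownames(m),
                                   cells = colnames(m)),
                    min_features_per_cell = 100)
  res2 <- qc_filter(res1$matrix, min_features_per_cell = 100)
  expect_equal(as.matrix(res2$matrix$counts), as.matrix(res1$matrix$counts))
  expect_equal(res2$audit$genes_removed + res2$audit$cells_low_features +
                 res2$audit$cells_high_mito, 0)

  expect_warning(
    qc_filter(toy_expression(matrix(1, 5, 3)),
              min_features_per_cell = 100),
    "all cells")
})

test_that("normalisation scales to a common library size on the log scale", {
  # one expressed gene with count 7 -> log(1 + 10000)
  m <- matrix(0, nrow = 3, ncol = 1)
  m[2, 1] <- 7
  nm <- normalize_counts(toy_expression(m))
  expect_equal(nm$normalized[2, 1], log(1 + 10000), tolerance = 1e-12)

  # proportional count vectors normalise identically
  m <- cbind(c(1, 2, 3), c(3, 6, 9))
  nm <- normalize_counts(toy_expression(m))
  expect_equal(nm$normalized[, 1], nm$normalized[, 2], tolerance = 1e-12)

  # every cell's expm1 sums back to the scale factor
  withr::with_seed(22, m <- matrix(rpois(50, 4) + 1, nrow = 10))
  nm <- normalize_counts(toy_expression(m))
  expect_equal(unname(Matrix::colSums(expm1(nm$normalized))),
               rep(10000, 5), tolerance = 1e-8)
})

test_that("rank-sum DE gives null results on identical distributions", {
  m <- matrix(rep(c(1, 2, 3, 4, 5), 4), nrow = 2, ncol = 10, byrow = TRUE)
  nm <- normalize_counts(toy_expression(m))
  g1 <- colnames(nm$normalized)[1:5]
  g2 <- colnames(nm$normalized)[6:10]
  res <- rank_sum_de(nm, g1, g2)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$log2_fold_change == 0))
})

test_that("complete separation reaches the extreme rank-sum tail", {
  m <- matrix(1, nrow = 2, ncol = 20)
  m[1, 1:10] <- 20 + seq_len(10) # distinct high counts in group1
  m[1, 11:20] <- 0
  nm <- normalize_counts(toy_expression(m))
  g1 <- colnames(nm$normalized)[1:10]
  g2 <- colnames(nm$normalized)[11:20]
  res <- rank_sum_de(nm, g1, g2)
  p <- res$p_value[res$gene == "G01"]
  ref <- suppressWarnings(stats::wilcox.test(
    nm$normalized["G01", g1], nm$normalized["G01", g2]))$p.value
  expect_equal(p, ref, tolerance = 1e-12)
  expect_lt(p, 1e-3)
  expect_gt(res$log2_fold_change[res$gene == "G01"], 1)
})

test_that("DE contract errors and BH adjustment invariants hold", {
  withr::with_seed(23, {
    m <- matrix(rpois(30 * 12, 2), nrow = 30,
                dimnames = list(sprintf("G%02d", 1:30),
                                sprintf("c%02d", 1:12)))
  })
  nm <- normalize_counts(expression_matrix(m))
  g1 <- colnames(m)[1:6]; g2 <- colnames(m)[7:12]
  expect_error(rank_sum_de(nm, g1, c(g2, g1[1])), "overlap")
  expect_error(rank_sum_de(nm, g1[1:2], g2), "at least 3")
  res <- rank_sum_de(nm, g1, g2)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  # the gene with the largest p keeps it after adjustment
  expect_equal(max(res$adjusted_p), max(res$p_value))
  # adjusted values do not depend on gene order
  res2 <- rank_sum_de(
    normalize_counts(expression_matrix(m[rev(rownames(m)), ])), g1, g2)
  res2 <- res2[match(res$gene, res2$gene), ]
  expect_equal(res$adjusted_p, res2$adjusted_p)
})

test_that("stratum contrasts pool cells per stratum and flag single samples", {
  withr::with_seed(24, {
    m <- matrix(rpois(20 * 40, 2) + 1, nrow = 20,
                dimnames = list(c("MARK", sprintf("G%02d", 2:20)),
                                sprintf("c%02d", 1:40)))
    # plant a strong shift in the Superexpanded samples (cells 1-20)
    m["MARK", 1:20] <- m["MARK", 1:20] + 25
  })
  nm <- normalize_counts(expression_matrix(m))
  md <- data.frame(cell_barcode = colnames(m),
                   sample_id = rep(c("s1", "s2", "s3", "s4"), each = 10),
                   cluster = "CD8_T")
  strata <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       disease = "ALS",
                       stratum = c("Superexpanded", "Superexpanded",
                                   "Expanded", "Expanded"))
  res <- stratum_contrast(nm, strata, md, disease = "ALS",
                          cluster = "CD8_T")
  expect_equal(res$gene[1], "MARK")
  expect_lt(res$adjusted_p[1], 0.05)
  expect_gt(res$log2_fold_change[1], 0)

  strata1 <- strata; strata1$stratum <- c("Superexpanded", rep("Expanded", 3))
  expect_warning(stratum_contrast(nm, strata1, md, disease = "ALS"),
                 "pseudoreplicated")
  strata2 <- strata; strata2$stratum <- "Expanded"
  expect_error(stratum_contrast(nm, strata2, md, disease = "ALS"),
               "lacks one of the strata")
})

test_that("the MatrixMarket triplet round-trips through the reader", {
  withr::with_seed(25, {
    m <- matrix(rpois(12 * 5, 1), nrow = 12,
                dimnames = list(sprintf("G%02d", 1:12),
                                sprintf("bc%02d", 1:5)))
  })
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(d, "matrix.mtx"))
  writeLines(colnames(m), file.path(d, "barcodes.tsv"))
  utils::write.table(data.frame(rownames(m), rownames(m), "Gene Expression"),
                     file.path(d, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ex <- read_mtx_10x(d)
  expect_equal(as.matrix(ex$counts), m)
})
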