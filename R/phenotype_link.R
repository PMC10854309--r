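# Expression QC, normalisation, and rank-sum differential expression between
# cell groups defined by clonal categories.

#' Construct an expression matrix object
#'
#' Thin container around a sparse genes-by-cells count matrix (10x
#' orientation). Column names are cell barcodes (assumed unique across the
#' run), row names are feature names.
#'
#' @param counts Matrix or `dgCMatrix` of non-negative integer counts,
#'   genes in rows, cells in columns, with dimnames.
#' @return Object of class `expr_matrix` with elements `counts` and
#'   `normalized` (NULL until [normalize_counts()]).
#' @export
expression_matrix <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and cell colnames")
  }
  structure(list(counts = counts, normalized = NULL), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells (%snormalized)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "not " else ""))
  invisible(x)
}

#' Read a 10x-convention MatrixMarket expression triplet
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` (feature file may have 1-3 tab-separated columns; the
#'   first is used as the feature name).
#' @param matrix_file,barcodes_file,features_file Explicit paths overriding
#'   the defaults under `dir`.
#' @return An `expr_matrix`.
#' @export
read_mtx_10x <- function(dir = NULL,
                         matrix_file = file.path(dir, "matrix.mtx"),
                         barcodes_file = file.path(dir, "barcodes.tsv"),
                         features_file = file.path(dir, "features.tsv")) {
  m <- Matrix::readMM(matrix_file)
  bc <- readLines(barcodes_file)
  ft <- utils::read.delim(features_file, header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(m) != nrow(ft) || ncol(m) != length(bc)) {
    stop("matrix dimensions do not match barcodes/features files")
  }
  dimnames(m) <- list(ft[[1]], bc)
  expression_matrix(m)
}

#' Quality-control filter for an expression matrix
#'
#' Removes features detected in fewer than `min_cells_per_gene` cells, cells
#' with fewer than `min_features_per_cell` detected features, and cells
#' whose mitochondrial read fraction exceeds `max_mito_fraction` (strictly
#' greater; a cell exactly at the threshold is retained). Mitochondrial
#' features are identified by name prefix. Filtering is iterated to a fixed
#' point so the operation is idempotent. Removing every cell produces an
#' empty matrix with a warning, not an error.
#'
#' @param x An `expr_matrix`.
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 3).
#' @param min_features_per_cell Minimum detected features per cell
#'   (default 200).
#' @param max_mito_fraction Maximum mitochondrial read fraction
#'   (default 0.10).
#' @param mito_prefix Feature-name prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return list with `matrix` (filtered `expr_matrix`) and `audit`
#'   (removal counts by reason).
#' @export
qc_filter <- function(x, min_cells_per_gene = 3, min_features_per_cell = 200,
                      max_mito_fraction = 0.10, mito_prefix = "MT-") {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$counts
  audit <- c(genes_removed = 0L, cells_low_features = 0L,
             cells_high_mito = 0L)
  repeat {
    det_gene <- Matrix::rowSums(m > 0)
    keep_gene <- det_gene >= min_cells_per_gene
    feats <- Matrix::colSums(m > 0)
    tot <- Matrix::colSums(m)
    mito <- startsWith(rownames(m), mito_prefix)
    mito_frac <- if (any(mito)) {
      mf <- Matrix::colSums(m[mito, , drop = FALSE]) / tot
      mf[tot == 0] <- 0
      mf
    } else rep(0, ncol(m))
    low_feat <- feats < min_features_per_cell
    high_mito <- !low_feat & mito_frac > max_mito_fraction
    keep_cell <- !low_feat & !high_mito
    if (all(keep_gene) && all(keep_cell)) break
    audit["genes_removed"] <- audit["genes_removed"] + sum(!keep_gene)
    audit["cells_low_features"] <- audit["cells_low_features"] +
      sum(low_feat)
    audit["cells_high_mito"] <- audit["cells_high_mito"] + sum(high_mito)
    m <- m[keep_gene, keep_cell, drop = FALSE]
    if (ncol(m) == 0) {
      warning("QC filtering removed all cells", call. = FALSE)
      break
    }
    if (nrow(m) == 0) break
  }
  out <- structure(list(counts = m, normalized = NULL),
                   class = "expr_matrix")
  list(matrix = out, audit = as.list(audit))
}

#' Library-size normalisation and log transform
#'
#' Scales each cell's counts to a common library size (default 10,000) and
#' applies log(1 + x). Cells with zero total counts are removed with a
#' warning. Sparsity is preserved (zeros map to zeros).
#'
#' @param x An `expr_matrix` (typically QC-filtered).
#' @param scale_factor Target library size (default 1e4).
#' @return The `expr_matrix` with `normalized` populated.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$counts
  libs <- Matrix::colSums(m)
  if (any(libs == 0)) {
    warning(sum(libs == 0), " zero-count cell(s) removed before ",
            "normalisation", call. = FALSE)
    m <- m[, libs > 0, drop = FALSE]
    libs <- libs[libs > 0]
  }
  norm <- m %*% Matrix::Diagonal(x = scale_factor / libs)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  structure(list(counts = m, normalized = norm), class = "expr_matrix")
}

#' Rank-sum differential expression between two cell groups
#'
#' For every gene detected in at least `min_pct` of either group, performs a
#' two-sided Wilcoxon rank-sum test on the normalised values, with
#' Benjamini-Hochberg adjustment across the tested genes. The log2 fold
#' change compares group means of expm1(normalised) values with a
#' pseudocount of 1, mirroring the convention of the mainstream single-cell
#' toolkits.
#'
#' @param x A normalised `expr_matrix`.
#' @param group1,group2 Disjoint character vectors of cell barcodes, each of
#'   size >= 3.
#' @param min_pct Minimum detection fraction in either group for a gene to
#'   be tested (default 0.10).
#' @return data.frame with `gene`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `pct_group1`, `pct_group2`, sorted by `adjusted_p` then
#'   decreasing absolute fold change.
#' @export
rank_sum_de <- function(x, group1, group2, min_pct = 0.10) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$normalized)) stop("run normalize_counts() first")
  if (length(intersect(group1, group2)) > 0) {
    stop("cell groups overlap")
  }
  if (length(group1) < 3 || length(group2) < 3) {
    stop("each group needs at least 3 cells")
  }
  norm <- x$normalized
  missing <- setdiff(c(group1, group2), colnames(norm))
  if (length(missing)) {
    stop("cells not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m1 <- norm[, group1, drop = FALSE]
  m2 <- norm[, group2, drop = FALSE]
  pct1 <- Matrix::rowSums(m1 > 0) / ncol(m1)
  pct2 <- Matrix::rowSums(m2 > 0) / ncol(m2)
  test <- pct1 >= min_pct | pct2 >= min_pct
  genes <- rownames(norm)[test]
  if (!length(genes)) {
    return(data.frame(gene = character(), log2_fold_change = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      pct_group1 = numeric(), pct_group2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  d1 <- as.matrix(m1[test, , drop = FALSE])
  d2 <- as.matrix(m2[test, , drop = FALSE])
  pvals <- numeric(length(genes))
  lfc <- numeric(length(genes))
  for (k in seq_along(genes)) {
    x1 <- d1[k, ]; x2 <- d2[k, ]
    pvals[k] <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
    lfc[k] <- log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))
  }
  pvals[is.nan(pvals)] <- 1
  res <- data.frame(gene = genes, log2_fold_change = lfc, p_value = pvals,
                    adjusted_p = stats::p.adjust(pvals, "BH"),
                    pct_group1 = unname(pct1[test]),
                    pct_group2 = unname(pct2[test]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$adjusted_p, -abs(res$log2_fold_change),
                   res$gene), ]
  rownames(res) <- NULL
  res
}

#' Differential expression between entropy strata
#'
#' Pools the cells of one cell group (optionally restricted to a cluster
#' label) across the Superexpanded samples of a disease and across its
#' Expanded samples, then runs [rank_sum_de()] Superexpanded vs Expanded.
#' A stratum represented by a single sample triggers a pseudoreplication
#' warning but still runs.
#'
#' @param x A normalised `expr_matrix`.
#' @param strata Stratum table from [stratify_samples()].
#' @param metadata Cell metadata with `cell_barcode`, `sample_id`, and
#'   optionally `cluster`.
#' @param disease Disease group to contrast within.
#' @param cluster Optional cluster label restriction.
#' @param ... Passed to [rank_sum_de()].
#' @return data.frame as from [rank_sum_de()] (group1 = Superexpanded).
#' @export
stratum_contrast <- function(x, strata, metadata, disease, cluster = NULL,
                             ...) {
  s <- strata[strata$disease == disease, , drop = FALSE]
  sup <- s$sample_id[s$stratum == "Superexpanded"]
  exp_ <- s$sample_id[s$stratum == "Expanded"]
  if (!length(sup) || !length(exp_)) {
    stop("disease '", disease, "' lacks one of the strata")
  }
  if (length(sup) == 1 || length(exp_) == 1) {
    warning("a stratum contains a single sample; contrast is ",
            "pseudoreplicated", call. = FALSE)
  }
  md <- metadata
  if (!is.null(cluster)) {
    if (!"cluster" %in% names(md)) stop("metadata has no 'cluster' column")
    md <- md[md$cluster == cluster, , drop = FALSE]
  }
  present <- md$cell_barcode %in% colnames(x$normalized %||% x$counts)
  md <- md[present, , drop = FALSE]
  g1 <- md$cell_barcode[md$sample_id %in% sup]
  g2 <- md$cell_barcode[md$sample_id %in% exp_]
  rank_sum_de(x, g1, g2, ...)
}
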