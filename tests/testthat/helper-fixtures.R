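# Shared fixture builders. Everything is generated in code; no data files.

# One contig record row in the package's normalised layout.
contig_row <- function(barcode, locus, cdr3_nt, sample = "S1",
                       v = "TRBV1", d = "TRBD1", j = "TRBJ1", c = "TRBC1",
                       cdr3_aa = "CASSF", productive = TRUE, umi = 1L) {
  if (locus == "TRA") {
    v <- sub("^TRB", "TRA", v); j <- sub("^TRB", "TRA", j)
    d <- NA_character_; c <- "TRAC"
  }
  data.frame(cell_barcode = barcode, sample_id = sample,
             chain_locus = locus, v_gene = v, d_gene = d, j_gene = j,
             c_gene = c, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             productive = productive, umi_count = umi,
             stringsAsFactors = FALSE)
}

# A well-formed TRA+TRB pair for one cell.
contig_pair <- function(barcode, sample = "S1", alpha_cdr3 = "TGTGCT",
                        beta_cdr3 = "TGTGCA") {
  rbind(contig_row(barcode, "TRA", alpha_cdr3, sample),
        contig_row(barcode, "TRB", beta_cdr3, sample))
}

# Metadata covering a set of barcodes.
make_metadata <- function(barcodes, sample = "S1", patient = "P1",
                          tissue = "meninges", disease = "ALS") {
  data.frame(cell_barcode = barcodes, sample_id = sample,
             patient_id = patient, tissue = tissue, disease = disease,
             stringsAsFactors = FALSE)
}

# One paired-cell row in the pair_cells() output layout.
cell_row <- function(barcode, sample = "S1", patient = "P1",
                     tissue = "meninges", disease = "ALS",
                     alpha_cdr3 = "TGTGCT", beta_cdr3 = "TGTGCA",
                     alpha_c = "TRAC", beta_v = "TRBV1") {
  data.frame(cell_barcode = barcode, sample_id = sample,
             patient_id = patient, tissue = tissue, disease = disease,
             alpha_v_gene = "TRAV1", alpha_d_gene = NA_character_,
             alpha_j_gene = "TRAJ1", alpha_c_gene = alpha_c,
             alpha_cdr3_nt = alpha_cdr3, alpha_cdr3_aa = "CA",
             alpha_umi_count = 1L,
             beta_v_gene = beta_v, beta_d_gene = "TRBD1",
             beta_j_gene = "TRBJ1", beta_c_gene = "TRBC1",
             beta_cdr3_nt = beta_cdr3, beta_cdr3_aa = "CASS",
             beta_umi_count = 1L, stringsAsFactors = FALSE)
}

# A repertoire with the given clone counts (distinct clones), built through
# call_clones() so internal invariants hold.
rep_from_counts <- function(counts, sample = "S1", patient = "P1",
                            tissue = "meninges", disease = "ALS",
                            beta_cdr3 = NULL) {
  # auto mode builds clone identities unique via distinct beta CDR3s;
  # explicit beta_cdr3 is used verbatim so callers can share clones
  nts <- beta_cdr3 %||% paste0("TGT", strrep("GCA", seq_along(counts)),
                               "TTC")
  idx <- rep(seq_along(counts), counts)
  rows <- cell_row("tmp", sample = sample, patient = patient,
                   tissue = tissue, disease = disease)[
                     rep(1, length(idx)), ]
  rows$cell_barcode <- sprintf("%s_c%04d_%04d", sample, idx,
                               stats::ave(idx, idx, FUN = seq_along))
  rows$beta_cdr3_nt <- nts[idx]
  rownames(rows) <- NULL
  call_clones(rows)$repertoires[[sample]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random paired-cell fixture: n cells drawing clone identities from a pool.
random_cells <- function(n, n_clone_pool = 6, sample = "S1",
                         patient = "P1", tissue = "meninges",
                         disease = "ALS", seed = 1) {
  withr::with_seed(seed, {
    pool_beta <- vapply(seq_len(n_clone_pool), function(i) {
      paste0("TGT", paste(sample(c("GCA", "TTC", "AAA", "GGG"),
                                 6, replace = TRUE), collapse = ""))
    }, character(1))
    pool_beta <- paste0(pool_beta, strrep("AAA", seq_len(n_clone_pool)))
    idx <- sample.int(n_clone_pool, n, replace = TRUE)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cell_row(sprintf("%s_rc%04d", sample, i), sample = sample,
               patient = patient, tissue = tissue, disease = disease,
               beta_cdr3 = pool_beta[idx[i]])
    }))
  })
}

# Memoised recursive Levenshtein oracle (the textbook recursive definition,
# evaluated with a cache so short strings stay cheap).
lev_recursive <- function(a, b) {
  cache <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (nchar(a) == 0L) nchar(b)
    else if (nchar(b) == 0L) nchar(a)
    else {
      cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
      min(rec(substring(a, 2), b) + 1L,
          rec(a, substring(b, 2)) + 1L,
          rec(substring(a, 2), substring(b, 2)) + cost)
    }
    cache[[key]] <- val
    val
  }
  rec(a, b)
}

random_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Small dense expression fixture with named genes.
toy_expression <- function(counts, genes = NULL, cells = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("cell%02d", seq_len(ncol(m)))
  expression_matrix(m)
}
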