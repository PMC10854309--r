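# Synthetic paired brain/meninges cohort generator with known ground truth.

#' Default planted marker effects
#'
#' Marker genes whose expression is shifted in defined cell groups,
#' emulating the structure reported for expanded and brain-shared T cells:
#' residency/activation markers (ZNF683, CXCR6, CCL5) up and lymph-node
#' homing markers (SELL, CCR7) down in expanded cells, CD27 down in
#' brain-shared meningeal cells, and interferon-response genes (ATF3,
#' IFIT2) up in cells from Superexpanded samples.
#'
#' @return list of effects, each a list with `gene`, `attr` (one of
#'   `expansion`, `brain_shared`, `stratum`, `tissue`, `disease`), `values`
#'   (matching attribute values) and `fold` (> 0 multiplier).
#' @export
default_marker_effects <- function() {
  list(
    list(gene = "ZNF683", attr = "expansion",
         values = c("expanded", "hyperexpanded"), fold = 2),
    list(gene = "CXCR6", attr = "expansion",
         values = c("expanded", "hyperexpanded"), fold = 2),
    list(gene = "CCL5", attr = "expansion",
         values = c("expanded", "hyperexpanded"), fold = 2),
    list(gene = "SELL", attr = "expansion",
         values = c("expanded", "hyperexpanded"), fold = 0.5),
    list(gene = "CCR7", attr = "expansion",
         values = c("expanded", "hyperexpanded"), fold = 0.5),
    list(gene = "CD27", attr = "brain_shared", values = "TRUE", fold = 0.5),
    list(gene = "ATF3", attr = "stratum", values = "Superexpanded",
         fold = 2),
    list(gene = "IFIT2", attr = "stratum", values = "Superexpanded",
         fold = 2))
}

#' Simulation parameters for the synthetic cohort
#'
#' Defines the cohort layout and generative law. Each patient contributes
#' one meningeal and one brain sample of `cells_per_tissue` paired-TCR
#' cells. Clone sizes follow a heavy-tailed law (zipf by default); a clone
#' seeds both tissues with probability logistic in
#' `qlogis(sharing_base) + sharing_coupling * log(size)`, so larger clones
#' are more likely shared when `sharing_coupling > 0`. Diseases shift the
#' clone-law exponent (negative shift = heavier tail = lower entropy), and
#' within each disease patients alternate between a Superexpanded-prone and
#' an Expanded-prone role offset by `stratum_shift`, giving every disease
#' group an intended entropy stratification.
#'
#' @param n_patients Number of patients (default 12).
#' @param diseases Named numeric vector: disease label -> clone-law
#'   exponent shift.
#' @param cells_per_tissue Paired-TCR cells per tissue per patient
#'   (default 500).
#' @param clone_law `"zipf"` or `"geometric"`.
#' @param clone_law_param Zipf exponent alpha (default 2.5) or geometric
#'   success probability.
#' @param stratum_shift Within-disease exponent offset creating the two
#'   entropy roles (default 0.9).
#' @param sharing_base Baseline probability that a size-1 clone seeds both
#'   tissues (default 0.05).
#' @param sharing_coupling Log-odds increase of sharing per unit log clone
#'   size (default 2, >= 0).
#' @param marker_effects Planted expression effects; see
#'   [default_marker_effects()].
#' @param n_genes Total number of features, including markers and
#'   mitochondrial pseudo-genes (default 600).
#' @param nb_dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts (default 0.5).
#' @param mito_high_rate Fraction of cells simulated as dying, with
#'   inflated mitochondrial expression (default 0.02).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_patients = 12,
                       diseases = c(ALS = -0.6, PD = -0.6, LOAD = 0.3),
                       cells_per_tissue = 500,
                       clone_law = c("zipf", "geometric"),
                       clone_law_param = 2.5,
                       stratum_shift = 0.9,
                       sharing_base = 0.05,
                       sharing_coupling = 2,
                       marker_effects = default_marker_effects(),
                       n_genes = 600,
                       nb_dispersion = 0.5,
                       mito_high_rate = 0.02,
                       seed = 1L) {
  clone_law <- match.arg(clone_law)
  if (cells_per_tissue < 1) stop("cells_per_tissue must be >= 1")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (is.null(names(diseases)) || any(names(diseases) == "")) {
    stop("diseases must be a named vector of exponent shifts")
  }
  if (sharing_base < 0 || sharing_base > 1) {
    stop("sharing_base must be a probability")
  }
  if (sharing_coupling < 0) stop("sharing_coupling must be >= 0")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  for (e in marker_effects) {
    if (!all(c("gene", "attr", "values", "fold") %in% names(e)) ||
        e$fold <= 0) {
      stop("each marker effect needs gene/attr/values and fold > 0")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), diseases = diseases,
    cells_per_tissue = as.integer(cells_per_tissue),
    clone_law = clone_law, clone_law_param = clone_law_param,
    stratum_shift = stratum_shift, sharing_base = sharing_base,
    sharing_coupling = sharing_coupling, marker_effects = marker_effects,
    n_genes = as.integer(n_genes), nb_dispersion = nb_dispersion,
    mito_high_rate = mito_high_rate, seed = as.integer(seed)),
    class = "sim_params")
}

.rzipf <- function(n, alpha, kmax) {
  sample.int(kmax, n, replace = TRUE, prob = (seq_len(kmax))^(-alpha))
}

.rclone_size <- function(n, params, alpha_eff) {
  if (params$clone_law == "zipf") {
    .rzipf(n, alpha_eff, params$cells_per_tissue)
  } else {
    p <- min(max(params$clone_law_param, 1e-6), 1)
    stats::rgeom(n, p) + 1L
  }
}

.V_A <- paste0("TRAV", 1:8); .J_A <- paste0("TRAJ", 1:6)
.V_B <- paste0("TRBV", 1:8); .D_B <- paste0("TRBD", 1:2)
.J_B <- paste0("TRBJ", 1:6); .C_B <- paste0("TRBC", 1:2)
.CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.rand_cdr3 <- function(n) {
  lens <- sample(seq(30L, 54L, 3L), n, replace = TRUE)
  vapply(lens, function(L) {
    paste0("TGT", paste(sample(.CODONS, L / 3L - 1L, replace = TRUE),
                        collapse = ""))
  }, character(1))
}

.translate_nt <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x)))
}

#' Simulate paired brain/meninges repertoires
#'
#' Draws, per patient, a stream of clones with heavy-tailed sizes, assigns
#' each clone to the meninges, the brain, or both (sharing probability
#' logistic in log clone size), resamples the per-tissue size of a shared
#' clone as a binomial thinning of its parent size, and emits cells with
#' unique sample-scoped barcodes until each tissue's cell budget is filled
#' (the final clone is truncated to the remaining budget). V/D/J/C calls come from a fixed
#' small gene alphabet and CDR3s are random in-frame, stop-free codon runs
#' of 30-54 nt starting with the TGT cysteine codon.
#'
#' @param params A `sim_params` object.
#' @return list of class `sim_repertoires` with `cells` (paired-cell table
#'   in the [pair_cells()] layout plus `clone_uid` and per-chain UMI
#'   counts) and `truth` (patients, samples with expected strata, and
#'   per-clone per-tissue sizes and sharing flags).
#' @export
simulate_repertoires <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, .simulate_repertoires_impl(params))
}

.simulate_repertoires_impl <- function(params) {
  dlab <- names(params$diseases)
  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(params$n_patients)),
    disease = rep(dlab, length.out = params$n_patients),
    stringsAsFactors = FALSE)
  # alternate entropy roles within each disease
  patients$stratum_role <- unlist(lapply(
    split(seq_len(nrow(patients)), patients$disease), function(ix) {
      rep(c("Superexpanded", "Expanded"), length.out = length(ix))
    }))[order(unlist(split(seq_len(nrow(patients)), patients$disease)))]

  clone_rows <- list()
  cell_rows <- list()
  uid <- 0L
  for (p in seq_len(nrow(patients))) {
    pid <- patients$patient_id[p]
    dis <- patients$disease[p]
    role <- patients$stratum_role[p]
    alpha_eff <- max(params$clone_law_param + params$diseases[[dis]] +
                       if (role == "Superexpanded") -params$stratum_shift
                       else params$stratum_shift, 1.05)
    bm <- params$cells_per_tissue
    bb <- params$cells_per_tissue
    pc <- list()
    while (bm > 0L || bb > 0L) {
      s <- .rclone_size(1L, params, alpha_eff)
      eta <- stats::qlogis(params$sharing_base) +
        params$sharing_coupling * log(s)
      shared <- stats::runif(1) < stats::plogis(eta)
      if (shared) {
        # per-tissue sizes are noisy thinnings of the parent clone size, so
        # a large clone stays large in both compartments
        sm <- 1L + stats::rbinom(1L, s - 1L, 0.6)
        sb <- 1L + stats::rbinom(1L, s - 1L, 0.6)
      } else {
        in_men <- if (bm > 0L && bb > 0L) stats::runif(1) < 0.5 else bm > 0L
        sm <- if (in_men) s else 0L
        sb <- if (in_men) 0L else s
      }
      sm <- min(sm, bm); sb <- min(sb, bb)
      if (sm == 0L && sb == 0L) next
      uid <- uid + 1L
      pc[[length(pc) + 1L]] <- data.frame(
        clone_uid = sprintf("K%06d", uid), patient_id = pid, disease = dis,
        base_size = s, size_meninges = sm, size_brain = sb,
        drawn_shared = shared, shared = sm > 0L && sb > 0L,
        stringsAsFactors = FALSE)
      bm <- bm - sm; bb <- bb - sb
    }
    clone_rows[[p]] <- do.call(rbind, pc)
  }
  clones <- do.call(rbind, clone_rows)
  rownames(clones) <- NULL

  nclone <- nrow(clones)
  clones$alpha_v <- sample(.V_A, nclone, replace = TRUE)
  clones$alpha_j <- sample(.J_A, nclone, replace = TRUE)
  clones$alpha_cdr3_nt <- .rand_cdr3(nclone)
  clones$beta_v <- sample(.V_B, nclone, replace = TRUE)
  clones$beta_d <- sample(.D_B, nclone, replace = TRUE)
  clones$beta_j <- sample(.J_B, nclone, replace = TRUE)
  clones$beta_c <- sample(.C_B, nclone, replace = TRUE)
  clones$beta_cdr3_nt <- .rand_cdr3(nclone)
  clones$alpha_cdr3_aa <- .translate_nt(clones$alpha_cdr3_nt)
  clones$beta_cdr3_aa <- .translate_nt(clones$beta_cdr3_nt)

  mk_cells <- function(tissue_label, size_col, sample_prefix) {
    idx <- rep(seq_len(nclone), clones[[size_col]])
    if (!length(idx)) return(NULL)
    sample_id <- paste0(sample_prefix, "_", clones$patient_id[idx])
    df <- data.frame(
      sample_id = sample_id,
      patient_id = clones$patient_id[idx],
      tissue = tissue_label,
      disease = clones$disease[idx],
      clone_uid = clones$clone_uid[idx],
      alpha_v_gene = clones$alpha_v[idx], alpha_d_gene = NA_character_,
      alpha_j_gene = clones$alpha_j[idx], alpha_c_gene = "TRAC",
      alpha_cdr3_nt = clones$alpha_cdr3_nt[idx],
      alpha_cdr3_aa = clones$alpha_cdr3_aa[idx],
      beta_v_gene = clones$beta_v[idx], beta_d_gene = clones$beta_d[idx],
      beta_j_gene = clones$beta_j[idx], beta_c_gene = clones$beta_c[idx],
      beta_cdr3_nt = clones$beta_cdr3_nt[idx],
      beta_cdr3_aa = clones$beta_cdr3_aa[idx],
      stringsAsFactors = FALSE)
    ord <- order(df$sample_id, method = "radix")
    df <- df[ord, , drop = FALSE]
    within_sample <- stats::ave(seq_len(nrow(df)), df$sample_id,
                                FUN = seq_along)
    df$cell_barcode <- sprintf("%s_BC%05d", df$sample_id, within_sample)
    df
  }
  cells <- rbind(mk_cells("meninges", "size_meninges", "MEN"),
                 mk_cells("brain", "size_brain", "BRN"))
  rownames(cells) <- NULL
  cells$alpha_umi_count <- stats::rpois(nrow(cells), 3) + 1L
  cells$beta_umi_count <- stats::rpois(nrow(cells), 5) + 1L
  first <- c("cell_barcode", "sample_id", "patient_id", "tissue", "disease")
  cells <- cells[c(first, setdiff(names(cells), first))]

  samples <- unique(cells[c("sample_id", "patient_id", "tissue", "disease")])
  samples$expected_stratum <-
    patients$stratum_role[match(samples$patient_id, patients$patient_id)]
  samples <- samples[order(samples$sample_id, method = "radix"), ]
  rownames(samples) <- NULL

  structure(list(
    cells = cells,
    truth = list(patients = patients, samples = samples, clones = clones,
                 seed = params$seed)),
    class = "sim_repertoires")
}

# Per-cell attributes used by marker-effect predicates.
.cell_attributes <- function(sim) {
  cells <- sim$cells
  key <- paste(cells$sample_id, cells$clone_uid, sep = .KSEP)
  cnt <- stats::ave(rep(1L, nrow(cells)), key, FUN = sum)
  tot <- stats::ave(rep(1L, nrow(cells)), cells$sample_id, FUN = sum)
  freq <- cnt / tot
  expansion <- ifelse(cnt == 1L, "singleton",
                      ifelse(freq >= 0.05, "hyperexpanded", "expanded"))
  tr <- sim$truth$clones
  shared <- tr$shared[match(cells$clone_uid, tr$clone_uid)]
  stratum <- sim$truth$samples$expected_stratum[
    match(cells$sample_id, sim$truth$samples$sample_id)]
  data.frame(cell_barcode = cells$cell_barcode,
             sample_id = cells$sample_id, tissue = cells$tissue,
             disease = cells$disease, expansion = expansion,
             brain_shared = shared, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Simulate a matched expression matrix
#'
#' Baseline counts are negative binomial per gene per cell with log-normal
#' gene-level means; planted marker effects multiply the mean for cells
#' matching their predicate (attribute in `expansion`, `brain_shared`,
#' `stratum`, `tissue`, `disease`). Five mitochondrial pseudo-genes
#' (`MT-*`) are included, and a small fraction of cells is simulated as
#' dying with inflated mitochondrial means so the QC filter has something
#' to remove. With `nb_dispersion = 0` counts are Poisson.
#'
#' @param sim A `sim_repertoires` object.
#' @param params The `sim_params` used to generate it.
#' @return list with `expression` (an `expr_matrix` over all simulated
#'   cells) and `gene_truth` (data.frame of planted effects; background
#'   genes have fold 1).
#' @export
simulate_expression <- function(sim, params) {
  stopifnot(inherits(sim, "sim_repertoires"),
            inherits(params, "sim_params"))
  withr::with_seed(derive_seed(params$seed, 101L), {
    attrs <- .cell_attributes(sim)
    ncell <- nrow(attrs)
    mito_genes <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "CYB"))
    marker_genes <- vapply(params$marker_effects, `[[`, "", "gene")
    n_bg <- params$n_genes - length(mito_genes) - length(marker_genes)
    if (n_bg < 1) stop("n_genes too small for markers + mito genes")
    genes <- c(marker_genes, sprintf("G%04d", seq_len(n_bg)), mito_genes)

    mu_gene <- stats::rlnorm(length(genes), meanlog = log(1.2), sdlog = 1)
    names(mu_gene) <- genes
    mu_gene[mito_genes] <- 2
    dying <- stats::runif(ncell) < params$mito_high_rate

    effect_mult <- matrix(1, nrow = length(params$marker_effects),
                          ncol = ncell)
    for (i in seq_along(params$marker_effects)) {
      e <- params$marker_effects[[i]]
      if (!e$attr %in% names(attrs)) {
        stop("marker effect references unknown cell attribute: ", e$attr)
      }
      hit <- as.character(attrs[[e$attr]]) %in% as.character(e$values)
      effect_mult[i, hit] <- e$fold
    }

    size <- if (params$nb_dispersion > 0) 1 / params$nb_dispersion else Inf
    rows <- vector("list", length(genes))
    for (g in seq_along(genes)) {
      gene <- genes[g]
      mu <- rep(mu_gene[[gene]], ncell)
      mi <- match(gene, marker_genes)
      if (!is.na(mi)) mu <- mu * effect_mult[mi, ]
      if (gene %in% mito_genes) mu[dying] <- mu[dying] * 25
      rows[[g]] <- if (is.finite(size)) {
        stats::rnbinom(ncell, size = size, mu = mu)
      } else {
        stats::rpois(ncell, mu)
      }
    }
    counts <- do.call(rbind, rows)
    dimnames(counts) <- list(genes, attrs$cell_barcode)

    gene_truth <- data.frame(
      gene = genes,
      attr = NA_character_, values = NA_character_, fold = 1,
      stringsAsFactors = FALSE)
    for (e in params$marker_effects) {
      k <- match(e$gene, gene_truth$gene)
      gene_truth$attr[k] <- e$attr
      gene_truth$values[k] <- paste(e$values, collapse = ",")
      gene_truth$fold[k] <- e$fold
    }
    list(expression = expression_matrix(counts), gene_truth = gene_truth,
         cell_attributes = attrs)
  })
}

#' Simulate a full cohort (repertoires plus expression)
#'
#' @param params A `sim_params` object.
#' @return list of class `sim_cohort` with `cells`, `expression`,
#'   `cell_attributes` and `truth` (repertoire truth plus `genes`).
#' @export
simulate_cohort <- function(params) {
  sim <- simulate_repertoires(params)
  ex <- simulate_expression(sim, params)
  truth <- sim$truth
  truth$genes <- ex$gene_truth
  structure(list(cells = sim$cells, expression = ex$expression,
                 cell_attributes = ex$cell_attributes, truth = truth),
            class = "sim_cohort")
}

#' Expand a paired-cell table into per-chain contig records
#'
#' Produces the normalised contig record layout of [read_contigs()] (two
#' rows per cell, one TRA and one TRB), useful for fault-injection tests
#' and fixture writing.
#'
#' @param cells Paired-cell table (generator output or [pair_cells()]
#'   cells).
#' @return Contig record data.frame.
#' @export
cells_to_contigs <- function(cells) {
  mk <- function(prefix, locus) {
    data.frame(
      cell_barcode = cells$cell_barcode,
      sample_id = cells$sample_id,
      chain_locus = locus,
      v_gene = cells[[paste0(prefix, "_v_gene")]],
      d_gene = cells[[paste0(prefix, "_d_gene")]],
      j_gene = cells[[paste0(prefix, "_j_gene")]],
      c_gene = cells[[paste0(prefix, "_c_gene")]],
      cdr3_nt = cells[[paste0(prefix, "_cdr3_nt")]],
      cdr3_aa = cells[[paste0(prefix, "_cdr3_aa")]],
      productive = TRUE,
      umi_count = cells[[paste0(prefix, "_umi_count")]] %||%
        rep(1L, nrow(cells)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk("alpha", "TRA"), mk("beta", "TRB"))
  out <- out[order(out$sample_id, out$cell_barcode, out$chain_locus,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Inject chain-level faults into a contig table
#'
#' Corrupts a clean contig record table for testing the pairing audit:
#' `n_missing_chain` cells lose their TRA contig (becoming beta-only) and
#' `n_multi_chain` other cells gain a second, distinct TRB contig. The
#' returned fault table gives the injected ground truth.
#'
#' @param records Contig record table (e.g. from [cells_to_contigs()]).
#' @param n_missing_chain,n_multi_chain Number of cells to corrupt.
#' @param seed Integer seed.
#' @return list with `records` (corrupted table) and `faults` (data.frame
#'   `sample_id`, `cell_barcode`, `type`).
#' @export
inject_chain_faults <- function(records, n_missing_chain = 0,
                                n_multi_chain = 0, seed = 1L) {
  ids <- unique(paste(records$sample_id, records$cell_barcode, sep = .KSEP))
  if (n_missing_chain + n_multi_chain > length(ids)) {
    stop("not enough cells to corrupt")
  }
  withr::with_seed(seed, {
    pick <- sample(ids, n_missing_chain + n_multi_chain)
    miss <- pick[seq_len(n_missing_chain)]
    multi <- setdiff(pick, miss)
    rid <- paste(records$sample_id, records$cell_barcode, sep = .KSEP)
    drop <- rid %in% miss & records$chain_locus == "TRA"
    out <- records[!drop, , drop = FALSE]
    extra <- out[paste(out$sample_id, out$cell_barcode, sep = .KSEP) %in%
                   multi & out$chain_locus == "TRB", , drop = FALSE]
    if (nrow(extra)) {
      # mutate the first base so the duplicated chain has a distinct key
      sub <- substr(extra$cdr3_nt, 1, 1)
      substr(extra$cdr3_nt, 1, 1) <- ifelse(sub == "A", "C", "A")
      out <- rbind(out, extra)
    }
    faults <- rbind(
      if (length(miss)) data.frame(
        id = miss, type = "missing_chain", stringsAsFactors = FALSE),
      if (length(multi)) data.frame(
        id = multi, type = "multi_chain", stringsAsFactors = FALSE))
    parts <- strsplit(faults$id, .KSEP, fixed = TRUE)
    faults <- data.frame(
      sample_id = vapply(parts, `[[`, "", 1L),
      cell_barcode = vapply(parts, `[[`, "", 2L),
      type = faults$type, stringsAsFactors = FALSE)
    list(records = out, faults = faults)
  })
}

#' Write a cohort as plain-text fixture files
#'
#' Writes, under `out_dir`: per-sample 10x-dialect contig CSVs
#' (`contigs_10x/<sample>.csv`), AIRR Rearrangement TSV mirrors
#' (`contigs_airr/<sample>.tsv`), the cell metadata table
#' (`metadata.tsv`), the expression triplet (`expression/matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`) when expression is present, and the
#' ground-truth tables (`truth.json`). Files round-trip losslessly through
#' [read_contigs()] and [read_mtx_10x()].
#'
#' @param sim A `sim_repertoires` or `sim_cohort` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(sim, out_dir) {
  cells <- sim$cells
  dir.create(file.path(out_dir, "contigs_10x"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "contigs_airr"), recursive = TRUE,
             showWarnings = FALSE)
  contigs <- cells_to_contigs(cells)
  paths <- character()
  na2 <- function(x, fill) ifelse(is.na(x), fill, x)
  for (s in sort(unique(contigs$sample_id))) {
    sc <- contigs[contigs$sample_id == s, , drop = FALSE]
    tenx <- data.frame(
      barcode = sc$cell_barcode, is_cell = "True",
      contig_id = paste0(sc$cell_barcode, "_", sc$chain_locus),
      high_confidence = "True", length = nchar(sc$cdr3_nt) + 400L,
      chain = sc$chain_locus,
      v_gene = na2(sc$v_gene, "None"), d_gene = na2(sc$d_gene, "None"),
      j_gene = na2(sc$j_gene, "None"), c_gene = na2(sc$c_gene, "None"),
      full_length = "True", productive = ifelse(sc$productive, "True",
                                                "False"),
      cdr3 = na2(sc$cdr3_aa, "None"), cdr3_nt = sc$cdr3_nt,
      reads = sc$umi_count * 10L, umis = sc$umi_count,
      stringsAsFactors = FALSE)
    p <- file.path(out_dir, "contigs_10x", paste0(s, ".csv"))
    utils::write.csv(tenx, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    airr <- data.frame(
      cell_id = sc$cell_barcode, locus = sc$chain_locus,
      v_call = na2(sc$v_gene, ""), d_call = na2(sc$d_gene, ""),
      j_call = na2(sc$j_gene, ""), c_call = na2(sc$c_gene, ""),
      junction = sc$cdr3_nt, junction_aa = na2(sc$cdr3_aa, ""),
      productive = ifelse(sc$productive, "T", "F"),
      duplicate_count = sc$umi_count, stringsAsFactors = FALSE)
    p <- file.path(out_dir, "contigs_airr", paste0(s, ".tsv"))
    .write_tsv(airr, p)
    paths <- c(paths, p)
  }
  md <- cells[c("cell_barcode", "sample_id", "patient_id", "tissue",
                "disease")]
  paths <- c(paths, .write_tsv(md, file.path(out_dir, "metadata.tsv")))
  if (!is.null(sim$expression)) {
    exdir <- file.path(out_dir, "expression")
    dir.create(exdir, showWarnings = FALSE)
    m <- sim$expression$counts
    Matrix::writeMM(m, file.path(exdir, "matrix.mtx"))
    writeLines(colnames(m), file.path(exdir, "barcodes.tsv"))
    utils::write.table(
      data.frame(rownames(m), rownames(m), "Gene Expression"),
      file.path(exdir, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    paths <- c(paths, file.path(exdir, c("matrix.mtx", "barcodes.tsv",
                                         "features.tsv")))
  }
  tp <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, tp, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, tp)
  invisible(paths)
}
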