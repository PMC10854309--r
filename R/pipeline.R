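# End-to-end orchestration: ingest -> clonotyping -> diversity -> lineage
# tracing -> CDR3 homology -> differential expression, with a reproducible
# run manifest.

#' Build a run configuration
#'
#' @param contigs Named character vector of contig file paths (names are
#'   sample ids).
#' @param metadata Path to the cell metadata TSV.
#' @param dialect Contig dialect, `"tenx_csv"` or `"airr_tsv"`.
#' @param expression Optional list with `matrix`, `barcodes`, `features`
#'   paths (or a directory string holding `matrix.mtx`/`barcodes.tsv`/
#'   `features.tsv`).
#' @param out_dir Output directory.
#' @param stages Named logical toggles: `diversity`, `trace`, `homology`,
#'   `de` (ingest and clonotyping always run).
#' @param seed Run seed; all stage randomness derives from it.
#' @param subsample Rarefaction for entropy: `"auto"` (smallest repertoire),
#'   `"off"`, or an integer depth.
#' @param n_boot Rarefaction draws (default 100).
#' @param median_groups Diseases stratified around the median (default
#'   `"PD"`).
#' @param min_cells_cdr3 Cell threshold for the homology screen
#'   (default 10).
#' @param max_dist Candidate-pair edit distance threshold (default 2).
#' @param qc List of QC thresholds passed to [qc_filter()].
#' @return list of class `run_config`.
#' @export
run_config <- function(contigs, metadata, dialect = "tenx_csv",
                       expression = NULL, out_dir = "clonotrace_out",
                       stages = list(diversity = TRUE, trace = TRUE,
                                     homology = TRUE, de = TRUE),
                       seed = 1L, subsample = "off", n_boot = 100,
                       median_groups = "PD", min_cells_cdr3 = 10,
                       max_dist = 2, qc = list()) {
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("contigs must be a named vector: sample_id -> path")
  }
  if (is.character(expression) && length(expression) == 1) {
    expression <- list(matrix = file.path(expression, "matrix.mtx"),
                       barcodes = file.path(expression, "barcodes.tsv"),
                       features = file.path(expression, "features.tsv"))
  }
  defaults <- list(diversity = TRUE, trace = TRUE, homology = TRUE,
                   de = TRUE)
  stages <- utils::modifyList(defaults, as.list(stages))
  structure(list(contigs = contigs, metadata = metadata, dialect = dialect,
                 expression = expression, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed),
                 subsample = subsample, n_boot = n_boot,
                 median_groups = median_groups,
                 min_cells_cdr3 = min_cells_cdr3, max_dist = max_dist,
                 qc = qc), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest, clonotyping, and the enabled downstream stages, writing
#' every output as plain TSV/JSON under `config$out_dir` together with a
#' run manifest (`manifest.json`) embedding the configuration, MD5 hashes
#' of every input file, per-stage audit counts, and the output file list.
#' Identical configuration and inputs give byte-identical outputs.
#'
#' @param config A `run_config` object.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(unname(config$contigs), config$metadata,
              unlist(config$expression))
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    inputs = as.list(tools::md5sum(inputs)),
    stages = list(), outputs = character())
  emit <- function(path) manifest$outputs <<- c(manifest$outputs,
                                                basename(path))

  # --- ingest ---------------------------------------------------------
  records <- do.call(rbind, lapply(names(config$contigs), function(s) {
    read_contigs(config$contigs[[s]], config$dialect, sample_id = s)
  }))
  filtered <- filter_chains(records)
  metadata <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  paired <- pair_cells(filtered, metadata)
  manifest$stages$ingest <- list(
    contigs_read = nrow(records), contigs_retained = nrow(filtered),
    cells_in = sum(paired$audit$kept) +
      sum(paired$audit$dropped_missing_chain) +
      sum(paired$audit$dropped_multi_chain),
    cells_kept = sum(paired$audit$kept),
    cells_dropped = sum(paired$audit$dropped_missing_chain) +
      sum(paired$audit$dropped_multi_chain))
  write_paired_cells(paired, file.path(out, "cells_paired.tsv"),
                     file.path(out, "ingest_audit.json"))
  emit("cells_paired.tsv"); emit("ingest_audit.json")

  # --- clonotyping ----------------------------------------------------
  cc <- call_clones(paired$cells)
  manifest$stages$clonotyping <- list(
    cells_in = nrow(paired$cells),
    cells_assigned = sum(vapply(cc$repertoires, `[[`, 0, "total_cells")),
    n_clones = nrow(cc$registry),
    n_samples = length(cc$repertoires))
  write_clone_tables(cc, file.path(out, "clones.tsv"),
                     file.path(out, "clone_registry.tsv"))
  emit("clones.tsv"); emit("clone_registry.tsv")
  labels <- lapply(cc$repertoires, classify_expansion)

  # --- diversity / strata ---------------------------------------------
  if (isTRUE(config$stages$diversity)) {
    depth <- config$subsample
    if (identical(depth, "auto")) {
      depth <- min(vapply(cc$repertoires, `[[`, 0, "total_cells"))
    }
    ent <- vapply(cc$repertoires, function(r) {
      if (identical(depth, "off") || is.null(depth)) shannon_entropy(r)
      else shannon_entropy(r, subsample_to = min(depth, r$total_cells),
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, 11L))
    }, numeric(1))
    edf <- data.frame(
      sample_id = names(ent),
      disease = vapply(cc$repertoires, `[[`, "", "disease"),
      tissue = vapply(cc$repertoires, `[[`, "", "tissue"),
      shannon_entropy = unname(ent), stringsAsFactors = FALSE)
    men <- edf[edf$tissue == "meninges", , drop = FALSE]
    strat_in <- if (nrow(men)) men else edf
    strata <- withCallingHandlers(
      stratify_samples(strat_in, median_groups = config$median_groups),
      warning = function(w) invokeRestart("muffleWarning"))
    .write_tsv(strata, file.path(out, "strata.tsv"))
    emit("strata.tsv")
    manifest$stages$diversity <- list(
      samples_in = nrow(strat_in),
      samples_stratified = if (is.null(strata)) 0L else nrow(strata),
      rarefaction_depth = if (identical(config$subsample, "off")) "off"
                          else depth)
  } else {
    strata <- NULL
    manifest$stages$diversity <- list(skipped = TRUE)
  }

  # --- lineage tracing ------------------------------------------------
  shared_flags <- list()
  if (isTRUE(config$stages$trace)) {
    tissues <- vapply(cc$repertoires, `[[`, "", "tissue")
    pats <- vapply(cc$repertoires, `[[`, "", "patient_id")
    overlap_rows <- list(); summary_rows <- list(); annot_rows <- list()
    for (pid in sort(unique(pats))) {
      men_s <- names(cc$repertoires)[pats == pid & tissues == "meninges"]
      brn_s <- names(cc$repertoires)[pats == pid & tissues == "brain"]
      for (ms in men_s) for (bs in brn_s) {
        mrep <- cc$repertoires[[ms]]; brep <- cc$repertoires[[bs]]
        flags <- flag_shared_clones(mrep, brep)
        shared_flags[[ms]] <- flags
        overlap_rows[[paste(ms, bs)]] <- data.frame(
          patient_id = pid, disease = mrep$disease,
          meninges_sample = ms, brain_sample = bs,
          morisita = morisita_overlap(mrep, brep),
          shared_clone_count = sum(flags), stringsAsFactors = FALSE)
        summary_rows[[paste(ms, bs)]] <-
          summarize_shared_expansion(mrep, flags, labels[[ms]])
        annot_rows[[ms]] <- annotate_brain_shared(mrep, flags)
      }
    }
    overlap <- do.call(rbind, overlap_rows)
    if (!is.null(overlap)) rownames(overlap) <- NULL
    .write_tsv(overlap %||% data.frame(), file.path(out, "overlap.tsv"))
    .write_tsv(do.call(rbind, summary_rows) %||% data.frame(),
               file.path(out, "shared_summary.tsv"))
    .write_tsv(do.call(rbind, annot_rows) %||% data.frame(),
               file.path(out, "meningeal_cells_annotated.tsv"))
    emit("overlap.tsv"); emit("shared_summary.tsv")
    emit("meningeal_cells_annotated.tsv")
    manifest$stages$trace <- list(
      patients_paired = length(unique(overlap$patient_id %||% character())),
      overlaps_computed = length(overlap_rows))
  } else {
    manifest$stages$trace <- list(skipped = TRUE)
  }

  # --- CDR3 homology ---------------------------------------------------
  if (isTRUE(config$stages$homology)) {
    entries <- select_expanded_cdr3(cc, min_cells = config$min_cells_cdr3)
    if (nrow(entries) >= 2) {
      dm <- distance_matrix(entries, max_dist = config$max_dist)
      mat_df <- data.frame(tagged_id = dm$ids,
                           as.data.frame(dm$values),
                           check.names = FALSE, stringsAsFactors = FALSE)
      .write_tsv(mat_df, file.path(out, "cdr3_distance_matrix.tsv"))
      .write_tsv(dm$candidates, file.path(out, "cdr3_candidates.tsv"))
      emit("cdr3_distance_matrix.tsv"); emit("cdr3_candidates.tsv")
      manifest$stages$homology <- list(
        entries = nrow(entries), candidate_pairs = nrow(dm$candidates))
    } else {
      manifest$stages$homology <- list(
        entries = nrow(entries),
        skipped_reason = "fewer than 2 clones passed the cell threshold")
    }
  } else {
    manifest$stages$homology <- list(skipped = TRUE)
  }

  # --- differential expression ----------------------------------------
  if (isTRUE(config$stages$de) && !is.null(config$expression)) {
    ex <- read_mtx_10x(matrix_file = config$expression$matrix,
                       barcodes_file = config$expression$barcodes,
                       features_file = config$expression$features)
    qcd <- do.call(qc_filter, c(list(ex), config$qc))
    nm <- suppressWarnings(normalize_counts(qcd$matrix))
    # expansion state of every paired meningeal cell
    men_reps <- Filter(function(r) r$tissue == "meninges", cc$repertoires)
    cell_expansion <- do.call(rbind, lapply(men_reps, function(r) {
      lab <- labels[[r$sample_id]]
      data.frame(cell_barcode = r$cells$cell_barcode,
                 expansion = lab$expansion[match(r$cells$clone_id,
                                                 lab$clone_id)],
                 stringsAsFactors = FALSE)
    }))
    avail <- intersect(cell_expansion$cell_barcode, colnames(nm$normalized))
    ce <- cell_expansion[cell_expansion$cell_barcode %in% avail, ]
    g_exp <- ce$cell_barcode[ce$expansion != "singleton"]
    g_sing <- ce$cell_barcode[ce$expansion == "singleton"]
    de1 <- tryCatch(rank_sum_de(nm, g_exp, g_sing),
                    error = function(e) NULL)
    if (!is.null(de1)) {
      .write_tsv(de1, file.path(out, "de_expanded_vs_singleton.tsv"))
      emit("de_expanded_vs_singleton.tsv")
    }
    de2 <- NULL
    if (length(shared_flags)) {
      ann <- do.call(rbind, lapply(names(shared_flags), function(ms) {
        annotate_brain_shared(cc$repertoires[[ms]], shared_flags[[ms]])
      }))
      ann <- ann[ann$cell_barcode %in% colnames(nm$normalized), ]
      de2 <- tryCatch(
        rank_sum_de(nm, ann$cell_barcode[ann$brain_shared],
                    ann$cell_barcode[!ann$brain_shared]),
        error = function(e) NULL)
      if (!is.null(de2)) {
        .write_tsv(de2, file.path(out, "de_brain_shared.tsv"))
        emit("de_brain_shared.tsv")
      }
    }
    manifest$stages$de <- list(
      cells_in = ncol(ex$counts), cells_after_qc = ncol(qcd$matrix$counts),
      qc_audit = qcd$audit,
      expanded_vs_singleton = !is.null(de1),
      brain_shared = !is.null(de2))
  } else {
    manifest$stages$de <- list(skipped = TRUE)
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
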