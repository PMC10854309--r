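# Ingest of TCR contig annotation tables and resolution of cells to single
# complete alpha/beta chain pairs.

#' Read a TCR contig annotation table
#'
#' Reads one per-sample contig table in either the 10x Genomics
#' `filtered_contig_annotations.csv` dialect or the AIRR Rearrangement TSV
#' dialect into a normalised contig record table (one row per assembled TCR
#' chain contig per cell barcode).
#'
#' Boolean literals of both dialects (`"True"`, `"TRUE"`, `"T"`, AIRR
#' `"T"`/`"F"`, ...) are normalised to logical; empty strings and `"None"`
#' become `NA` (absent). Loci other than TRA/TRB are kept with
#' `chain_locus = "other"` so downstream filters can drop them explicitly.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @param sample_id Sample identifier attached to every record. Defaults to
#'   the file name without extension.
#' @return A data.frame with columns `cell_barcode`, `sample_id`,
#'   `chain_locus`, `v_gene`, `d_gene`, `j_gene`, `c_gene`, `cdr3_nt`,
#'   `cdr3_aa`, `productive`, `umi_count`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "barcode,chain,v_gene,d_gene,j_gene,c_gene,cdr3_nt,cdr3,productive,umis",
#'   "BC1,TRA,TRAV1,None,TRAJ2,TRAC,TGTGCT,CA,True,4"), f)
#' read_contigs(f, "tenx_csv", sample_id = "S1")
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv"),
                         sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("contig file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.airr$", "", tools::file_path_sans_ext(basename(path)))
  }
  if (dialect == "tenx_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
    req <- c("barcode", "chain", "v_gene", "d_gene", "j_gene", "c_gene",
             "cdr3_nt", "productive")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      stop("tenx_csv file is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    }
    out <- data.frame(
      cell_barcode = df$barcode,
      sample_id = sample_id,
      chain_locus = ifelse(df$chain %in% c("TRA", "TRB"), df$chain, "other"),
      v_gene = .absent_to_na(df$v_gene),
      d_gene = .absent_to_na(df$d_gene),
      j_gene = .absent_to_na(df$j_gene),
      c_gene = .absent_to_na(df$c_gene),
      cdr3_nt = .absent_to_na(df$cdr3_nt),
      cdr3_aa = if ("cdr3" %in% names(df)) .absent_to_na(df$cdr3)
                else NA_character_,
      productive = .parse_bool(df$productive),
      umi_count = if ("umis" %in% names(df))
        suppressWarnings(as.integer(df$umis)) else 0L,
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    req <- c("cell_id", "locus", "v_call", "d_call", "j_call", "c_call",
             "junction", "productive")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      stop("airr_tsv file is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    }
    out <- data.frame(
      cell_barcode = df$cell_id,
      sample_id = sample_id,
      chain_locus = ifelse(df$locus %in% c("TRA", "TRB"), df$locus, "other"),
      v_gene = .absent_to_na(df$v_call),
      d_gene = .absent_to_na(df$d_call),
      j_gene = .absent_to_na(df$j_call),
      c_gene = .absent_to_na(df$c_call),
      cdr3_nt = .absent_to_na(df$junction),
      cdr3_aa = if ("junction_aa" %in% names(df))
        .absent_to_na(df$junction_aa) else NA_character_,
      productive = .parse_bool(df$productive),
      umi_count = if ("duplicate_count" %in% names(df))
        suppressWarnings(as.integer(df$duplicate_count)) else 0L,
      stringsAsFactors = FALSE)
  }
  out$umi_count[is.na(out$umi_count)] <- 0L
  out
}

#' Retain complete, productive TRA/TRB contigs
#'
#' Keeps only contig records that are productive, lie on the TRA or TRB
#' locus, and carry a non-empty CDR3 nucleotide sequence free of ambiguity
#' codes (pure A/C/G/T). This is the chain-level "complete CDR3" filter
#' applied before pairing; it is idempotent.
#'
#' @param records Contig record table from [read_contigs()].
#' @return The retained subset of `records`.
#' @export
filter_chains <- function(records) {
  keep <- !is.na(records$productive) & records$productive &
    records$chain_locus %in% c("TRA", "TRB") &
    !is.na(records$cdr3_nt) & grepl("^[ACGT]+$", records$cdr3_nt)
  records[keep, , drop = FALSE]
}

#' Resolve cells to single alpha/beta chain pairs
#'
#' A cell is emitted if and only if it carries exactly one retained TRA chain
#' and exactly one retained TRB chain (counted over distinct chain keys, so
#' duplicate assemblies of the same chain do not make a cell ambiguous).
#' Cells with zero or two-plus distinct chains of either locus are dropped
#' and tallied in a per-sample audit. Cell barcodes are sample-scoped:
#' identity is `(sample_id, cell_barcode)`.
#'
#' @param records Contig records, already passed through [filter_chains()].
#' @param metadata Cell metadata data.frame with columns `cell_barcode`,
#'   `sample_id`, `patient_id`, `tissue`, `disease`.
#' @return A list with
#'   \describe{
#'     \item{cells}{data.frame of paired cells, one row per cell, with
#'       metadata columns plus flattened `alpha_*`/`beta_*` chain fields.}
#'     \item{audit}{per-sample data.frame with `kept`,
#'       `dropped_missing_chain`, `dropped_multi_chain` counts.}
#'   }
#' @export
pair_cells <- function(records, metadata) {
  req_md <- c("cell_barcode", "sample_id", "patient_id", "tissue", "disease")
  miss <- setdiff(req_md, names(metadata))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0) {
    return(list(cells = .empty_cells(), audit = data.frame(
      sample_id = character(), kept = integer(),
      dropped_missing_chain = integer(), dropped_multi_chain = integer(),
      stringsAsFactors = FALSE)))
  }
  records$.ckey <- chain_key(records$v_gene, records$d_gene, records$j_gene,
                             records$c_gene, records$cdr3_nt)
  # duplicate assemblies of an identical chain collapse to one observation
  records <- records[!duplicated(records[c("sample_id", "cell_barcode",
                                           "chain_locus", ".ckey")]), ,
                     drop = FALSE]
  cid <- paste(records$sample_id, records$cell_barcode, sep = .KSEP)
  cells <- records[!duplicated(cid), c("sample_id", "cell_barcode")]
  ids <- paste(cells$sample_id, cells$cell_barcode, sep = .KSEP)
  ta <- table(cid[records$chain_locus == "TRA"])
  tb <- table(cid[records$chain_locus == "TRB"])
  n_a <- as.integer(ta[ids]); n_a[is.na(n_a)] <- 0L
  n_b <- as.integer(tb[ids]); n_b[is.na(n_b)] <- 0L
  multi <- n_a >= 2L | n_b >= 2L
  missing_chain <- !multi & (n_a == 0L | n_b == 0L)
  kept <- n_a == 1L & n_b == 1L

  audit <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$sample_id),
    function(ix) data.frame(
      sample_id = cells$sample_id[ix[1]],
      kept = sum(kept[ix]),
      dropped_missing_chain = sum(missing_chain[ix]),
      dropped_multi_chain = sum(multi[ix]),
      stringsAsFactors = FALSE)))
  rownames(audit) <- NULL

  if (!any(kept)) {
    return(list(cells = .empty_cells(), audit = audit))
  }
  kept_ids <- ids[kept]
  flat <- function(locus, prefix) {
    r <- records[records$chain_locus == locus &
                   cid %in% kept_ids, , drop = FALSE]
    r <- r[match(kept_ids, paste(r$sample_id, r$cell_barcode, sep = .KSEP)), ]
    out <- r[c("v_gene", "d_gene", "j_gene", "c_gene", "cdr3_nt", "cdr3_aa",
               "umi_count")]
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  cells_out <- cbind(cells[kept, , drop = FALSE],
                     flat("TRA", "alpha"), flat("TRB", "beta"))
  rownames(cells_out) <- NULL

  md_ids <- paste(metadata$sample_id, metadata$cell_barcode, sep = .KSEP)
  mi <- match(kept_ids, md_ids)
  if (anyNA(mi)) {
    bad <- cells_out$cell_barcode[is.na(mi)]
    stop("no metadata for cell barcode(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  cells_out$patient_id <- metadata$patient_id[mi]
  cells_out$tissue <- metadata$tissue[mi]
  cells_out$disease <- metadata$disease[mi]
  first <- c("cell_barcode", "sample_id", "patient_id", "tissue", "disease")
  cells_out <- cells_out[c(first, setdiff(names(cells_out), first))]
  list(cells = cells_out, audit = audit)
}

.empty_cells <- function() {
  cols <- c("cell_barcode", "sample_id", "patient_id", "tissue", "disease",
            paste0("alpha_", c("v_gene", "d_gene", "j_gene", "c_gene",
                               "cdr3_nt", "cdr3_aa", "umi_count")),
            paste0("beta_", c("v_gene", "d_gene", "j_gene", "c_gene",
                              "cdr3_nt", "cdr3_aa", "umi_count")))
  df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Write a paired-cell table and its audit report
#'
#' @param paired Result of [pair_cells()].
#' @param cells_path Output TSV path for the paired-cell table.
#' @param audit_path Output JSON path for the per-sample audit counts.
#' @return Invisibly, the two paths.
#' @export
write_paired_cells <- function(paired, cells_path, audit_path) {
  .write_tsv(paired$cells, cells_path)
  jsonlite::write_json(paired$audit, audit_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(cells_path, audit_path))
}
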