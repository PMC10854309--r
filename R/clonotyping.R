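# Clone calling by strict paired VDJC + CDR3-nucleotide identity, and
# per-sample expansion classification.

#' Call clones from paired cells
#'
#' Two cells belong to the same clone iff their V/D/J/C gene calls and CDR3
#' nucleotide sequences are identical field-wise on both the alpha and beta
#' chain (absent fields compare equal only to absent fields). Amino-acid
#' CDR3s and UMI counts play no part in clone identity. Clone ids are
#' assigned from the lexicographically sorted set of clone keys, so the
#' registry is invariant under permutation of the input rows and is shared
#' across all samples and tissues of one run.
#'
#' @param cells Paired-cell data.frame from [pair_cells()].
#' @return An object of class `clone_call`: a list with
#'   \describe{
#'     \item{repertoires}{named list of per-sample `repertoire` objects
#'       (see [repertoire]).}
#'     \item{registry}{run-level data.frame mapping `clone_id` to the
#'       flattened chain fields.}
#'   }
#' @export
call_clones <- function(cells) {
  if (is.null(cells) || nrow(cells) == 0) stop("no paired cells to clonotype")
  akey <- chain_key(cells$alpha_v_gene, cells$alpha_d_gene,
                    cells$alpha_j_gene, cells$alpha_c_gene,
                    cells$alpha_cdr3_nt)
  bkey <- chain_key(cells$beta_v_gene, cells$beta_d_gene, cells$beta_j_gene,
                    cells$beta_c_gene, cells$beta_cdr3_nt)
  cells$clone_key <- paste(akey, bkey, sep = .CSEP)
  ukeys <- sort(unique(cells$clone_key), method = "radix")
  id_of <- stats::setNames(sprintf("C%05d", seq_along(ukeys)), ukeys)
  cells$clone_id <- unname(id_of[cells$clone_key])

  reg_rows <- cells[!duplicated(cells$clone_key), , drop = FALSE]
  reg_rows <- reg_rows[order(reg_rows$clone_id, method = "radix"), ]
  reg_cols <- c("clone_id",
                paste0("alpha_", c("v_gene", "d_gene", "j_gene", "c_gene",
                                   "cdr3_nt", "cdr3_aa")),
                paste0("beta_", c("v_gene", "d_gene", "j_gene", "c_gene",
                                  "cdr3_nt", "cdr3_aa")),
                "clone_key")
  registry <- reg_rows[reg_cols]
  rownames(registry) <- NULL

  reps <- lapply(split(cells, cells$sample_id), function(sc) {
    tab <- table(sc$clone_id)
    clones <- data.frame(clone_id = names(tab),
                         count = as.integer(tab),
                         stringsAsFactors = FALSE)
    clones$frequency <- clones$count / nrow(sc)
    clones$clone_key <- registry$clone_key[match(clones$clone_id,
                                                 registry$clone_id)]
    clones <- clones[order(clones$clone_id, method = "radix"), ]
    rownames(clones) <- NULL
    structure(list(
      sample_id = sc$sample_id[1],
      patient_id = sc$patient_id[1],
      tissue = sc$tissue[1],
      disease = sc$disease[1],
      clones = clones,
      total_cells = nrow(sc),
      cells = sc[c("cell_barcode", "clone_id")]), class = "repertoire")
  })
  reps <- reps[sort(names(reps), method = "radix")]
  structure(list(repertoires = reps, registry = registry),
            class = "clone_call")
}

#' Per-sample clone repertoire
#'
#' A `repertoire` is the per-sample clone table produced by [call_clones()]:
#' sample context (`sample_id`, `patient_id`, `tissue`, `disease`), a
#' `clones` data.frame (`clone_id`, `count`, `frequency`, `clone_key`),
#' `total_cells`, and the per-cell clone assignment in `cells`.
#'
#' @param x A `repertoire` object.
#' @param ... Ignored.
#' @name repertoire
#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("repertoire '%s' (%s, %s, %s): %d cells, %d clones\n",
              x$sample_id, x$patient_id, x$tissue, x$disease,
              x$total_cells, nrow(x$clones)))
  invisible(x)
}

#' Classify clonal expansion within a sample
#'
#' A clone seen in exactly one cell is a `singleton`; a clone seen in two or
#' more cells is `expanded`, and additionally `hyperexpanded` when it makes
#' up at least 5% of the sample's paired-TCR cells. The frequency
#' denominator is the number of cells with a resolved paired clone in the
#' sample. The count rule takes precedence: in a tiny repertoire a
#' single-cell clone above 5% frequency remains a singleton, since
#' hyperexpansion is a stronger form of multi-cell expansion.
#'
#' @param rep A `repertoire` object.
#' @param hyper_threshold Repertoire fraction at or above which an expanded
#'   clone is hyperexpanded (default 0.05).
#' @return data.frame with `clone_id`, `count`, `frequency`, `expansion`.
#' @export
classify_expansion <- function(rep, hyper_threshold = 0.05) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clones
  lab <- ifelse(cl$count == 1L, "singleton",
                ifelse(cl$frequency >= hyper_threshold,
                       "hyperexpanded", "expanded"))
  data.frame(clone_id = cl$clone_id, count = cl$count,
             frequency = cl$frequency, expansion = lab,
             stringsAsFactors = FALSE)
}

#' Fraction of a repertoire occupied by its largest clone
#'
#' @param rep A `repertoire` object.
#' @return The maximum clone frequency, in (0, 1].
#' @export
top_clone_fraction <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep$clones) == 0) stop("empty repertoire")
  max(rep$clones$frequency)
}

#' Write per-sample clone tables and the run-level registry
#'
#' @param cc A `clone_call` object.
#' @param clones_path Output TSV for the per-sample clone table (one row per
#'   clone per sample, with expansion labels).
#' @param registry_path Output TSV for the run-level clone registry.
#' @return Invisibly, the paths.
#' @export
write_clone_tables <- function(cc, clones_path, registry_path) {
  stopifnot(inherits(cc, "clone_call"))
  per_sample <- do.call(rbind, lapply(cc$repertoires, function(r) {
    lab <- classify_expansion(r)
    data.frame(sample_id = r$sample_id, patient_id = r$patient_id,
               tissue = r$tissue, disease = r$disease, lab,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  .write_tsv(per_sample, clones_path)
  reg <- cc$registry[setdiff(names(cc$registry), "clone_key")]
  .write_tsv(reg, registry_path)
  invisible(c(clones_path, registry_path))
}
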