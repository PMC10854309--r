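# Cross-tissue clonal overlap and shared-clone expansion summaries.

#' Morisita-Horn overlap between two repertoires
#'
#' Abundance-weighted overlap of two clone repertoires on the union of their
#' clone keys. The default `"horn"` variant is the bounded Morisita-Horn
#' index
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\, X Y}}
#' with cell counts x, y and totals X, Y; it is symmetric, lies in [0, 1],
#' equals 1 for identical normalised repertoires and 0 for disjoint clone
#' sets, and is invariant to scaling all counts of one repertoire. The
#' `"classical"` variant uses the original Morisita similarity with
#' size-corrected concentration terms \eqn{\sum x_i(x_i-1)/(X(X-1))}; it can
#' slightly exceed 1.
#'
#' @param rep_a,rep_b `repertoire` objects from the same [call_clones()] run
#'   (clone keys must be comparable).
#' @param variant `"horn"` (bounded, default) or `"classical"`.
#' @return Overlap index (scalar).
#' @export
morisita_overlap <- function(rep_a, rep_b, variant = c("horn", "classical")) {
  variant <- match.arg(variant)
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  if (nrow(rep_a$clones) == 0 || nrow(rep_b$clones) == 0) {
    stop("empty repertoire")
  }
  keys <- union(rep_a$clones$clone_key, rep_b$clones$clone_key)
  x <- rep_a$clones$count[match(keys, rep_a$clones$clone_key)]
  y <- rep_b$clones$count[match(keys, rep_b$clones$clone_key)]
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  X <- sum(x); Y <- sum(y)
  num <- 2 * sum(x * y)
  if (num == 0) return(0)
  if (variant == "horn") {
    num / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  } else {
    lx <- sum(x * (x - 1)) / (X * (X - 1))
    ly <- sum(y * (y - 1)) / (Y * (Y - 1))
    num / ((lx + ly) * X * Y)
  }
}

#' Flag meningeal clones shared with the matched brain repertoire
#'
#' A meningeal clone is flagged as brain-shared iff its clone key occurs
#' with count >= 1 in the matched brain repertoire of the same patient.
#' Matching is exact clone-key equality (paired VDJC + CDR3 nucleotide),
#' with no edit-distance tolerance.
#'
#' @param meninges_rep,brain_rep `repertoire` objects of one patient.
#' @return Named logical vector over the meningeal clone ids.
#' @export
flag_shared_clones <- function(meninges_rep, brain_rep) {
  stopifnot(inherits(meninges_rep, "repertoire"),
            inherits(brain_rep, "repertoire"))
  if (!identical(meninges_rep$patient_id, brain_rep$patient_id)) {
    stop("repertoires belong to different patients: ",
         meninges_rep$patient_id, " vs ", brain_rep$patient_id)
  }
  stats::setNames(
    meninges_rep$clones$clone_key %in% brain_rep$clones$clone_key,
    meninges_rep$clones$clone_id)
}

#' Summarise expansion of brain-shared meningeal clones
#'
#' Counts meningeal cells and singleton cells, and among clones shared with
#' the brain, the ones labelled expanded or hyperexpanded in the meninges.
#' The headline fraction is reported both clone-wise (shared clones that are
#' expanded / shared clones) and cell-wise (meningeal cells in shared
#' expanded clones / meningeal cells in shared clones), since "shared TCRs
#' that are expanded" admits either denominator. With no shared clones both
#' fractions are `NA`.
#'
#' @param meninges_rep `repertoire` of the meningeal sample.
#' @param flags Logical vector from [flag_shared_clones()], named by the
#'   meningeal clone ids.
#' @param labels Expansion table from [classify_expansion()] on
#'   `meninges_rep`.
#' @return One-row data.frame: `patient_id`, `n_meningeal_cells`,
#'   `n_meningeal_singleton_cells`, `n_shared_clones`,
#'   `n_shared_clones_expanded_in_meninges`,
#'   `fraction_shared_expanded_clonewise`,
#'   `fraction_shared_expanded_cellwise`.
#' @export
summarize_shared_expansion <- function(meninges_rep, flags, labels) {
  stopifnot(inherits(meninges_rep, "repertoire"))
  cl <- meninges_rep$clones
  if (!all(cl$clone_id %in% names(flags)) ||
      !all(cl$clone_id %in% labels$clone_id)) {
    stop("flags and labels must be keyed on the meningeal repertoire's clones")
  }
  lab <- labels$expansion[match(cl$clone_id, labels$clone_id)]
  shared <- unname(flags[cl$clone_id])
  expanded <- lab %in% c("expanded", "hyperexpanded")
  n_shared <- sum(shared)
  n_shared_exp <- sum(shared & expanded)
  data.frame(
    patient_id = meninges_rep$patient_id,
    n_meningeal_cells = meninges_rep$total_cells,
    n_meningeal_singleton_cells = sum(cl$count[lab == "singleton"]),
    n_shared_clones = n_shared,
    n_shared_clones_expanded_in_meninges = n_shared_exp,
    fraction_shared_expanded_clonewise =
      if (n_shared == 0) NA_real_ else n_shared_exp / n_shared,
    fraction_shared_expanded_cellwise =
      if (n_shared == 0) NA_real_ else
        sum(cl$count[shared & expanded]) / sum(cl$count[shared]),
    stringsAsFactors = FALSE)
}

#' Compare per-patient overlap values between two disease groups
#'
#' Two-sided Wilcoxon rank-sum test of per-patient Morisita-Horn overlap
#' values between two disease groups.
#'
#' @param overlap_df data.frame with columns `patient_id`, `disease`,
#'   `morisita`.
#' @param groups Character vector of the two disease labels to compare.
#' @return list with `statistic` (W), `p_value`, `groups`, and per-group
#'   sizes `n`.
#' @export
overlap_group_comparison <- function(overlap_df, groups) {
  stopifnot(length(groups) == 2)
  a <- overlap_df$morisita[overlap_df$disease == groups[1]]
  b <- overlap_df$morisita[overlap_df$disease == groups[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("each compared group needs at least 2 patients")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       groups = groups, n = c(length(a), length(b)))
}

#' Per-cell brain-shared annotation for a meningeal sample
#'
#' @param meninges_rep `repertoire` of the meningeal sample.
#' @param flags Logical vector from [flag_shared_clones()].
#' @return data.frame with `cell_barcode`, `sample_id`, `clone_id`,
#'   `brain_shared`.
#' @export
annotate_brain_shared <- function(meninges_rep, flags) {
  cells <- meninges_rep$cells
  data.frame(cell_barcode = cells$cell_barcode,
             sample_id = meninges_rep$sample_id,
             clone_id = cells$clone_id,
             brain_shared = unname(flags[cells$clone_id]),
             stringsAsFactors = FALSE)
}
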