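# Shannon-entropy clonal diversity and sample stratification.

#' Shannon entropy of a clone distribution
#'
#' Computes H = -sum(p_i log p_i) in nats over the clone frequencies of a
#' repertoire, unnormalised (no division by log richness). With
#' `subsample_to` set, the repertoire is rarefied: `n_boot` draws of
#' `subsample_to` cells are taken without replacement and the mean entropy
#' across draws is returned, equalising sequencing depth across samples.
#' Rarefying to the full repertoire size reproduces the unrarefied value
#' exactly, since sampling all cells without replacement returns the same
#' multiset every draw.
#'
#' @param x A `repertoire` object or a vector of positive clone counts.
#' @param subsample_to Optional rarefaction depth (cells), at most the
#'   repertoire size.
#' @param n_boot Number of rarefaction draws (default 100).
#' @param seed Integer seed controlling the draws.
#' @return Entropy in nats (non-negative scalar).
#' @export
#' @examples
#' shannon_entropy(c(1, 1, 1, 1)) # log(4)
#' shannon_entropy(c(2, 1, 1))    # 1.0397...
shannon_entropy <- function(x, subsample_to = NULL, n_boot = 100, seed = 1L) {
  counts <- if (inherits(x, "repertoire")) x$clones$count else as.numeric(x)
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts)) stop("empty repertoire")
  H <- function(cn) {
    p <- cn / sum(cn)
    -sum(p * log(p))
  }
  if (is.null(subsample_to)) return(H(counts))
  total <- sum(counts)
  if (subsample_to > total) {
    stop("subsample_to (", subsample_to, ") exceeds repertoire size (",
         total, ")")
  }
  cellvec <- rep.int(seq_along(counts), counts)
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_boot), function(i) {
      H(tabulate(sample(cellvec, subsample_to)))
    }, numeric(1)))
  })
}

#' Stratify samples by Shannon entropy within disease groups
#'
#' Within each disease group, samples with entropy below the group's central
#' value are labelled `Superexpanded` (more clonally expanded, less diverse)
#' and samples at or above it `Expanded`. The centre is the group mean by
#' default; groups named in `median_groups` use the median instead (useful
#' when a group's entropies are skewed). Groups with fewer than two samples
#' cannot be stratified and are excluded with a warning.
#'
#' @param entropy_df data.frame with columns `sample_id`, `disease`,
#'   `shannon_entropy`.
#' @param median_groups Character vector of diseases centred on the median
#'   (default `"PD"`).
#' @return data.frame with columns `sample_id`, `disease`,
#'   `shannon_entropy`, `center_used`, `center_value`, `stratum`.
#' @export
stratify_samples <- function(entropy_df, median_groups = "PD") {
  req <- c("sample_id", "disease", "shannon_entropy")
  miss <- setdiff(req, names(entropy_df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(entropy_df) == 0) stop("no samples to stratify")
  out <- lapply(split(entropy_df, entropy_df$disease), function(g) {
    if (nrow(g) < 2) {
      warning("disease group '", g$disease[1],
              "' has fewer than 2 samples; not stratifiable", call. = FALSE)
      return(NULL)
    }
    use_median <- g$disease[1] %in% median_groups
    ctr <- if (use_median) stats::median(g$shannon_entropy)
           else mean(g$shannon_entropy)
    data.frame(
      sample_id = g$sample_id, disease = g$disease,
      shannon_entropy = g$shannon_entropy,
      center_used = if (use_median) "median" else "mean",
      center_value = ctr,
      stratum = ifelse(g$shannon_entropy < ctr, "Superexpanded", "Expanded"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare entropy across disease groups
#'
#' One-way ANOVA of Shannon entropy on disease group, followed by pairwise
#' Welch t-tests of every other group against a designated reference group,
#' Holm-adjusted. Degenerate inputs are handled explicitly: when all group
#' means are equal with zero between-group variance the F statistic is 0 and
#' p = 1; a pairwise comparison of two constant, identical groups yields
#' p = 1.
#'
#' @param entropy_df data.frame with `sample_id`, `disease`,
#'   `shannon_entropy`; at least two groups of two samples each.
#' @param reference Disease label every other group is compared against.
#' @return list with `f_statistic`, `p_value`, and `posthoc` (data.frame of
#'   per-group p-values against the reference, Holm-adjusted).
#' @export
compare_entropy_groups <- function(entropy_df, reference) {
  tab <- table(entropy_df$disease)
  if (length(tab) < 2) stop("need at least 2 disease groups")
  if (any(tab < 2)) stop("every compared group needs at least 2 samples")
  if (!reference %in% names(tab)) stop("reference group not present")
  d <- data.frame(y = entropy_df$shannon_entropy,
                  g = factor(entropy_df$disease))
  fit <- stats::aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  ss_between <- s[["Sum Sq"]][1]
  if (ss_between <= .Machine$double.eps * sum(s[["Sum Sq"]])) {
    fstat <- 0; pval <- 1
  } else {
    fstat <- s[["F value"]][1]
    pval <- s[["Pr(>F)"]][1]
    if (is.nan(fstat)) { fstat <- 0; pval <- 1 }
    if (is.infinite(fstat)) pval <- 0
  }
  others <- setdiff(names(tab), reference)
  yref <- d$y[d$g == reference]
  pp <- vapply(others, function(gname) {
    yg <- d$y[d$g == gname]
    if (stats::sd(yg) == 0 && stats::sd(yref) == 0) {
      return(if (isTRUE(all.equal(mean(yg), mean(yref)))) 1 else 0)
    }
    tryCatch(stats::t.test(yg, yref)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  posthoc <- data.frame(group = others, reference = reference,
                        p_value = unname(pp),
                        p_adjusted = unname(stats::p.adjust(pp, "holm")),
                        stringsAsFactors = FALSE)
  list(f_statistic = fstat, p_value = pval, posthoc = posthoc)
}
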