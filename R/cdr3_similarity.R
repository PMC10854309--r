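# CDR3 homology screening of highly expanded clones by Levenshtein distance.

#' Select highly expanded CDR3 sequences across samples
#'
#' Collects, from every sample's repertoire, the clones observed in at least
#' `min_cells` cells and tags each entry with a deterministic per-sample
#' suffix ("_a", "_b", ..., "_z", "_aa", ...; samples in sorted order) so
#' the sample source remains identifiable in the distance matrix. The
#' screened sequence is the beta-chain amino-acid CDR3 by default.
#'
#' @param cc A `clone_call` object.
#' @param min_cells Minimum cells per clone per sample (default 10).
#' @param chain `"beta"` or `"alpha"`.
#' @param level `"aa"` or `"nt"`.
#' @return data.frame with `clone_id`, `sample_id`, `sample_tag`,
#'   `tagged_id`, `sequence`, `cell_count` (possibly zero rows).
#' @export
select_expanded_cdr3 <- function(cc, min_cells = 10,
                                 chain = c("beta", "alpha"),
                                 level = c("aa", "nt")) {
  stopifnot(inherits(cc, "clone_call"))
  chain <- match.arg(chain)
  level <- match.arg(level)
  seq_col <- paste0(chain, "_cdr3_", level)
  samples <- sort(names(cc$repertoires), method = "radix")
  tags <- stats::setNames(sample_tags(length(samples)), samples)
  out <- lapply(samples, function(s) {
    r <- cc$repertoires[[s]]
    cl <- r$clones[r$clones$count >= min_cells, , drop = FALSE]
    if (nrow(cl) == 0) return(NULL)
    seqs <- cc$registry[[seq_col]][match(cl$clone_id, cc$registry$clone_id)]
    data.frame(clone_id = cl$clone_id, sample_id = s,
               sample_tag = paste0("_", tags[[s]]),
               tagged_id = paste0(cl$clone_id, "_", tags[[s]]),
               sequence = seqs, cell_count = cl$count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(clone_id = character(), sample_id = character(),
                      sample_tag = character(), tagged_id = character(),
                      sequence = character(), cell_count = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Scalar Levenshtein distance, iterative two-row dynamic programme.
.lev1 <- function(a, b) {
  s <- strsplit(a, "", fixed = TRUE)[[1]]
  t <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(s); m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    cost <- as.integer(s[i] != t)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions converting one string into the other, with unit costs,
#' computed by dynamic programming. Vectorised over pairs with the usual
#' recycling; empty strings are allowed. The result is a metric: symmetric,
#' zero iff the strings are equal, and satisfying the triangle inequality,
#' with `abs(nchar(a) - nchar(b)) <= d <= max(nchar(a), nchar(b))`.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting") # 3
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  as.integer(mapply(.lev1, a, b, USE.NAMES = FALSE))
}

#' Pairwise CDR3 distance matrix with cross-sample candidate pairs
#'
#' Computes all pairwise Levenshtein distances between the tagged CDR3
#' entries and lists the cross-sample pairs at or below `max_dist` edits as
#' candidate shared-specificity pairs. The screen is descriptive: it reports
#' the distance distribution and near matches rather than a significance
#' test.
#'
#' @param entries data.frame from [select_expanded_cdr3()], at least 2 rows.
#' @param max_dist Maximum edit distance for a candidate pair (default 2).
#' @return list of class `cdr3_distances` with `ids`, `values` (symmetric
#'   integer matrix, zero diagonal) and `candidates` (data.frame `id_a`,
#'   `id_b`, `sample_a`, `sample_b`, `distance`).
#' @export
distance_matrix <- function(entries, max_dist = 2) {
  n <- nrow(entries)
  if (n < 2) stop("need at least 2 tagged CDR3 entries")
  D <- matrix(0L, n, n, dimnames = list(entries$tagged_id,
                                        entries$tagged_id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- .lev1(entries$sequence[i], entries$sequence[j])
    }
  }
  cand <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (entries$sample_id[i] != entries$sample_id[j] &&
          D[i, j] <= max_dist) {
        cand[[length(cand) + 1L]] <- data.frame(
          id_a = entries$tagged_id[i], id_b = entries$tagged_id[j],
          sample_a = entries$sample_id[i], sample_b = entries$sample_id[j],
          distance = D[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(id_a = character(), id_b = character(),
               sample_a = character(), sample_b = character(),
               distance = integer(), stringsAsFactors = FALSE)
  structure(list(ids = entries$tagged_id, values = D,
                 candidates = candidates), class = "cdr3_distances")
}
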