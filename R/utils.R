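# Internal helpers shared across modules.

# Field separators for composite chain/clone keys. Control characters cannot
# occur in gene names or CDR3 sequences, so keys are collision-free.
.KSEP <- "\x1f"
.KNA <- "\x01"
.CSEP <- "\x1e"

#' @importFrom withr with_seed
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.absent_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "None" | x == "NA")] <- NA_character_
  x
}

.parse_bool <- function(x) {
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("True", "true", "T", "TRUE")] <- TRUE
  out[x %in% c("False", "false", "F", "FALSE", "None", "")] <- FALSE
  out[is.na(x) | x == "" | x == "None"] <- NA
  out
}

#' Build a composite chain key from VDJC calls and CDR3 nucleotide sequence
#'
#' Equality of two chain keys is field-wise over v/d/j/c gene calls and the
#' CDR3 nucleotide sequence; an absent field (NA) compares equal only to an
#' absent field.
#'
#' @param v,d,j,c Character vectors of gene segment calls (NA for absent).
#' @param cdr3_nt Character vector of CDR3 nucleotide sequences.
#' @return Character vector of opaque key strings.
#' @keywords internal
chain_key <- function(v, d, j, c, cdr3_nt) {
  f <- function(x) ifelse(is.na(x), .KNA, as.character(x))
  paste(f(v), f(d), f(j), f(c), f(cdr3_nt), sep = .KSEP)
}

# Deterministic sample tags: "a".."z", then "aa", "ab", ...
sample_tags <- function(n) {
  tags <- letters
  if (n > 26L) {
    two <- as.vector(t(outer(letters, letters, paste0)))
    tags <- c(tags, two)
  }
  if (n > length(tags)) stop("too many samples to tag (max ", length(tags), ")")
  tags[seq_len(n)]
}

# Derive a stage-specific seed from a run seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
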