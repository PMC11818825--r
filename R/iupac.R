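# IUPAC nucleotide alphabet, bit-encoded so that set membership (does a
# concrete base belong to the set a degenerate code denotes?) is a single
# bitwAnd. A=1, C=2, G=4, T=8; a degenerate code is the OR of its bases.

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_MASK <- vapply(.IUPAC_SETS, function(b) sum(.BASE_BITS[b]), integer(1))

.COMPLEMENT_BASE <- c(A = "T", C = "G", G = "C", T = "A")

# complement of a degenerate code = the code whose set is the complement of
# each member base (R <-> Y, K <-> M, B <-> V, D <-> H; A/T, C/G swap).
.IUPAC_COMPLEMENT <- vapply(names(.IUPAC_SETS), function(code) {
  comp <- sort(unname(.COMPLEMENT_BASE[.IUPAC_SETS[[code]]]))
  names(Filter(function(s) identical(sort(s), comp), .IUPAC_SETS))[1]
}, character(1))

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.validate_iupac <- function(sequence, what = "primer") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(sprintf("%s sequence must be a single non-empty string", what),
         call. = FALSE)
  chars <- .seq_chars(sequence)
  bad <- which(!chars %in% names(.IUPAC_SETS))
  if (length(bad))
    stop(sprintf(
      "invalid IUPAC character '%s' at position %d in %s sequence '%s'",
      chars[bad[1]], bad[1], what, sequence), call. = FALSE)
  invisible(chars)
}

.validate_acgt <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  chars <- .seq_chars(sequence)
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("unexpected character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  invisible(chars)
}

#' Expand a degenerate primer into its concrete sequences
#'
#' A primer written with IUPAC ambiguity codes denotes the pool of all
#' concrete A/C/G/T oligonucleotides obtained by choosing one base at each
#' degenerate position. The number of expansions is the product of the
#' per-position degeneracy counts.
#'
#' @param primer a [degenerate_primer] or a single IUPAC character string.
#' @param max_variants guard against combinatorial explosion; expansion
#'   stops with an error if the pool would exceed this size.
#' @return Character vector of distinct concrete sequences, each the same
#'   length as the input.
#' @examples
#' expand_degenerate("ACGR")          # "ACGA" "ACGG"
#' length(expand_degenerate("RYN"))   # 2 * 2 * 4 = 16
#' @export
expand_degenerate <- function(primer, max_variants = 65536L) {
  sequence <- if (inherits(primer, "degenerate_primer")) primer$sequence
              else primer
  chars <- .validate_iupac(sequence)
  sets <- .IUPAC_SETS[chars]
  n <- prod(lengths(sets))
  if (n > max_variants)
    stop(sprintf("degenerate expansion of '%s' has %d variants (> %d)",
                 sequence, n, max_variants), call. = FALSE)
  out <- Reduce(function(acc, s) as.vector(outer(acc, s, paste0)),
                sets, accumulate = FALSE, "")
  sort(out)
}

#' Reverse complement of concrete DNA sequences
#'
#' @param x character vector of sequences over A/C/G/T.
#' @return Character vector of reverse complements; applying the function
#'   twice returns the input.
#' @examples
#' reverse_complement("GTGCCAGCAGCCGCGGTAA")
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    .validate_acgt(s)
    paste(rev(.seq_chars(chartr("ACGT", "TGCA", s))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# reverse complement in IUPAC space (R -> Y etc.); internal, used to place
# reverse-orientation primers on the sense strand before scanning.
.iupac_revcomp <- function(sequence) {
  chars <- .validate_iupac(sequence)
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

.encode_acgt <- function(sequence) unname(.BASE_BITS[.validate_acgt(sequence)])
.encode_iupac <- function(sequence) unname(.IUPAC_MASK[.validate_iupac(sequence)])
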