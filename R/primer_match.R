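# Ungapped scan of a (possibly degenerate) primer along a concrete
# reference. The minimum over all concrete expansions of the Hamming
# distance at a fixed offset equals the count of positions whose reference
# base is outside the IUPAC set, because expansions form the full Cartesian
# product over positions; this lets the scan work on bitmasks without
# enumerating expansions.
.scan_min <- function(mask, refbits) {
  w <- length(mask)
  l <- length(refbits)
  if (w > l)
    stop(sprintf(
      "primer (%d nt) is longer than the reference (%d nt): reference unusable",
      w, l), call. = FALSE)
  n_off <- l - w + 1L
  idx <- outer(seq_len(n_off) - 1L, seq_len(w), `+`)
  m <- matrix(refbits[idx], n_off, w)
  hits <- matrix(bitwAnd(m, matrix(mask, n_off, w, byrow = TRUE)) == 0L,
                 n_off, w)
  mm <- rowSums(hits)
  best <- which.min(mm)  # first (smallest) offset attaining the minimum
  c(min_mismatches = as.integer(mm[best]), best_offset = best - 1L)
}

#' Minimum mismatches of a primer against a reference sequence
#'
#' Slides the primer (or every member of a set of concrete variants) along
#' the reference without gaps and returns the smallest Hamming distance and
#' the 0-based offset attaining it (ties broken by the smallest offset).
#' Reverse-orientation primers are reverse-complemented first, so the scan
#' always runs on the sense strand. A mismatch count of 0 means the
#' reference contains an exact binding site for at least one expansion of
#' the primer.
#'
#' @param primer a [degenerate_primer], a single IUPAC string, or a
#'   character vector of concrete variant sequences of equal length.
#' @param reference a reference sequence (A/C/G/T string).
#' @param orientation `"forward"` or `"reverse"`; defaults to the primer's
#'   own orientation when a [degenerate_primer] is given.
#' @return List with `min_mismatches` (non-negative integer) and
#'   `best_offset` (0-based).
#' @examples
#' min_mismatch("ACGT", "TTACGTTT")   # exact site at offset 2
#' @export
min_mismatch <- function(primer, reference, orientation = NULL) {
  if (inherits(primer, "degenerate_primer")) {
    if (is.null(orientation)) orientation <- primer$orientation
    primer <- primer$sequence
  }
  if (is.null(orientation)) orientation <- "forward"
  orientation <- match.arg(orientation, c("forward", "reverse"))
  refbits <- .encode_acgt(reference)
  if (length(primer) > 1L) {
    if (length(unique(nchar(primer))) != 1L)
      stop("variant sequences must have equal length", call. = FALSE)
    best <- NULL
    for (v in sort(primer)) {
      v2 <- if (orientation == "reverse") reverse_complement(v) else v
      res <- .scan_min(.encode_acgt(v2), refbits)
      if (is.null(best) || res["min_mismatches"] < best["min_mismatches"] ||
          (res["min_mismatches"] == best["min_mismatches"] &&
           res["best_offset"] < best["best_offset"]))
        best <- res
    }
    return(list(min_mismatches = unname(best["min_mismatches"]),
                best_offset = unname(best["best_offset"])))
  }
  pat <- if (orientation == "reverse") .iupac_revcomp(primer) else primer
  res <- .scan_min(.encode_iupac(pat), refbits)
  list(min_mismatches = unname(res["min_mismatches"]),
       best_offset = unname(res["best_offset"]))
}

#' Match a primer pool against a taxonomy-annotated reference set
#'
#' For every genus in the reference database and every primer in the pool,
#' computes the smallest mismatch count over that genus's reference
#' sequences. A primer is considered *matched* for a genus when at least
#' one reference of the genus contains an exact (0-mismatch) binding site;
#' otherwise the primer is recorded as a mismatch for that taxon.
#'
#' @param pool a [primer_pool].
#' @param refdb a [reference_db] (or data.frame with `id`, `genus`,
#'   `sequence`).
#' @return A data.frame of class `taxon_match_table` with one row per
#'   genus x orientation x primer: columns `genus`, `pool`, `orientation`,
#'   `primer_index`, `primer_name`, `min_mismatches`, `matched`,
#'   `n_reference_sequences`.
#' @seealso [matched_primers()], [summarize_matches()]
#' @export
match_pool_to_taxa <- function(pool, refdb) {
  stopifnot(inherits(pool, "primer_pool"))
  if (nrow(refdb) == 0L)
    stop("reference database is empty", call. = FALSE)
  if (!inherits(refdb, "reference_db")) refdb <- reference_db(refdb)
  wmax <- .longest_primer_length(pool)
  short <- nchar(refdb$sequence) < wmax
  if (any(short))
    stop(sprintf(
      "reference '%s' (%d nt) is shorter than the longest primer (%d nt)",
      refdb$id[which(short)[1]], nchar(refdb$sequence[which(short)[1]]), wmax),
      call. = FALSE)
  refbits <- lapply(refdb$sequence, .encode_acgt)
  genera <- unique(refdb$genus)
  by_genus <- split(seq_len(nrow(refdb)), refdb$genus)

  one_side <- function(primers, orientation) {
    rows <- list()
    for (p in primers) {
      pat <- if (orientation == "reverse") .iupac_revcomp(p$sequence)
             else p$sequence
      mask <- .encode_iupac(pat)
      per_ref <- vapply(refbits, function(rb) .scan_min(mask, rb)[1L],
                        numeric(1))
      mins <- vapply(by_genus, function(ix) min(per_ref[ix]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        genus = names(by_genus), pool = pool$label,
        orientation = orientation, primer_index = p$index,
        primer_name = p$name, min_mismatches = as.integer(mins),
        matched = mins == 0,
        n_reference_sequences = lengths(by_genus),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    do.call(rbind, rows)
  }
  out <- rbind(one_side(pool$forward, "forward"),
               one_side(pool$reverse, "reverse"))
  out <- out[order(match(out$genus, genera), out$orientation,
                   out$primer_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("taxon_match_table", "data.frame")
  out
}

#' Matched primer indices for one genus
#'
#' @param table a `taxon_match_table` from [match_pool_to_taxa()].
#' @param genus genus label.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Sorted integer vector of primer indices with an exact site in at
#'   least one reference of the genus (possibly empty).
#' @export
matched_primers <- function(table, genus, orientation) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  sub <- table[table$genus == genus & table$orientation == orientation &
                 table$matched, , drop = FALSE]
  sort(unique(sub$primer_index))
}

#' Summarize primer matches for genera of interest
#'
#' Produces one report row per requested genus (in the given order) and
#' pool present in the match table, flagging genera absent from the
#' reference database rather than dropping them.
#'
#' @param table a `taxon_match_table` (tables from several pools may be
#'   combined with `rbind`).
#' @param genera ordered character vector of genus labels.
#' @return data.frame with columns `genus`, `pool`, `in_database`,
#'   `forward_matched`, `reverse_matched` (comma-separated indices, or
#'   `"no match"`), `n_reference_sequences`.
#' @export
summarize_matches <- function(table, genera) {
  pools <- unique(table$pool)
  rows <- list()
  for (g in genera) {
    for (p in pools) {
      sub <- table[table$genus == g & table$pool == p, , drop = FALSE]
      in_db <- nrow(sub) > 0L
      fmt <- function(ori) {
        if (!in_db) return(NA_character_)
        idx <- sort(unique(sub$primer_index[sub$orientation == ori &
                                              sub$matched]))
        if (length(idx)) paste(idx, collapse = ", ") else "no match"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, pool = p, in_database = in_db,
        forward_matched = fmt("forward"), reverse_matched = fmt("reverse"),
        n_reference_sequences =
          if (in_db) sub$n_reference_sequences[1] else 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genus = character(0), pool = character(0),
                      in_database = logical(0),
                      forward_matched = character(0),
                      reverse_matched = character(0),
                      n_reference_sequences = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
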