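#' Construct a taxonomy-annotated 16S reference set
#'
#' A curated reference database is represented as a data frame with one
#' row per reference sequence: an `id`, taxonomic rank columns (at least
#' `genus`; typically `domain` through `genus`, with `unclassified_<parent>`
#' labels where classification stops early), and the `sequence` itself.
#' Sequences must be concrete (A/C/G/T only): ambiguity codes in curated
#' references are rejected at load.
#'
#' @param x data.frame with columns `id`, `genus`, `sequence` (plus any
#'   higher rank columns).
#' @return The validated data.frame with class `reference_db` prepended.
#' @export
reference_db <- function(x) {
  need <- c("id", "genus", "sequence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("reference table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0L)
    stop("reference database is empty", call. = FALSE)
  if (anyDuplicated(x$id))
    stop("duplicated reference ids", call. = FALSE)
  if (any(is.na(x$genus) | !nzchar(x$genus)))
    stop("every reference needs a non-empty genus label", call. = FALSE)
  x$sequence <- toupper(x$sequence)
  for (i in seq_len(nrow(x))) {
    ch <- .seq_chars(x$sequence[i])
    bad <- which(!ch %in% c("A", "C", "G", "T"))
    if (length(bad))
      stop(sprintf(
        "reference '%s' contains non-A/C/G/T character '%s' at position %d; curated references must be unambiguous",
        x$id[i], ch[bad[1]], bad[1]), call. = FALSE)
  }
  class(x) <- c("reference_db", "data.frame")
  x
}

#' Read a reference database from FASTA plus a lineage table
#'
#' @param fasta_path FASTA file of 16S sequences; record ids must match the
#'   lineage table's `id` column.
#' @param taxonomy_path tab-separated lineage table with header; must
#'   contain `id` and `genus` columns (higher ranks are carried along).
#' @return A [reference_db].
#' @export
read_reference_db <- function(fasta_path, taxonomy_path) {
  seqs <- readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("id", "genus") %in% names(tax)))
    stop("lineage table must have 'id' and 'genus' columns", call. = FALSE)
  missing_ids <- setdiff(ids, tax$id)
  if (length(missing_ids))
    stop("sequences without lineage: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  tax <- tax[match(ids, tax$id), , drop = FALSE]
  tax$sequence <- as.character(seqs)
  rownames(tax) <- NULL
  reference_db(tax)
}

#' Write a reference database to FASTA plus a lineage table
#'
#' Mirrors [read_reference_db()].
#'
#' @param db a [reference_db].
#' @param fasta_path,taxonomy_path output paths.
#' @return Invisibly, `db`.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "reference_db"))
  seqs <- DNAStringSet(setNames(db$sequence, db$id))
  writeXStringSet(seqs, fasta_path)
  tax <- db[, setdiff(names(db), "sequence"), drop = FALSE]
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(db)
}
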