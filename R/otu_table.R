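.RANK_COLS <- c("domain", "phylum", "class", "order", "family", "genus")

# Fill missing genus labels as unclassified_<lowest named parent rank>,
# the convention used for OTUs classified only to a higher rank.
.resolve_genus <- function(taxonomy) {
  ranks <- intersect(.RANK_COLS, names(taxonomy))
  parents <- setdiff(ranks, "genus")
  genus <- if ("genus" %in% ranks) taxonomy$genus
           else rep(NA_character_, nrow(taxonomy))
  for (i in seq_along(genus)) {
    if (!is.na(genus[i]) && nzchar(genus[i])) next
    parent <- NA_character_
    for (r in rev(parents)) {
      v <- taxonomy[[r]][i]
      if (!is.na(v) && nzchar(v)) { parent <- v; break }
    }
    genus[i] <- paste0("unclassified_",
                       if (is.na(parent)) "root" else parent)
  }
  genus
}

#' Construct an OTU count table
#'
#' The pipeline's central object: a samples x OTUs matrix of sequence
#' counts, per-OTU taxonomy (with `unclassified_<parent>` fallback genus
#' labels filled in), and per-sample metadata including the protocol label
#' used to prepare each sample.
#'
#' @param counts non-negative integer matrix, samples in rows, OTUs in
#'   columns, both dimensions named.
#' @param taxonomy data.frame with `otu_id` and rank columns (`genus`, and
#'   optionally `domain` ... `family`); one row per OTU.
#' @param sample_meta data.frame with `sample_id` and `protocol` (plus any
#'   covariates); one row per sample.
#' @return Object of class `otu_table` (a list with elements `counts`,
#'   `taxonomy`, `sample_meta`).
#' @export
otu_table <- function(counts, taxonomy, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names",
         call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0))
    stop(sprintf("negative or missing count for OTU '%s'",
                 colnames(counts)[which(apply(is.na(counts) | counts < 0, 2,
                                              any))[1]]), call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"

  if (!all(c("sample_id", "protocol") %in% names(sample_meta)))
    stop("sample metadata needs 'sample_id' and 'protocol' columns",
         call. = FALSE)
  missing_meta <- setdiff(rownames(counts), sample_meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ",
         paste(head(missing_meta, 5), collapse = ", "), call. = FALSE)
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id),
                             , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad_prot <- is.na(sample_meta$protocol) | !nzchar(sample_meta$protocol)
  if (any(bad_prot))
    stop(sprintf("sample '%s' has no protocol label",
                 sample_meta$sample_id[which(bad_prot)[1]]), call. = FALSE)

  if (!"otu_id" %in% names(taxonomy))
    stop("taxonomy needs an 'otu_id' column", call. = FALSE)
  missing_tax <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing_tax))
    stop("OTUs without taxonomy: ",
         paste(head(missing_tax, 5), collapse = ", "), call. = FALSE)
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  taxonomy$genus <- .resolve_genus(taxonomy)

  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_meta = sample_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs (%d genera); protocols: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$genus)),
              paste(unique(x$sample_meta$protocol), collapse = ", ")))
  invisible(x)
}

#' Read an OTU table from tab-separated files
#'
#' @param counts_path TSV, rows = OTUs (first column `otu_id`), remaining
#'   columns = samples.
#' @param taxonomy_path TSV with `otu_id` and rank columns.
#' @param metadata_path TSV with `sample_id`, `protocol`, covariates.
#' @return An [otu_table].
#' @export
read_otu_table <- function(counts_path, taxonomy_path, metadata_path) {
  cts <- read.delim(counts_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (names(cts)[1] != "otu_id")
    stop("first column of the counts file must be 'otu_id'", call. = FALSE)
  mat <- t(as.matrix(cts[, -1, drop = FALSE]))
  colnames(mat) <- cts$otu_id
  taxonomy <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  sample_meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  extra <- setdiff(rownames(mat), sample_meta$sample_id)
  if (length(extra))
    stop("count columns without metadata: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  otu_table(mat, taxonomy, sample_meta)
}

#' Write an OTU table to tab-separated files
#'
#' Mirrors [read_otu_table()] bit-exactly (a written table reads back
#' identical).
#'
#' @param x an [otu_table].
#' @param counts_path,taxonomy_path,metadata_path output paths.
#' @return Invisibly, `x`.
#' @export
write_otu_table <- function(x, counts_path, taxonomy_path, metadata_path) {
  stopifnot(inherits(x, "otu_table"))
  cts <- data.frame(otu_id = colnames(x$counts), t(x$counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$sample_meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Remove low-occurrence OTUs
#'
#' Drops every OTU whose total count across the entire dataset is below
#' `min_total` (default 30: OTUs with fewer than 30 occurrences are
#' removed; an OTU with exactly 30 survives). Samples are never removed
#' and remaining counts are unchanged. Applied before genus aggregation
#' and all downstream statistics.
#'
#' @param x an [otu_table].
#' @param min_total non-negative integer threshold.
#' @return Filtered [otu_table].
#' @export
filter_low_abundance <- function(x, min_total = 30L) {
  stopifnot(inherits(x, "otu_table"))
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  keep <- colSums(x$counts) >= min_total
  x$counts <- x$counts[, keep, drop = FALSE]
  x$taxonomy <- x$taxonomy[keep, , drop = FALSE]
  rownames(x$taxonomy) <- NULL
  x
}

#' Per-genus count of detected OTUs within a protocol group
#'
#' An OTU counts toward its genus if its total count over the group's
#' samples is greater than zero.
#'
#' @param x an [otu_table].
#' @param group protocol label.
#' @return Named integer vector over all genera in the table.
#' @export
count_otus_per_genus <- function(x, group) {
  stopifnot(inherits(x, "otu_table"))
  sel <- x$sample_meta$protocol == group
  if (!any(sel)) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  detected <- colSums(x$counts[sel, , drop = FALSE]) > 0
  genera <- unique(x$taxonomy$genus)
  out <- vapply(split(detected, x$taxonomy$genus), sum, numeric(1))
  setNames(as.integer(out[genera]), genera)
}
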