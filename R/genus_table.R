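#' Construct a genus-level abundance table
#'
#' @param abundances numeric matrix, samples x genera, named in both
#'   dimensions. In `"percent"` mode every non-zero row sums to 100
#'   (tolerance 1e-9); all-zero rows are permitted and flagged.
#' @param mode `"counts"` or `"percent"`.
#' @param sample_meta per-sample metadata (`sample_id`, `protocol`, ...).
#' @return Object of class `genus_table`.
#' @export
genus_table <- function(abundances, mode = c("counts", "percent"),
                        sample_meta) {
  mode <- match.arg(mode)
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("abundance matrix must be named in both dimensions", call. = FALSE)
  if (any(is.na(abundances)) || any(abundances < 0))
    stop("abundances must be non-negative", call. = FALSE)
  rs <- rowSums(abundances)
  if (mode == "percent" &&
      any(rs > 0 & abs(rs - 100) > 1e-9))
    stop("percent-mode rows must sum to 100", call. = FALSE)
  sample_meta <- sample_meta[match(rownames(abundances),
                                   sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(abundances = abundances, mode = mode,
                 sample_meta = sample_meta,
                 zero_samples = rownames(abundances)[rs == 0]),
            class = "genus_table")
}

#' @export
print.genus_table <- function(x, ...) {
  cat(sprintf("<genus_table> %d samples x %d genera (%s mode)\n",
              nrow(x$abundances), ncol(x$abundances), x$mode))
  if (length(x$zero_samples))
    cat("  all-zero samples:", paste(x$zero_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums each sample's OTU counts within genus (or another rank); total
#' reads per sample are conserved.
#'
#' @param x an [otu_table].
#' @param rank rank column to aggregate on; default `"genus"` (the only
#'   rank with unclassified-fallback labels filled in).
#' @return A [genus_table] in counts mode.
#' @export
aggregate_to_genus <- function(x, rank = "genus") {
  stopifnot(inherits(x, "otu_table"))
  if (!rank %in% names(x$taxonomy))
    stop(sprintf("taxonomy has no '%s' column", rank), call. = FALSE)
  labels <- x$taxonomy[[rank]]
  agg <- t(rowsum(t(x$counts), group = labels))
  genus_table(agg, mode = "counts", sample_meta = x$sample_meta)
}

#' Convert genus counts to per-sample percentages
#'
#' Each sample row is rescaled to sum to 100. Samples with zero total
#' reads remain all-zero and are flagged in the result's `zero_samples`.
#'
#' @param x a [genus_table] in counts mode.
#' @return A [genus_table] in percent mode.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "genus_table"))
  if (x$mode != "counts")
    stop("relative_abundance expects a counts-mode table", call. = FALSE)
  rs <- rowSums(x$abundances)
  pct <- x$abundances
  nz <- rs > 0
  pct[nz, ] <- sweep(x$abundances[nz, , drop = FALSE], 1, rs[nz], `/`) * 100
  genus_table(pct, mode = "percent", sample_meta = x$sample_meta)
}

#' Per-genus prevalence within a protocol group
#'
#' Percentage of the group's samples in which a genus is detected
#' (non-zero abundance).
#'
#' @param x a [genus_table] (counts or percent mode).
#' @param group protocol label.
#' @return Named numeric vector in \[0, 100\].
#' @export
prevalence <- function(x, group) {
  stopifnot(inherits(x, "genus_table"))
  sel <- x$sample_meta$protocol == group
  if (!any(sel)) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  colMeans(x$abundances[sel, , drop = FALSE] > 0) * 100
}
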