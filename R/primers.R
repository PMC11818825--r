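#' Construct a degenerate primer
#'
#' A named oligonucleotide over the 15-letter IUPAC alphabet, the unit of
#' the in-silico binding analysis. Reverse-orientation primers are stored
#' as the oligo sequence (5'->3' on the antisense strand) and are
#' reverse-complemented internally before scanning the sense strand.
#'
#' @param name short label, e.g. `"27F"`.
#' @param index 1-based position of the primer within its pool; match
#'   tables report these indices.
#' @param orientation `"forward"` or `"reverse"`.
#' @param sequence IUPAC string, uppercase.
#' @return An object of class `degenerate_primer`.
#' @examples
#' degenerate_primer("27F", 1, "forward", "AGAGTTTGATCCTGGCTCAG")
#' @export
degenerate_primer <- function(name, index, orientation, sequence) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    stop("primer index must be an integer >= 1", call. = FALSE)
  .validate_iupac(sequence, what = sprintf("primer '%s'", name))
  structure(list(name = as.character(name), index = index,
                 orientation = orientation, sequence = sequence),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> #%d %s (%s): %s\n",
              x$index, x$name, x$orientation, x$sequence))
  invisible(x)
}

#' Construct a primer pool
#'
#' The set of forward and reverse primers used by one protocol (a single
#' 27F/357R pair for a conventional protocol, or a degenerate pool).
#'
#' @param label protocol name, e.g. `"HMP"` or `"Rapid"`.
#' @param forward,reverse lists of [degenerate_primer] objects with the
#'   matching orientation and distinct indices.
#' @return An object of class `primer_pool`.
#' @export
primer_pool <- function(label, forward, reverse) {
  if (inherits(forward, "degenerate_primer")) forward <- list(forward)
  if (inherits(reverse, "degenerate_primer")) reverse <- list(reverse)
  if (length(forward) < 1L || length(reverse) < 1L)
    stop("a primer pool needs at least one forward and one reverse primer",
         call. = FALSE)
  for (side in list(forward = forward, reverse = reverse)) {
    stopifnot(all(vapply(side, inherits, logical(1), "degenerate_primer")))
  }
  ori <- function(p) vapply(p, `[[`, character(1), "orientation")
  if (any(ori(forward) != "forward") || any(ori(reverse) != "reverse"))
    stop("primer orientations do not match their pool slot", call. = FALSE)
  idx <- function(p) vapply(p, `[[`, integer(1), "index")
  if (anyDuplicated(idx(forward)) || anyDuplicated(idx(reverse)))
    stop("primer indices must be distinct within a pool and orientation",
         call. = FALSE)
  structure(list(label = as.character(label),
                 forward = forward, reverse = reverse),
            class = "primer_pool")
}

#' @export
print.primer_pool <- function(x, ...) {
  cat(sprintf("<primer_pool> %s: %d forward, %d reverse primer(s)\n",
              x$label, length(x$forward), length(x$reverse)))
  invisible(x)
}

.longest_primer_length <- function(pool) {
  max(vapply(c(pool$forward, pool$reverse),
             function(p) nchar(p$sequence), integer(1)))
}

#' Read primer pools from a tab-separated table
#'
#' Expects columns `pool`, `orientation`, `index`, `name`, `sequence`
#' (header row required). Each distinct `pool` value becomes one
#' [primer_pool]. An example file ships with the package:
#' `system.file("extdata", "example_primers_synthetic.tsv", package =
#' "amplicomp")` — a synthetic demonstration pool built around the
#' canonical 27F/357R V1-V3 pair.
#'
#' @param path file path.
#' @return Named list of [primer_pool] objects.
#' @export
read_primer_pools <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pool", "orientation", "index", "name", "sequence")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("primer table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pools <- lapply(split(tab, tab$pool), function(sub) {
    prim <- lapply(seq_len(nrow(sub)), function(i)
      degenerate_primer(sub$name[i], sub$index[i], sub$orientation[i],
                        sub$sequence[i]))
    ori <- vapply(prim, `[[`, character(1), "orientation")
    primer_pool(sub$pool[1], prim[ori == "forward"], prim[ori == "reverse"])
  })
  pools
}
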