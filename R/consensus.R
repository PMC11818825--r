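#' Ranking directions for the nine discriminating metrics
#'
#' `"asc"`: smaller is more discriminating (p-values); `"desc"`: larger is
#' more discriminating (differences, contributions, abundances,
#' importances); `"desc_abs"`: larger magnitude is more discriminating
#' (log2 fold change enters ranking as |log2fc|, direction-agnostic).
#' Rank 1 always means "most discriminating".
#'
#' @format Named character vector over the nine metric columns.
#' @export
metric_directions <- c(
  prevalence_diff = "desc", abundance_diff = "desc",
  bc_contribution = "desc", wilcoxon_p = "asc",
  overall_mean_abundance = "desc", log2fc = "desc_abs",
  foldchange_p = "asc", rf_mda = "desc", rf_mdg = "desc")

#' Rank genera within each metric
#'
#' Each metric column is converted to ranks of discriminative strength
#' (rank 1 = strongest) with average ranks for ties, so every column's
#' ranks sum to G (G + 1) / 2. Missing metric values receive the worst
#' rank in their column and are flagged in the `na_flagged` attribute.
#'
#' @param metrics a `genus_metric_table` (or data.frame with a `genus`
#'   column and the metric columns).
#' @param directions named direction vector; default [metric_directions].
#' @return Numeric matrix genera x metrics of class `rank_matrix`
#'   (rownames = genera) with attributes `directions` and `na_flagged`.
#' @export
rank_metrics <- function(metrics, directions = metric_directions) {
  missing_cols <- setdiff(names(directions), names(metrics))
  if (length(missing_cols))
    stop("metric table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  na_flagged <- list()
  cols <- lapply(names(directions), function(mname) {
    v <- metrics[[mname]]
    if (all(is.na(v)))
      stop(sprintf("metric '%s' is entirely missing", mname), call. = FALSE)
    dir <- directions[[mname]]
    if (dir == "desc_abs") v <- abs(v)
    strength <- if (dir == "asc") -v else v  # larger strength = rank 1
    strength[is.na(strength)] <- -Inf        # missing -> worst rank
    if (any(is.na(v))) na_flagged[[mname]] <<- metrics$genus[is.na(v)]
    rank(-strength, ties.method = "average")
  })
  rm <- do.call(cbind, cols)
  dimnames(rm) <- list(metrics$genus, names(directions))
  structure(rm, class = c("rank_matrix", class(rm)),
            directions = directions, na_flagged = na_flagged)
}

#' Combine per-metric ranks into a consensus score
#'
#' The consensus score of a genus is the geometric mean of its ranks over
#' the metric columns — with nine metrics, the ninth root of the product
#' of its nine ranking scores — computed in log space. Genera are ordered
#' by ascending score (rank 1 = most consistently discriminating); exact
#' score ties are broken alphabetically and flagged.
#'
#' @param rm a `rank_matrix` from [rank_metrics()] (strictly positive
#'   entries).
#' @return data.frame of class `consensus_result` ordered by score, with
#'   `final_rank` (average ranks for tied scores), `genus`, `score`, and
#'   a logical `tied` column.
#' @export
combine_ranks <- function(rm) {
  rm <- unclass(rm)
  if (any(is.na(rm)) || any(rm <= 0))
    stop("ranks must be positive and non-missing", call. = FALSE)
  score <- exp(rowMeans(log(rm)))
  genus <- rownames(rm)
  ord <- order(score, genus)
  tied <- duplicated(score) | duplicated(score, fromLast = TRUE)
  out <- data.frame(final_rank = rank(score, ties.method = "average")[ord],
                    genus = genus[ord], score = score[ord],
                    tied = tied[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("consensus_result", "data.frame")
  out
}

#' Combined top-k report of protocol-discriminating genera
#'
#' Assembles the headline table: the k most discriminating genera by
#' consensus rank, annotated (where the inputs are supplied) with matched
#' primer indices per pool and orientation (genera absent from the
#' reference database are flagged, not dropped), per-protocol detected OTU
#' counts, and per-protocol prevalence.
#'
#' @param cr a `consensus_result`.
#' @param k number of genera to report (default 20); if `k` exceeds the
#'   number of genera, all are reported with a warning.
#' @param match_summary optional output of [summarize_matches()] (may
#'   combine several pools).
#' @param otu_counts optional named list of named vectors,
#'   `group -> genus -> detected OTU count` (see
#'   [count_otus_per_genus()]).
#' @param prevalences optional named list of named vectors,
#'   `group -> genus -> prevalence percent` (see [prevalence()]).
#' @return data.frame, one row per top-k genus in consensus order.
#' @export
top_k_report <- function(cr, k = 20L, match_summary = NULL,
                         otu_counts = NULL, prevalences = NULL) {
  stopifnot(inherits(cr, "consensus_result"))
  if (k > nrow(cr)) {
    warning(sprintf("k = %d exceeds the %d ranked genera; reporting all",
                    k, nrow(cr)))
    k <- nrow(cr)
  }
  out <- head(as.data.frame(cr), k)
  if (!is.null(match_summary)) {
    for (p in unique(match_summary$pool)) {
      sub <- match_summary[match_summary$pool == p, , drop = FALSE]
      m <- match(out$genus, sub$genus)
      in_db <- !is.na(m) & sub$in_database[m]
      flag <- function(v) ifelse(in_db, v, "not in database")
      out[[paste0(p, "_forward")]] <- flag(sub$forward_matched[m])
      out[[paste0(p, "_reverse")]] <- flag(sub$reverse_matched[m])
      out[[paste0(p, "_in_database")]] <- in_db
    }
  }
  add_group_cols <- function(lst, prefix, out) {
    for (grp in names(lst)) {
      v <- lst[[grp]][out$genus]
      out[[paste0(prefix, "_", grp)]] <- unname(v)
    }
    out
  }
  if (!is.null(otu_counts)) out <- add_group_cols(otu_counts, "otus", out)
  if (!is.null(prevalences))
    out <- add_group_cols(prevalences, "prevalence", out)
  rownames(out) <- NULL
  out
}
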