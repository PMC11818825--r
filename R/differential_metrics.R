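#' Log2 fold change between two mean abundances
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`. The
#' pseudocount keeps the ratio finite when a genus is absent from one
#' group.
#'
#' @param mean_a,mean_b non-negative mean percent abundances.
#' @param pseudocount positive percent offset.
#' @return log2 ratio (positive = enriched in the `a` group).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount) {
  if (any(pseudocount <= 0))
    stop("pseudocount must be positive", call. = FALSE)
  if (any(mean_a < 0) || any(mean_b < 0))
    stop("mean abundances must be non-negative", call. = FALSE)
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

# Welch two-sided t on log2(percent + pseudocount); degenerate
# (zero-variance) genera: p = 1 when the two group means coincide, NA
# otherwise (the test is undefined; ranking assigns NA the worst rank).
.welch_log_t <- function(a, b) {
  out <- tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
  if (is.na(out) && isTRUE(all.equal(mean(a), mean(b)))) out <- 1
  out
}

#' Nine per-genus metrics discriminating two protocol groups
#'
#' For every genus computes: absolute prevalence difference and absolute
#' mean-abundance difference (percentage points); the genus's additive
#' contribution to the mean between-group Bray-Curtis dissimilarity
#' (`mean over pairs of |x_g - y_g| / sum_k (x_k + y_k)` — these
#' contributions sum over genera to the mean between-group Bray-Curtis);
#' the Wilcoxon rank-sum p-value; overall mean percent abundance; log2
#' fold change of group means (with a scale-adaptive pseudocount of half
#' the smallest non-zero percentage in the table); the two-sided Welch
#' t-test p-value on log2(percent + pseudocount); and random forest mean
#' decrease in accuracy and in Gini impurity for classifying the protocol
#' label from genus abundances (fixed seed; importances are stochastic
#' across seeds but bit-reproducible under the same seed).
#'
#' @param x a [genus_table] in percent mode with a `protocol` column in
#'   its metadata.
#' @param groups length-2 character vector; `groups[1]` is the log2fc
#'   numerator. Defaults to the two protocol labels in metadata order.
#' @param rf_trees number of trees in the random forest (default 500).
#' @param seed integer seed for the random forest.
#' @param pseudocount optional override of the adaptive pseudocount.
#' @return data.frame of class `genus_metric_table`, one row per genus,
#'   with the nine metric columns; attributes `groups`, `pseudocount`,
#'   `group_sizes`.
#' @export
compute_genus_metrics <- function(x, groups = NULL, rf_trees = 500L,
                                  seed = 1L, pseudocount = NULL) {
  stopifnot(inherits(x, "genus_table"))
  if (x$mode != "percent")
    stop("metrics are computed on percent-mode tables", call. = FALSE)
  prot <- x$sample_meta$protocol
  if (is.null(groups)) groups <- unique(prot)
  if (length(groups) != 2L || !all(groups %in% prot))
    stop("exactly two groups present in the data are required",
         call. = FALSE)
  ia <- prot == groups[1]
  ib <- prot == groups[2]
  if (sum(ia) < 3L || sum(ib) < 3L)
    stop("each group needs at least three samples", call. = FALSE)
  xa <- x$abundances[ia, , drop = FALSE]
  xb <- x$abundances[ib, , drop = FALSE]
  genera <- colnames(x$abundances)

  if (is.null(pseudocount)) {
    nz <- x$abundances[x$abundances > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 0.5
  }

  prev_a <- colMeans(xa > 0) * 100
  prev_b <- colMeans(xb > 0) * 100
  mean_a <- colMeans(xa)
  mean_b <- colMeans(xb)

  # shared-denominator Bray-Curtis decomposition over between-group pairs
  denom <- outer(rowSums(xa), rowSums(xb), `+`)  # nA x nB
  bc_contribution <- vapply(seq_along(genera), function(g) {
    mean(abs(outer(xa[, g], xb[, g], `-`)) / denom)
  }, numeric(1))

  wilcoxon_p <- vapply(seq_along(genera), function(g)
    wilcoxon_rank_sum(xa[, g], xb[, g]), numeric(1))

  la <- log2(xa + pseudocount)
  lb <- log2(xb + pseudocount)
  foldchange_p <- vapply(seq_along(genera), function(g)
    .welch_log_t(la[, g], lb[, g]), numeric(1))

  set.seed(seed)
  rf <- randomForest(x = x$abundances[ia | ib, , drop = FALSE],
                     y = factor(prot[ia | ib], levels = groups),
                     ntree = rf_trees, importance = TRUE)
  imp <- importance(rf, scale = FALSE)

  out <- data.frame(
    genus = genera,
    prevalence_diff = abs(prev_a - prev_b),
    abundance_diff = abs(mean_a - mean_b),
    bc_contribution = bc_contribution,
    wilcoxon_p = wilcoxon_p,
    overall_mean_abundance = colMeans(x$abundances[ia | ib, , drop = FALSE]),
    log2fc = log2_fold_change(mean_a, mean_b, pseudocount),
    foldchange_p = foldchange_p,
    rf_mda = unname(imp[genera, "MeanDecreaseAccuracy"]),
    rf_mdg = unname(imp[genera, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("genus_metric_table", "data.frame"),
            groups = groups, pseudocount = pseudocount,
            group_sizes = c(sum(ia), sum(ib)))
}

#' Per-genus enrichment calls from fold change and adjusted p-values
#'
#' A genus is called enriched in one protocol when |log2fc| exceeds the
#' fold-change cutoff (values inside (-cut, cut) are never called) and its
#' Benjamini-Hochberg adjusted fold-change p-value is below `alpha`; the
#' sign of log2fc decides the direction.
#'
#' @param metrics a `genus_metric_table`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param fc_cut log2 fold-change cutoff (default 1).
#' @param p_adjust_method method for [stats::p.adjust] (default `"BH"`).
#' @return data.frame with `genus`, `log2fc`, `foldchange_p`,
#'   `adjusted_p`, `passes_fc_threshold`, `enriched_in` (a group label or
#'   `"none"`).
#' @export
significance_calls <- function(metrics, alpha = 0.05, fc_cut = 1,
                               p_adjust_method = "BH") {
  stopifnot(inherits(metrics, "genus_metric_table"))
  groups <- attr(metrics, "groups")
  adj <- p.adjust(metrics$foldchange_p, method = p_adjust_method)
  passes <- abs(metrics$log2fc) > fc_cut
  sig <- passes & !is.na(adj) & adj < alpha
  data.frame(
    genus = metrics$genus,
    log2fc = metrics$log2fc,
    foldchange_p = metrics$foldchange_p,
    adjusted_p = adj,
    passes_fc_threshold = passes,
    enriched_in = ifelse(sig, ifelse(metrics$log2fc > 0,
                                     groups[1], groups[2]), "none"),
    stringsAsFactors = FALSE)
}
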