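.chao1 <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s + f1^2 / (2 * f2)
  else s + f1 * (f1 - 1) / 2  # bias-corrected form, F2 = 0
}

#' Per-sample alpha diversity
#'
#' Computes observed richness S (count of non-zero genera), Shannon
#' entropy H in nats, Pielou evenness J = H / ln S (reported as `NA` when
#' S < 2, where evenness is undefined), and the Chao1 richness estimate
#' S + F1^2 / (2 F2), using the bias-corrected form
#' S + F1 (F1 - 1) / (2 (F2 + 1)) when no doubletons are present (F1, F2 =
#' counts of genera observed exactly once / twice). Chao1 requires integer
#' counts, so the input must be a counts-mode table; no rarefaction is
#' applied.
#'
#' @param x a [genus_table] in counts mode.
#' @return data.frame with columns `sample_id`, `group`, `richness`,
#'   `shannon`, `pielou`, `chao1`.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "genus_table"))
  if (x$mode != "counts")
    stop("alpha diversity requires integer counts (Chao1); got percent mode",
         call. = FALSE)
  mat <- x$abundances
  s <- rowSums(mat > 0)
  h <- diversity(mat, index = "shannon")  # natural log
  j <- ifelse(s >= 2, h / log(s), NA_real_)
  chao <- apply(mat, 1, .chao1)
  data.frame(sample_id = rownames(mat),
             group = x$sample_meta$protocol,
             richness = as.integer(s), shannon = unname(h),
             pielou = unname(j), chao1 = unname(chao),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i) on percent profiles;
#' 0 for identical samples, 1 for disjoint support. Pairs of all-zero
#' samples have undefined dissimilarity and are reported as `NA`.
#'
#' @param x a [genus_table] in percent mode.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "genus_table"))
  if (x$mode != "percent")
    stop("bray_curtis expects a percent-mode table", call. = FALSE)
  d <- suppressWarnings(vegdist(x$abundances, method = "bray"))
  d[is.nan(d)] <- NA_real_
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared-distance matrix, eigendecomposes, and scales
#' eigenvectors by the square root of their (positive) eigenvalues.
#' Negative eigenvalues are reported but receive no axes; percent variance
#' explained is computed over positive eigenvalues only.
#'
#' @param dm a `dist` object or symmetric matrix of dissimilarities.
#' @return List of class `pcoa_result` with `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, non-increasing), and `pct_var`
#'   (percent of positive-eigenvalue variance per axis).
#' @export
pcoa <- function(dm) {
  m <- as.matrix(dm)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(is.na(m)))
    stop("distance matrix contains missing values", call. = FALSE)
  n <- nrow(m)
  fit <- suppressWarnings(cmdscale(as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 pct_var = 100 * eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes; first axes: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", head(x$pct_var, 3)), collapse = ", ")))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. R = (mean between-group rank -
#' mean within-group rank) / (M / 2) with M = n (n - 1) / 2 ranked
#' distance pairs (average ranks for ties); the permutation p-value is
#' (number of permuted R >= observed R + 1) / (n_permutations + 1), so 999
#' permutations give an attainable floor of 1e-3.
#'
#' @param dm `dist` object or symmetric dissimilarity matrix.
#' @param groups grouping vector (>= 2 groups, each with >= 2 samples).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer; set for a reproducible permutation p.
#' @return List with `statistic` (R), `p_value`, `n_permutations`.
#' @export
anosim_test <- function(dm, groups, n_permutations = 999L, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("ANOSIM needs at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least two samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- anosim(as.dist(as.matrix(dm)), groups,
                permutations = n_permutations)
  list(statistic = unname(fit$statistic),
       p_value = fit$signif,
       n_permutations = n_permutations)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20L) && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}
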