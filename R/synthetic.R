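#' Configuration of the synthetic two-protocol community generator
#'
#' Defines the ground-truth model behind [generate_otu_tables()]: genus
#' base abundances are log-normal; the first protocol's genus means are
#' multiplied by `2^b_g` for biased genera (so `b_g` is the injected log2
#' effect); per-sample genus proportions are a Dirichlet perturbation of
#' the protocol means (smaller `concentration` = more overdispersion);
#' per-genus, per-protocol dropout zeroes a genus in a sample with the
#' stated probability (driving prevalence differences); counts are
#' multinomial at fixed `depth` and split across a genus's OTUs by fixed
#' Zipf-like within-genus weights.
#'
#' @param n_genera number of genera (default 60).
#' @param otus_per_genus integer range (length 2) of OTUs per genus.
#' @param n_samples samples per protocol (scalar or length 2).
#' @param protocols the two protocol labels; the first is the biased
#'   ("numerator") protocol.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of genus
#'   base abundances.
#' @param biased_genera named numeric vector, genus name -> `b_g` in log2
#'   units (|b_g| capped at `bias_cap`); empty for a null community.
#' @param dropout baseline per-genus, per-protocol zero-inflation
#'   probability (scalar), or an `n_genera` x 2 matrix with the protocols
#'   as columns.
#' @param dropout_contrast extra dropout added, for each biased genus, in
#'   the protocol where it is depleted (prevalence follows abundance bias).
#' @param concentration Dirichlet concentration (sum of the alpha vector).
#' @param depth reads per sample.
#' @param seed integer seed; the whole table is reproducible from the
#'   config alone.
#' @param bias_cap documented cap on |b_g|.
#' @return List of class `bias_model_config`.
#' @export
bias_model_config <- function(n_genera = 60L, otus_per_genus = c(1L, 5L),
                              n_samples = 30L,
                              protocols = c("Rapid", "HMP"),
                              baseline_meanlog = 0, baseline_sdlog = 1,
                              biased_genera = numeric(0),
                              dropout = 0.02, dropout_contrast = 0.2,
                              concentration = 50, depth = 20000L,
                              seed = 1L, bias_cap = 8) {
  n_genera <- as.integer(n_genera)
  if (n_genera < 2L) stop("need at least two genera", call. = FALSE)
  if (length(otus_per_genus) != 2L || any(otus_per_genus < 1L) ||
      otus_per_genus[1] > otus_per_genus[2])
    stop("otus_per_genus must be a valid integer range", call. = FALSE)
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, 2L)
  if (any(n_samples < 1L)) stop("n_samples must be positive", call. = FALSE)
  if (length(protocols) != 2L || anyDuplicated(protocols))
    stop("exactly two distinct protocol labels required", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  genera <- sprintf("Genus_%02d", seq_len(n_genera))
  if (length(biased_genera)) {
    if (is.null(names(biased_genera)) ||
        !all(names(biased_genera) %in% genera))
      stop("biased_genera must be named by genus (Genus_01 ...)",
           call. = FALSE)
    if (any(abs(biased_genera) > bias_cap))
      stop(sprintf("|b_g| exceeds the cap of %g", bias_cap), call. = FALSE)
  }
  if (is.matrix(dropout)) {
    if (!identical(dim(dropout), c(n_genera, 2L)))
      stop("dropout matrix must be n_genera x 2", call. = FALSE)
    dropout_mat <- dropout
  } else {
    if (length(dropout) != 1L)
      stop("dropout must be a scalar or an n_genera x 2 matrix",
           call. = FALSE)
    dropout_mat <- matrix(dropout, n_genera, 2L)
  }
  colnames(dropout_mat) <- protocols
  rownames(dropout_mat) <- genera
  if (any(dropout_mat < 0) || any(dropout_mat > 1))
    stop("dropout probabilities must lie in [0, 1]", call. = FALSE)
  # biased genera get extra dropout on the side where they are depleted
  for (g in names(biased_genera)) {
    depleted <- if (biased_genera[[g]] > 0) protocols[2] else protocols[1]
    dropout_mat[g, depleted] <-
      min(1, dropout_mat[g, depleted] + dropout_contrast)
  }
  structure(list(n_genera = n_genera, genera = genera,
                 otus_per_genus = as.integer(otus_per_genus),
                 n_samples = as.integer(n_samples), protocols = protocols,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 biased_genera = biased_genera, dropout = dropout_mat,
                 concentration = concentration, depth = as.integer(depth),
                 seed = as.integer(seed), bias_cap = bias_cap),
            class = "bias_model_config")
}

#' Generate a two-protocol OTU table with known ground truth
#'
#' Draws a synthetic community under the model described in
#' [bias_model_config()] and returns both the [otu_table] and the ground
#' truth (injected effects and model-expected log2 fold changes after
#' dropout and compositional renormalisation). Identical configs (same
#' seed) produce identical tables.
#'
#' @param config a [bias_model_config].
#' @return List with elements `table` (an [otu_table]) and `truth` (a
#'   data.frame: `genus`, `b_log2`, per-protocol dropout, `base_abundance`,
#'   `expected_log2fc`).
#' @export
generate_otu_tables <- function(config) {
  stopifnot(inherits(config, "bias_model_config"))
  set.seed(config$seed)
  n <- config$n_genera
  genera <- config$genera
  base <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  b <- setNames(numeric(n), genera)
  b[names(config$biased_genera)] <- config$biased_genera

  means <- cbind(base * 2^b, base)
  colnames(means) <- config$protocols
  props <- sweep(means, 2, colSums(means), `/`)

  k_otus <- sample(seq(config$otus_per_genus[1], config$otus_per_genus[2]),
                   n, replace = TRUE)
  otu_genus <- rep(genera, k_otus)
  otu_ids <- sprintf("Otu%04d", seq_along(otu_genus))
  otu_w <- unlist(lapply(k_otus, function(k) {
    w <- 1 / seq_len(k)
    w / sum(w)
  }), use.names = FALSE)

  sample_ids <- character(0)
  protocol_of <- character(0)
  counts <- matrix(0L, 0, length(otu_ids),
                   dimnames = list(NULL, otu_ids))
  for (pi in 1:2) {
    prot <- config$protocols[pi]
    drop_p <- config$dropout[, prot]
    for (s in seq_len(config$n_samples[pi])) {
      alpha <- config$concentration * props[, prot]
      gam <- rgamma(n, shape = alpha, rate = 1)
      keep <- runif(n) >= drop_p
      gam[!keep] <- 0
      if (sum(gam) == 0) gam <- props[, prot]  # degenerate draw guard
      genus_counts <- as.integer(rmultinom(1, config$depth, gam / sum(gam)))
      otu_counts <- integer(length(otu_ids))
      pos <- 0L
      for (g in seq_len(n)) {
        k <- k_otus[g]
        if (genus_counts[g] > 0) {
          w <- otu_w[(pos + 1L):(pos + k)]
          otu_counts[(pos + 1L):(pos + k)] <-
            as.integer(rmultinom(1, genus_counts[g], w))
        }
        pos <- pos + k
      }
      counts <- rbind(counts, otu_counts)
      sample_ids <- c(sample_ids, sprintf("%s_S%03d", prot, s))
      protocol_of <- c(protocol_of, prot)
    }
  }
  rownames(counts) <- sample_ids

  taxonomy <- data.frame(
    otu_id = otu_ids, domain = "Bacteria",
    phylum = sprintf("Phylum_%02d", (match(otu_genus, genera) - 1L) %% 6L + 1L),
    family = sprintf("Family_%02d", (match(otu_genus, genera) - 1L) %% 15L + 1L),
    genus = otu_genus, stringsAsFactors = FALSE)
  sample_meta <- data.frame(sample_id = sample_ids, protocol = protocol_of,
                            stringsAsFactors = FALSE)

  surv <- 1 - config$dropout
  eff <- props * surv  # expected detected mass per genus and protocol
  eff <- sweep(eff, 2, colSums(eff), `/`)
  truth <- data.frame(
    genus = genera, b_log2 = unname(b),
    dropout_1 = unname(config$dropout[, 1]),
    dropout_2 = unname(config$dropout[, 2]),
    base_abundance = base,
    expected_log2fc = log2(eff[, 1] / eff[, 2]),
    stringsAsFactors = FALSE)
  names(truth)[3:4] <- paste0("dropout_", config$protocols)

  list(table = otu_table(counts, taxonomy, sample_meta), truth = truth)
}

#' Random primer-site design for a synthetic reference database
#'
#' Assigns each genus one forward and one reverse primer from the pool and
#' a number of substitutions to implant at its binding site (0 = exact
#' site).
#'
#' @param pool a [primer_pool].
#' @param genera character vector of genus labels (one reference each).
#' @param max_mismatches largest substitution count to draw (default 3).
#' @param p_exact probability a site is implanted exactly (default 0.5).
#' @param seed optional integer seed.
#' @return data.frame usable as the `design` of [generate_reference_db()].
#' @export
random_site_design <- function(pool, genera, max_mismatches = 3L,
                               p_exact = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genera)
  draw_mm <- function() ifelse(runif(n) < p_exact, 0L,
                               sample(seq_len(max_mismatches), n,
                                      replace = TRUE))
  data.frame(
    genus = genera,
    forward_index = vapply(pool$forward, `[[`, integer(1), "index")[
      sample(length(pool$forward), n, replace = TRUE)],
    forward_mismatches = draw_mm(),
    reverse_index = vapply(pool$reverse, `[[`, integer(1), "index")[
      sample(length(pool$reverse), n, replace = TRUE)],
    reverse_mismatches = draw_mm(),
    stringsAsFactors = FALSE)
}

.random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# implant `k` substitutions into a concrete site, each at a distinct
# position and to a base outside the primer's IUPAC set there (so the
# designed primer's mismatch count at the site is exactly k).
.substitute_site <- function(site, primer_seq, k) {
  chars <- .seq_chars(site)
  masks <- .encode_iupac(primer_seq)
  mutable <- which(masks != 15L)  # cannot force a mismatch at an N
  if (k > nchar(primer_seq))
    stop("requested mismatch count exceeds the primer length",
         call. = FALSE)
  if (k > length(mutable))
    stop("requested mismatch count exceeds the primer's non-N positions",
         call. = FALSE)
  if (k == 0) return(site)
  pos <- mutable[sample.int(length(mutable), k)]
  for (p in pos) {
    allowed <- .IUPAC_SETS[[.seq_chars(primer_seq)[p]]]
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1)
  }
  paste(chars, collapse = "")
}

.pattern_matches_site <- function(primer_seq, site) {
  all(bitwAnd(.encode_iupac(primer_seq), .encode_acgt(site)) != 0L)
}

#' Generate a synthetic reference database with controlled primer sites
#'
#' Builds one reference sequence per design row: random flank, a forward
#' binding site (an expansion of the designed forward primer, optionally
#' with a stated number of substitutions to bases outside the primer's
#' IUPAC sets), a random spacer, the sense-strand reverse site (the
#' reverse-complement of an expansion of the designed reverse primer,
#' likewise optionally substituted), and a random flank.
#' [match_pool_to_taxa()] on the output reproduces the implanted design.
#'
#' @param pool a [primer_pool]; within each orientation all primers must
#'   have equal length (so the implied truth is well defined).
#' @param design data.frame with columns `genus`, `forward_index`,
#'   `forward_mismatches`, `reverse_index`, `reverse_mismatches`; one row
#'   per reference (a genus may have several rows).
#' @param flank_length,spacer_length lengths of the random segments.
#' @param seed optional integer seed.
#' @return List with `refdb` (a [reference_db]) and `truth`: a named list
#'   `genus -> list(forward = indices, reverse = indices)` of the primer
#'   indices whose IUPAC pattern exactly matches an implanted site of the
#'   genus (degenerate primers overlap, so a site implanted for one primer
#'   can legitimately match others too).
#' @export
generate_reference_db <- function(pool, design, flank_length = 15L,
                                  spacer_length = 120L, seed = NULL) {
  stopifnot(inherits(pool, "primer_pool"))
  need <- c("genus", "forward_index", "forward_mismatches",
            "reverse_index", "reverse_mismatches")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols))
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (side in c("forward", "reverse")) {
    lens <- unique(vapply(pool[[side]], function(p) nchar(p$sequence),
                          integer(1)))
    if (length(lens) != 1L)
      stop(sprintf("all %s primers must have equal length", side),
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  f_idx <- vapply(pool$forward, `[[`, integer(1), "index")
  r_idx <- vapply(pool$reverse, `[[`, integer(1), "index")

  rows <- vector("list", nrow(design))
  truth <- list()
  for (i in seq_len(nrow(design))) {
    g <- design$genus[i]
    fp <- pool$forward[[match(design$forward_index[i], f_idx)]]
    rp <- pool$reverse[[match(design$reverse_index[i], r_idx)]]
    f_variant <- sample(expand_degenerate(fp), 1)
    f_site <- .substitute_site(f_variant, fp$sequence,
                               design$forward_mismatches[i])
    r_variant <- sample(expand_degenerate(rp), 1)
    r_oligo <- .substitute_site(r_variant, rp$sequence,
                                design$reverse_mismatches[i])
    r_site <- reverse_complement(r_oligo)  # sense strand
    seq <- paste0(.random_acgt(flank_length), f_site,
                  .random_acgt(spacer_length), r_site,
                  .random_acgt(flank_length))
    rows[[i]] <- data.frame(
      id = sprintf("%s_ref%02d", g, sum(design$genus[seq_len(i)] == g)),
      domain = "Bacteria", genus = g, sequence = seq,
      stringsAsFactors = FALSE)
    fwd_hit <- f_idx[vapply(pool$forward, function(p)
      .pattern_matches_site(p$sequence, f_site), logical(1))]
    rev_hit <- r_idx[vapply(pool$reverse, function(p)
      .pattern_matches_site(p$sequence, r_oligo), logical(1))]
    prev <- truth[[g]]
    truth[[g]] <- list(
      forward = sort(unique(c(prev$forward, fwd_hit))),
      reverse = sort(unique(c(prev$reverse, rev_hit))))
  }
  list(refdb = reference_db(do.call(rbind, rows)), truth = truth,
       design = design)
}
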