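# Naive enumeration oracle for primer matching, independent of the
# package's bitmask scan: expand every degenerate position with
# expand.grid, then compare every variant at every ungapped offset.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expand <- function(sequence) {
  sets <- ORACLE_IUPAC[strsplit(sequence, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(as.matrix(grid), 1, paste, collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_min_mismatch <- function(primer, reference,
                                orientation = "forward") {
  variants <- oracle_expand(primer)
  if (orientation == "reverse")
    variants <- vapply(variants, oracle_revcomp, character(1))
  refc <- strsplit(reference, "")[[1]]
  w <- nchar(primer)
  n_off <- length(refc) - w + 1
  windows <- matrix(refc[outer(seq_len(n_off) - 1L, seq_len(w), `+`)],
                    n_off, w)
  best <- Inf
  best_off <- NA_integer_
  for (v in sort(variants)) {
    vc <- strsplit(v, "")[[1]]
    mm_by_off <- rowSums(windows != matrix(vc, n_off, w, byrow = TRUE))
    mm <- min(mm_by_off)
    off <- which.min(mm_by_off) - 1L
    if (mm < best || (mm == best && off < best_off)) {
      best <- mm
      best_off <- off
    }
  }
  list(min_mismatches = best, best_offset = best_off)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# random primer up to max_len nt with at most max_deg degenerate positions
random_degenerate_primer <- function(max_len = 25L, max_deg = 4L) {
  len <- sample(8:max_len, 1)
  chars <- strsplit(random_acgt(len), "")[[1]]
  ndeg <- sample(0:max_deg, 1)
  if (ndeg > 0) {
    pos <- sample(len, ndeg)
    chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M",
                           "B", "D", "H", "V", "N"),
                         ndeg, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# small OTU-table fixture: 4 samples (2 per protocol), 5 OTUs, 3 genera
# plus one OTU classified only to family level
make_tiny_otu <- function() {
  counts <- matrix(
    c(10L, 0L, 3L, 4L, 2L,
      5L, 1L, 0L, 6L, 0L,
      0L, 8L, 2L, 0L, 1L,
      2L, 9L, 0L, 0L, 0L),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("R1", "R2", "H1", "H2"),
                    c("Otu1", "Otu2", "Otu3", "Otu4", "Otu5")))
  taxonomy <- data.frame(
    otu_id = paste0("Otu", 1:5),
    domain = "Bacteria",
    family = c("Lactobacillaceae", "Bacteroidaceae", "Lachnospiraceae",
               "Lactobacillaceae", "Lachnospiraceae"),
    genus = c("Lactobacillus", "Bacteroides", NA, "Lactobacillus", NA),
    stringsAsFactors = FALSE)
  sample_meta <- data.frame(
    sample_id = c("R1", "R2", "H1", "H2"),
    protocol = c("Rapid", "Rapid", "HMP", "HMP"),
    stringsAsFactors = FALSE)
  otu_table(counts, taxonomy, sample_meta)
}

# percent-mode genus table with n_per samples per protocol forming two
# well-separated community profiles (all between-group dissimilarities
# exceed all within-group ones)
make_separated_genus_table <- function(n_per = 15L, seed = 42L) {
  set.seed(seed)
  g <- 8L
  prof_a <- c(70, 20, 5, 5, 0, 0, 0, 0)
  prof_b <- c(0, 0, 0, 0, 5, 5, 20, 70)
  jitter_profile <- function(p) {
    x <- pmax(p + runif(g, -1, 1) * ifelse(p > 0, 1, 0), 0)
    100 * x / sum(x)
  }
  rows <- rbind(t(replicate(n_per, jitter_profile(prof_a))),
                t(replicate(n_per, jitter_profile(prof_b))))
  dimnames(rows) <- list(
    c(sprintf("A%02d", seq_len(n_per)), sprintf("B%02d", seq_len(n_per))),
    sprintf("Genus_%02d", seq_len(g)))
  meta <- data.frame(sample_id = rownames(rows),
                     protocol = rep(c("Rapid", "HMP"), each = n_per),
                     stringsAsFactors = FALSE)
  genus_table(rows, mode = "percent", sample_meta = meta)
}

# distinctive test pool: primers share no expansions, so implanted exact
# sites identify a single primer
make_plain_pool <- function() {
  fwd <- list(
    degenerate_primer("f1", 1, "forward", "AAAACCCCGG"),
    degenerate_primer("f2", 2, "forward", "GGGGTTTTAA"),
    degenerate_primer("f3", 3, "forward", "ACACACACTT"))
  rev <- list(
    degenerate_primer("r1", 1, "reverse", "TTTTGGGGCA"),
    degenerate_primer("r2", 2, "reverse", "CCCCAAAATG"))
  primer_pool("TestPool", fwd, rev)
}

example_pools <- function() {
  read_primer_pools(system.file("extdata", "example_primers_synthetic.tsv",
                                package = "amplicomp"))
}
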