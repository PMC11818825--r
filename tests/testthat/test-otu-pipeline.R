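test_that("OTU tables round-trip through the TSV writer and reader", {
  x <- make_tiny_otu()
  tmp <- withr::local_tempdir()
  paths <- file.path(tmp, c("counts.tsv", "tax.tsv", "meta.tsv"))
  write_otu_table(x, paths[1], paths[2], paths[3])
  y <- read_otu_table(paths[1], paths[2], paths[3])
  expect_identical(y$counts, x$counts)
  expect_identical(y$taxonomy, x$taxonomy)
  expect_identical(y$sample_meta, x$sample_meta)
})

test_that("missing genus labels fall back to unclassified_<parent>", {
  x <- make_tiny_otu()
  expect_identical(x$taxonomy$genus[3], "unclassified_Lachnospiraceae")
  tax <- data.frame(otu_id = "OtuX", domain = NA, family = NA,
                    genus = NA, stringsAsFactors = FALSE)
  counts <- matrix(1L, 1, 1, dimnames = list("S1", "OtuX"))
  meta <- data.frame(sample_id = "S1", protocol = "Rapid",
                     stringsAsFactors = FALSE)
  y <- otu_table(counts, tax, meta)
  expect_identical(y$taxonomy$genus, "unclassified_root")
})

test_that("malformed inputs fail at load with the offending record named", {
  x <- make_tiny_otu()
  meta_bad <- x$sample_meta
  meta_bad$protocol[2] <- NA
  expect_error(otu_table(x$counts, x$taxonomy, meta_bad), "R2")
  expect_error(otu_table(x$counts, x$taxonomy,
                         x$sample_meta[-1, , drop = FALSE]), "R1")
  counts_bad <- x$counts
  counts_bad[1, 2] <- -1L
  expect_error(otu_table(counts_bad, x$taxonomy, x$sample_meta), "Otu2")
  expect_error(otu_table(x$counts, x$taxonomy[-4, , drop = FALSE],
                         x$sample_meta), "Otu4")
})

test_that("low-abundance filtering uses a strict fewer-than threshold", {
  counts <- matrix(c(9L, 10L, 12L,
                     20L, 20L, 19L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("O1", "O2", "O3")))
  # totals 29, 30, 31
  tax <- data.frame(otu_id = c("O1", "O2", "O3"),
                    genus = c("A", "B", "C"), stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("S1", "S2"),
                     protocol = c("Rapid", "HMP"), stringsAsFactors = FALSE)
  x <- otu_table(counts, tax, meta)
  f <- filter_low_abundance(x, min_total = 30)
  expect_identical(colnames(f$counts), c("O2", "O3"))
  expect_identical(f$counts, x$counts[, c("O2", "O3")])
  expect_identical(rownames(f$counts), rownames(x$counts))
  expect_identical(filter_low_abundance(x, 0)$counts, x$counts)
  empty <- filter_low_abundance(x, 100)
  expect_identical(ncol(empty$counts), 0L)
})

test_that("genus aggregation sums OTUs and conserves per-sample totals", {
  x <- make_tiny_otu()
  gt <- aggregate_to_genus(x)
  expect_s3_class(gt, "genus_table")
  # Otu1 + Otu4 are both Lactobacillus: 10 + 4 = 14 in sample R1
  expect_identical(unname(gt$abundances["R1", "Lactobacillus"]), 14L)
  expect_equal(rowSums(gt$abundances), rowSums(x$counts))
  # single-OTU genera pass through unchanged
  expect_identical(unname(gt$abundances[, "Bacteroides"]),
                   unname(x$counts[, "Otu2"]))
})

test_that("filtering commutes with aggregation on random tables", {
  set.seed(21)
  for (i in 1:5) {
    n_otu <- 12
    counts <- matrix(rpois(6 * n_otu, 8), nrow = 6,
                     dimnames = list(sprintf("S%d", 1:6),
                                     sprintf("O%d", seq_len(n_otu))))
    storage.mode(counts) <- "integer"
    tax <- data.frame(otu_id = colnames(counts),
                      genus = sample(c("A", "B", "C"), n_otu,
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
    meta <- data.frame(sample_id = rownames(counts),
                       protocol = rep(c("Rapid", "HMP"), each = 3),
                       stringsAsFactors = FALSE)
    x <- otu_table(counts, tax, meta)
    thr <- 50
    direct <- aggregate_to_genus(filter_low_abundance(x, thr))$abundances
    removed <- colSums(counts) < thr
    manual <- t(rowsum(t(counts[, !removed, drop = FALSE]),
                       tax$genus[!removed]))
    expect_equal(direct, manual[, colnames(direct), drop = FALSE])
  }
})

test_that("relative abundance rescales rows to 100 and flags zero rows", {
  counts <- matrix(c(25L, 75L,
                     1L, 3L,
                     0L, 0L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"), c("A", "B")))
  meta <- data.frame(sample_id = c("S1", "S2", "S3"),
                     protocol = "Rapid", stringsAsFactors = FALSE)
  gt <- genus_table(counts, "counts", meta)
  pct <- relative_abundance(gt)
  expect_equal(unname(pct$abundances["S1", ]), c(25, 75))
  expect_equal(unname(pct$abundances["S2", ]), c(25, 75))
  expect_equal(unname(pct$abundances["S3", ]), c(0, 0))
  expect_identical(pct$zero_samples, "S3")
  nz <- rowSums(pct$abundances) > 0
  expect_true(all(abs(rowSums(pct$abundances)[nz] - 100) < 1e-9))
  expect_error(relative_abundance(pct), "counts-mode")
})

test_that("prevalence is the percent of group samples with detection", {
  counts <- matrix(c(0L, 5L, 10L, 0L,
                     0L, 0L, 0L, 0L,
                     1L, 2L, 3L, 4L),
                   ncol = 3,
                   dimnames = list(sprintf("S%d", 1:4), c("A", "B", "C")))
  meta <- data.frame(sample_id = sprintf("S%d", 1:4),
                     protocol = "Rapid", stringsAsFactors = FALSE)
  gt <- genus_table(counts, "counts", meta)
  p <- prevalence(gt, "Rapid")
  expect_equal(unname(p), c(50, 0, 100))
  expect_error(prevalence(gt, "Nope"), "unknown group")
})

test_that("detected-OTU counts per genus are group-wise and order-invariant", {
  x <- make_tiny_otu()
  # Lactobacillus: Otu1 and Otu4 both detected in Rapid, Otu1+Otu4 in HMP?
  rapid <- count_otus_per_genus(x, "Rapid")
  hmp <- count_otus_per_genus(x, "HMP")
  expect_identical(unname(rapid["Lactobacillus"]), 2L)
  expect_identical(unname(hmp["Lactobacillus"]), 1L)
  expect_identical(unname(hmp["unclassified_Lachnospiraceae"]), 2L)
  expect_error(count_otus_per_genus(x, "Nope"), "unknown group")

  # permuting samples changes nothing
  perm <- c(3, 1, 4, 2)
  y <- otu_table(x$counts[perm, ], x$taxonomy,
                 x$sample_meta[perm, , drop = FALSE])
  expect_identical(count_otus_per_genus(y, "Rapid"), rapid)
  expect_identical(prevalence(aggregate_to_genus(y), "HMP"),
                   prevalence(aggregate_to_genus(x), "HMP"))
})
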