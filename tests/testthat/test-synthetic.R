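test_that("identical configs generate identical tables", {
  cfg <- bias_model_config(n_genera = 15, n_samples = 5, depth = 3000,
                           seed = 99)
  a <- generate_otu_tables(cfg)
  b <- generate_otu_tables(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$table$taxonomy, b$table$taxonomy)
  expect_identical(a$truth, b$truth)
  cfg2 <- bias_model_config(n_genera = 15, n_samples = 5, depth = 3000,
                            seed = 100)
  expect_false(identical(generate_otu_tables(cfg2)$table$counts,
                         a$table$counts))
})

test_that("every sample carries exactly the configured depth", {
  cfg <- bias_model_config(n_genera = 25, n_samples = 8, depth = 7500,
                           dropout = 0.1, seed = 3)
  sim <- generate_otu_tables(cfg)
  expect_true(all(rowSums(sim$table$counts) == 7500L))
  expect_identical(nrow(sim$table$counts), 16L)
  expect_identical(sort(unique(sim$table$sample_meta$protocol)),
                   c("HMP", "Rapid"))
})

test_that("invalid configurations are rejected", {
  expect_error(bias_model_config(depth = 0), "depth")
  expect_error(bias_model_config(concentration = -1), "concentration")
  expect_error(bias_model_config(dropout = 1.5), "\\[0, 1\\]")
  expect_error(bias_model_config(biased_genera = c(2, -2)), "named")
  expect_error(bias_model_config(biased_genera = c(Genus_01 = 12)), "cap")
  expect_error(bias_model_config(otus_per_genus = c(3, 1)), "range")
})

test_that("an unbiased community yields near-zero fold changes", {
  ests <- vapply(c(301, 302, 303), function(seed) {
    cfg <- bias_model_config(n_genera = 60, n_samples = 50, depth = 20000,
                             dropout = 0.02, seed = seed)
    sim <- generate_otu_tables(cfg)
    pct <- relative_abundance(aggregate_to_genus(sim$table))
    rapid <- pct$sample_meta$protocol == "Rapid"
    pc <- min(pct$abundances[pct$abundances > 0]) / 2
    lfc <- log2_fold_change(colMeans(pct$abundances[rapid, ]),
                            colMeans(pct$abundances[!rapid, ]), pc)
    c(mean_abs = mean(abs(lfc)), mean_signed = mean(lfc))
  }, c(mean_abs = 0, mean_signed = 0))
  expect_lt(mean(ests["mean_abs", ]), 0.4)
  expect_lt(abs(mean(ests["mean_signed", ])), 0.15)
})

test_that("an injected two-log2 bias is recovered from the counts", {
  est <- vapply(1:10, function(i) {
    seed <- 5000 + i
    null_cfg <- bias_model_config(n_genera = 60, n_samples = 50,
                                  depth = 20000, dropout = 0, seed = seed)
    bases <- generate_otu_tables(null_cfg)$truth$base_abundance
    target <- null_cfg$genera[order(bases)][30]   # median-abundance genus
    cfg <- bias_model_config(n_genera = 60, n_samples = 50, depth = 20000,
                             dropout = 0, dropout_contrast = 0,
                             biased_genera = setNames(2, target),
                             seed = seed)
    sim <- generate_otu_tables(cfg)
    pct <- relative_abundance(aggregate_to_genus(sim$table))
    rapid <- pct$sample_meta$protocol == "Rapid"
    pc <- min(pct$abundances[pct$abundances > 0]) / 2
    log2_fold_change(mean(pct$abundances[rapid, target]),
                     mean(pct$abundances[!rapid, target]), pc)
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.3)
})

test_that("prevalence differences track the dropout contrast", {
  drop <- matrix(0, 20, 2)
  drop[1, ] <- c(0.4, 0)
  cfg <- bias_model_config(n_genera = 20, n_samples = 200, depth = 5000,
                           baseline_sdlog = 0.2, dropout = drop,
                           seed = 31)
  sim <- generate_otu_tables(cfg)
  gt <- aggregate_to_genus(sim$table)
  p_rapid <- prevalence(gt, "Rapid")["Genus_01"]
  p_hmp <- prevalence(gt, "HMP")["Genus_01"]
  expect_lt(abs((p_hmp - p_rapid) - 40), 10)
})

test_that("implanted primer sites round-trip through pool matching", {
  pool <- example_pools()$RapidSynth

  # exact site of forward primer 3 -> matched forward set contains 3
  des <- data.frame(genus = "G1", forward_index = 3,
                    forward_mismatches = 0, reverse_index = 2,
                    reverse_mismatches = 0, stringsAsFactors = FALSE)
  out <- generate_reference_db(pool, des, seed = 8)
  tm <- match_pool_to_taxa(pool, out$refdb)
  expect_true(3L %in% matched_primers(tm, "G1", "forward"))
  expect_identical(matched_primers(tm, "G1", "forward"),
                   out$truth$G1$forward)
  expect_identical(matched_primers(tm, "G1", "reverse"),
                   out$truth$G1$reverse)

  # three substitutions against a single-primer pool: no match, min 3
  single <- primer_pool("Mini",
                        list(degenerate_primer("f", 1, "forward",
                                               "AGAGTTTGATCCTGGCTCAG")),
                        list(degenerate_primer("r", 1, "reverse",
                                               "TTACCGCGGCTGCTGGCAC")))
  des3 <- data.frame(genus = "G2", forward_index = 1,
                     forward_mismatches = 3, reverse_index = 1,
                     reverse_mismatches = 0, stringsAsFactors = FALSE)
  out3 <- generate_reference_db(single, des3, seed = 9)
  tm3 <- match_pool_to_taxa(single, out3$refdb)
  expect_identical(matched_primers(tm3, "G2", "forward"), integer(0))
  expect_identical(
    tm3$min_mismatches[tm3$orientation == "forward"], 3L)

  # random designs over many genera reproduce the implanted truth
  for (seed in 1:5) {
    genera <- sprintf("Gen%02d", 1:20)
    des_r <- random_site_design(pool, genera, seed = seed)
    out_r <- generate_reference_db(pool, des_r, seed = seed)
    tm_r <- match_pool_to_taxa(pool, out_r$refdb)
    for (g in genera) {
      expect_identical(matched_primers(tm_r, g, "forward"),
                       out_r$truth[[g]]$forward)
      expect_identical(matched_primers(tm_r, g, "reverse"),
                       out_r$truth[[g]]$reverse)
    }
  }
})

test_that("impossible substitution requests are rejected", {
  pool <- example_pools()$RapidSynth
  des <- data.frame(genus = "G1", forward_index = 1,
                    forward_mismatches = 25, reverse_index = 1,
                    reverse_mismatches = 0, stringsAsFactors = FALSE)
  expect_error(generate_reference_db(pool, des, seed = 1),
               "exceeds the primer length")
})
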