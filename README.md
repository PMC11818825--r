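# amplicomp

Tools for asking a practical question in microbiome profiling: **when two
16S rRNA sample-preparation protocols disagree about a community's
composition, which genera drive the disagreement — and could degenerate
PCR primers explain it?**

Different DNA extraction chemistries (bead-beating vs alkaline lysis) and
different primer sets (a single 27F/357R pair vs a degenerate V1–V3 pool)
each bias which taxa are recovered. Starting from an OTU count table with
per-sample protocol labels and a taxonomy-annotated 16S reference set,
`amplicomp` provides:

* **In-silico primer coverage** — expand degenerate (IUPAC) primers,
  scan references ungapped for exact or near-exact binding sites, and
  report per genus which primer indices of each pool have an exact match
  (`expand_degenerate`, `min_mismatch`, `match_pool_to_taxa`).
* **Genus-level community statistics** — low-count OTU filtering, genus
  aggregation, relative abundance, prevalence and per-protocol OTU
  detection counts; richness, Shannon *H*, Pielou *J = H / ln S*, Chao1
  *S + F1²/(2 F2)*; Bray–Curtis *d = Σ|x−y| / Σ(x+y)*, PCoA, ANOSIM and
  Wilcoxon tests.
* **Nine per-genus discriminating metrics** — prevalence and abundance
  differences, the genus's additive Bray–Curtis contribution, Wilcoxon
  *p*, overall mean abundance, log2 fold change and its Welch-*t* *p*,
  and random-forest mean-decrease-accuracy/Gini importances — plus
  MA-plot style enrichment calls (|log2FC| > 1, BH-adjusted *p* < 0.05).
* **Consensus ranking** — each metric issues a ranking list; the
  consensus score of a genus is the geometric mean of its nine ranks
  (the ninth root of the product of its ranking scores), and the top-*k*
  report combines ranks, primer matches, OTU counts and prevalence into
  a single table.
* **A synthetic-data generator** — two-protocol OTU tables with injected
  genus-specific log2 biases, Dirichlet overdispersion, dropout-driven
  prevalence differences and multinomial depth, and reference databases
  with implanted primer-site variants, all reproducible from one seed —
  so the entire pipeline runs and is testable with no external data.

See the vignette (`vignettes/protocol-comparison.Rmd`) for the models,
parameter choices and limitations.

## Worked example

```r
library(amplicomp)

# 1. simulate a two-protocol community with three biased genera
cfg <- bias_model_config(
  n_genera = 40, n_samples = 20, depth = 10000,
  biased_genera = c(Genus_03 = 2, Genus_11 = -2, Genus_27 = 2),
  seed = 42)
sim <- generate_otu_tables(cfg)
sim$table
#> <otu_table> 40 samples x 128 OTUs (40 genera); protocols: Rapid, HMP

# 2. filter low-count OTUs, aggregate to genus, convert to percentages
genus_pct <- relative_abundance(
  aggregate_to_genus(filter_low_abundance(sim$table)))

# 3. community-level comparison
d <- bray_curtis(genus_pct)
anosim_test(d, genus_pct$sample_meta$protocol, seed = 1)
#> $statistic
#> [1] 0.3705526
#> $p_value
#> [1] 0.001

# 4. nine per-genus metrics and the consensus ranking
metrics <- compute_genus_metrics(genus_pct, groups = c("Rapid", "HMP"),
                                 seed = 1)
consensus <- combine_ranks(rank_metrics(metrics))
head(consensus, 5)
#>   final_rank    genus    score  tied
#> 1          1 Genus_11 1.985709 FALSE
#> 2          2 Genus_27 2.494809 FALSE
#> 3          3 Genus_03 2.981728 FALSE
#> 4          4 Genus_35 8.008435 FALSE
#> 5          5 Genus_38 8.472610 FALSE
```

The ANOSIM statistic (R = 0.37, p at the 999-permutation floor of 1e-3)
says the two protocols yield significantly different communities; the
consensus ranking puts the three genera with injected bias — and only
those — at the top, with a clear score gap to the unbiased background.

Primer coverage annotates the same table. Here the references are
synthetic with implanted binding sites; with a real curated reference
set, substitute `read_reference_db()`:

```r
pool <- read_primer_pools(system.file(
  "extdata", "example_primers_synthetic.tsv",
  package = "amplicomp"))$RapidSynth
design <- random_site_design(pool, consensus$genus[1:5], seed = 2)
refs <- generate_reference_db(pool, design, seed = 2)
matches <- match_pool_to_taxa(pool, refs$refdb)
top_k_report(
  consensus, k = 5,
  match_summary = summarize_matches(matches, consensus$genus[1:5]),
  otu_counts = list(Rapid = count_otus_per_genus(sim$table, "Rapid"),
                    HMP = count_otus_per_genus(sim$table, "HMP")),
  prevalences = list(Rapid = prevalence(genus_pct, "Rapid"),
                     HMP = prevalence(genus_pct, "HMP")))
#>   final_rank    genus    score  tied      RapidSynth_forward RapidSynth_reverse
#> 1          1 Genus_11 1.985709 FALSE                no match           no match
#> 2          2 Genus_27 2.494809 FALSE                       6      1, 2, 3, 4, 6
#> 3          3 Genus_03 2.981728 FALSE                no match      1, 2, 3, 4, 6
#> 4          4 Genus_35 8.008435 FALSE                no match                  6
#> 5          5 Genus_38 8.472610 FALSE 1, 2, 3, 5, 6, 7, 8, 10           no match
#>   RapidSynth_in_database otus_Rapid otus_HMP prevalence_Rapid prevalence_HMP
#> 1                   TRUE          5        5               70            100
#> 2                   TRUE          3        3              100             70
#> 3                   TRUE          2        2              100             90
#> 4                   TRUE          1        1              100             95
#> 5                   TRUE          3        3               65             80
```

Each row reads like the headline table of a protocol comparison: the
consensus rank, which primer indices of the pool bind the genus's
references exactly (or a "not in database" flag), how many OTUs each
protocol detected for the genus, and in what fraction of each protocol's
samples it appears.

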