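---
title: "Comparing 16S sample-preparation protocols: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing 16S sample-preparation protocols: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicomp)
```

# The problem

Two sample-preparation protocols for 16S rRNA amplicon sequencing — for
example a conventional bead-beating kit with a single 27F/357R primer pair
versus an alkaline lysis kit with a degenerate V1–V3 primer pool — can
recover visibly different bacterial communities from the same material.
Two mechanisms contribute: differential cell lysis (extraction bias) and
sequence mismatches at primer binding sites (primer bias). `amplicomp`
provides the downstream machinery to quantify both from (a) an OTU count
table carrying per-sample protocol labels and (b) a taxonomy-annotated
16S reference sequence set, and to summarise which genera most
consistently discriminate between the protocols.

The pipeline starts from an OTU table: read processing, OTU clustering,
chimera removal and taxonomic classification are upstream tools'
responsibility and out of scope here.

# In-silico primer binding

A degenerate primer over the IUPAC alphabet denotes the pool of concrete
oligos obtained by choosing one base per degenerate position
(`expand_degenerate()`). For a primer and a reference sequence,
`min_mismatch()` reports the smallest Hamming distance over all ungapped
offsets and all expansions, plus the 0-based offset attaining it. Because
the expansions form the full Cartesian product over positions, the
minimum over expansions at a fixed offset equals the number of reference
bases falling outside the primer's per-position IUPAC sets; the scan is
implemented on bitmasks and verified in the test suite against a naive
expand-everything enumeration.

Numerical and representational choices:

* **Ungapped scan over the full reference.** Binding sites of 19–20 nt
  are effectively unique within a 16S gene, so no anchoring to expected
  positions is needed; the best offset is recorded. Ties go to the
  smallest offset.
* **Hamming distance only.** Indels are not modelled; primer–template
  mismatch is treated base-wise.
* **Strand convention.** References are stored as the 16S sense strand.
  Reverse primers are stored as oligo sequences and reverse-complemented
  (IUPAC-aware) before scanning, so both orientations scan the sense
  strand. The packaged example pool therefore stores the canonical
  357R-region site `GTGCCAGCAGCCGCGGTAA` as its reverse-complement oligo
  `TTACCGCGGCTGCTGGCAC`.
* **Curated references are unambiguous.** Ambiguity codes in reference
  sequences are rejected at load with a positional error rather than
  guessed at.

`match_pool_to_taxa()` aggregates per genus: a primer *matches* a genus
when at least one of the genus's references contains an exact
(0-mismatch) site; otherwise the smallest mismatch count over the genus's
references is reported. Genera requested in a report but absent from the
reference set are flagged "not in database" rather than dropped
(`summarize_matches()`).

The example primer table shipped in
`inst/extdata/example_primers_synthetic.tsv` is synthetic: it contains
the canonical 27F/357R pair plus hand-made degenerate variants (including
a concrete 27F variant, `AGGGTTCGATTCTGGCTCAG`, of the kind documented
for *Bifidobacterium* binding sites). It demonstrates the machinery; it
is not a commercial kit's primer set.

```{r primer-example}
pool <- read_primer_pools(system.file(
  "extdata", "example_primers_synthetic.tsv", package = "amplicomp"))
min_mismatch("AGAGTTTGATCCTGGCTCAG",
             paste0(strrep("T", 30), "AGGGTTCGATTCTGGCTCAG",
                    strrep("A", 30)))
```

# From OTU counts to genus profiles

`filter_low_abundance()` removes OTUs whose *dataset-wide* total count is
below 30 before anything else happens. The threshold is a strict
"fewer than": an OTU totalling exactly 30 survives. This mirrors the
common practice of removing sequences at negative-control contamination
levels; no per-control subtraction is attempted because contaminant
profiles of individual controls are not part of the input contract.

`aggregate_to_genus()` sums OTU counts within genus (reads are conserved
per sample); OTUs classified only to a higher rank get
`unclassified_<parent>` genus labels at load. `relative_abundance()`
rescales each sample to percentages summing to 100 (all-zero samples stay
zero and are flagged). Species-level summaries use the same aggregation
keyed on a different rank column, but all headline outputs are
genus-level. **No rarefaction is applied anywhere**: diversity and
metrics are computed on filtered counts/percentages as-is, so unequal
sequencing depths translate into (documented) variance differences rather
than discarded reads.

# Diversity

Alpha diversity per sample (`alpha_diversity()`, counts mode required):

* richness `S` — the count of detected genera (the simplest reading of
  observed richness; no extrapolation),
* Shannon `H = -sum p_i ln p_i` in nats,
* Pielou `J = H / ln S`, reported as missing when `S < 2`,
* Chao1 `S + F1^2 / (2 F2)`, with the bias-corrected form
  `S + F1 (F1 - 1) / (2 (F2 + 1))` when no doubletons exist. The classic
  form is used whenever `F2 > 0` so that the estimator matches its
  textbook closed form (e.g. `S = 10, F1 = 4, F2 = 2` gives 14).

Beta diversity uses Bray–Curtis dissimilarity on percent profiles
(`bray_curtis()`, via `vegan::vegdist`), classical-scaling PCoA
(`pcoa()`: double-centre the squared distances, eigendecompose, scale
eigenvectors by the square root of positive eigenvalues; negative
eigenvalues are reported but get no axes, and percent variance is over
positive eigenvalues only), and ANOSIM (`anosim_test()`, via
`vegan::anosim`). ANOSIM defaults to 999 permutations, whose attainable
p-value floor is `1 / (999 + 1) = 1e-3` — the natural resolution for
reporting strong separations. The permutation stream is controlled by an
explicit `seed` argument, as everywhere randomness enters this package.

`wilcoxon_rank_sum()` uses exact enumeration up to a combined sample size
of 20 without ties and the tie- and continuity-corrected normal
approximation otherwise.

# The nine discriminating metrics

`compute_genus_metrics()` computes, per genus, between the two protocol
groups (at least three samples each):

1. absolute prevalence difference (percentage points),
2. absolute mean-abundance difference (percentage points),
3. Bray–Curtis contribution — the genus's additive share
   `mean over between-group pairs of |x_g - y_g| / sum_k (x_k + y_k)`.
   A per-genus "Bray–Curtis distance" is not uniquely defined; this
   shared-denominator decomposition is used because the contributions
   provably sum to the mean between-group Bray–Curtis dissimilarity,
   making the metric auditable (the identity is asserted in the tests),
4. Wilcoxon rank-sum p-value on the genus's percent abundances,
5. overall mean percent abundance,
6. log2 fold change of group means with a pseudocount,
7. fold-change p-value — a two-sided Welch t-test on
   `log2(percent + pseudocount)`; Welch because group variances cannot
   be assumed equal between protocols,
8. random forest mean decrease in accuracy (out-of-bag permutation
   importance, unscaled), and
9. random forest mean decrease in Gini impurity,

from a 500-tree forest with the default `sqrt(G)` split-candidate size
classifying protocol labels. Importances depend on the random seed; under
a fixed seed they are bit-reproducible, and they are documented as
stochastic otherwise.

The **pseudocount** defaults to half the smallest non-zero percentage in
the table — scale-adaptive, keeps fold changes finite when a genus is
absent from one group, and is recorded in the result's attributes.
Zero-variance (constant) genera make the t statistic undefined: the
p-value is set to 1 when the group means coincide and to missing
otherwise; missing metric values are handled at the ranking stage.

`significance_calls()` labels a genus enriched in one protocol when
`|log2fc| > 1` **and** its Benjamini–Hochberg adjusted fold-change
p-value is below 0.05. The BH procedure is the default choice for
adjusting across tens of co-tested genera; it is selectable. Values of
log2fc strictly inside (−1, 1) are never called, whatever the p-value.

# Consensus ranking

`rank_metrics()` turns each metric column into ranks of discriminative
strength: p-values ascending (smallest p is rank 1), all magnitudes
(differences, contributions, overall abundance, importances, |log2fc|)
descending. This direction table is the only assignment under which rank
1 uniformly means "most discriminating"; it is configurable and recorded
in the result. Log2 fold change enters as its magnitude because the
headline ranking deliberately mixes genera enriched in either protocol.
Ties receive averaged ranks, so every column sums to `G (G + 1) / 2` — a
testable invariant. Missing metric values get the worst rank in their
column and are flagged.

`combine_ranks()` scores each genus by the geometric mean of its nine
ranks — the ninth root of the product of its nine ranking scores —
computed in log space for numerical stability (agreement with the
closed form is asserted to 1e-9; e.g. ranks 1..9 give
`362880^(1/9) ≈ 4.1472`). The score is strictly increasing in every rank
and invariant to the order of the metric columns. Exact score ties are
broken alphabetically and flagged. `top_k_report()` assembles the final
table: consensus rank, genus, matched primer indices per pool (or a
"not in database" flag), per-protocol detected-OTU counts and
prevalence.

# The synthetic community generator

`generate_otu_tables()` provides ground-truth-known input for every stage
(`bias_model_config()` holds the knobs):

* genus base abundances: log-normal (`meanlog 0`, `sdlog 1` — about a
  30-fold spread between the 10th and 90th percentile genus, a modest but
  realistic inequality for genus-level gut profiles);
* protocol bias: the first protocol's genus means are multiplied by
  `2^b_g`. Bias acts *before* compositional renormalisation, so the
  injected log2 effect of a rare genus is approximately recoverable while
  biasing an abundant genus perturbs every other genus — the coupling
  real compositional data exhibit;
* overdispersion: per-sample Dirichlet perturbation with concentration
  50, giving within-protocol community variation comparable to replicate
  fecal samples rather than technical replicates;
* zero inflation: per-genus, per-protocol dropout (default 0.02), with an
  extra 0.2 on the depleted side of each biased genus so prevalence
  differences accompany abundance bias (`dropout_contrast`);
* counts: multinomial at exactly `depth` reads per sample (default
  20,000), split across a genus's OTUs (1–5 per genus) by fixed
  Zipf-like weights so per-protocol OTU detection counts respond to
  depth and dropout;
* determinism: everything derives from the config's single seed;
  identical configs give identical tables.

`generate_reference_db()` builds the matching synthetic reference set:
each reference embeds a forward site and a sense-strand reverse site —
exact copies of a designated primer expansion or copies with a stated
number of substitutions, each substitution chosen outside the primer's
IUPAC set at its position so the designed mismatch count is exact. The
returned truth records every pool primer whose pattern matches an
implanted site (degenerate primers overlap, so one site can legitimately
match several primers), and `match_pool_to_taxa()` reproduces that truth
— a round-trip property exercised across random designs in the tests.

What the generator deliberately does **not** emulate: phylogenetic
sequence structure (flanks and spacers are uniform random), sequencing
error and chimeras, taxon-correlated bias (each genus's bias is
independent), and depth variation across samples. Passing tests
therefore demonstrate that the machinery recovers known signals under a
plausible compositional noise model — not that any particular real
protocol pair behaves like the simulation.

# Problem sizes and test design

The packaged experiments run at 60 genera, 30 samples per protocol and
20,000 reads per sample — large enough for stable rank behaviour, small
enough to iterate comfortably — with 20 replicate seeds for the
stochastic checks: recovery of six injected `|b_g| = 2` genera into the
consensus top ten, and the size of the raw fold-change test on unbiased
communities (checked against the binomial 99% band around 0.05).
Deterministic numerics (expansion cardinalities, mismatch scans against a
naive enumeration oracle, diversity closed forms, the consensus score)
are tested exactly or to 1e-9; classical-scaling geometry to 1e-8.

# Known limitations

* Primer coverage is sequence-identity only: no thermodynamics, no
  3'-end weighting, no amplicon-length or multi-template PCR modelling —
  an exact-match count is a proxy for, not a prediction of,
  amplification efficiency.
* The OTU-table analyses are compositional but untransformed (no CLR,
  no zero-imputation model); fold changes on percentages inherit the
  usual compositional coupling.
* ANOSIM and the rank-based metrics assume exchangeable samples within
  protocol; host/strain covariates carried in the metadata are not
  adjusted for.
* The consensus score weights all nine metrics equally; correlated
  metrics (e.g. the two forest importances) therefore carry shared
  weight. Alternative aggregation schemes are out of scope.
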