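Package: amplicomp
Title: Comparing 16S rRNA Sample-Preparation Protocols with In-Silico
    Primer Coverage and Consensus Genus Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two 16S rRNA amplicon sample-preparation
    protocols from an OTU count table and a taxonomy-annotated reference
    sequence set. Expands degenerate (IUPAC) primer pools and locates
    exact or near-exact binding sites in reference 16S sequences per
    genus; filters and aggregates OTU tables to genus-level relative
    abundances with per-protocol prevalence and OTU detection counts;
    computes alpha diversity (richness, Shannon, Pielou, Chao1),
    Bray-Curtis dissimilarity, principal coordinates, and ANOSIM;
    derives nine per-genus discriminating metrics (prevalence and
    abundance differences, Bray-Curtis contribution, Wilcoxon p,
    overall mean abundance, log2 fold change and its t-test p, random
    forest importances) and combines their ranks by geometric mean into
    a consensus ranking of protocol-discriminating genera. Includes a
    synthetic community and reference-database generator with known
    ground truth so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
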