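# protomir

Predicting whether a protein-coding gene is regulated by **any** microRNA,
from the properties of its **encoded protein** rather than from miRNA seed
matches in its 3′-UTR.

Most miRNA-target predictors work from the transcript side (seed
complementarity, binding energetics, site conservation) and disagree with
each other and with experiments. `protomir` takes the complementary,
protein-centric view: the coding region and its curated annotations
(keywords, GO terms, family membership, PTMs, tissue specificity), plus
simple sequence statistics (length, residue composition, k-mers) and
optional genomic attributes (UTR lengths, transcript structure, 3′-UTR
n-grams), are used to train per-species binary classifiers on
experimentally supported miRNA-target evidence. The package is aimed at
computational biologists who want a transparent, testable version of that
workflow: every stage is an exported, pipe-friendly function on tibbles,
and a synthetic-data generator with planted ground truth makes the whole
pipeline verifiable offline.

## The method in brief

**Labels.** Per-gene evidence rows are collapsed into a three-way label:
`1` (regulated) for genes with at least one strong-evidence experiment
(reporter assay, Western blot, qRT-PCR) or at least two *unique* weak
(high-throughput) experiments; `0` (likely positive) for a single unique
weak experiment; `-1` (negative) otherwise. Likely positives are treated as
positives by default; excluding them is supported.

**Feature ranking.** Every candidate binary feature *a* is scored by
relative information gain against the binary label *T*:

    IG(T, a) = H(T) − H(T | a),    RIG = IG / H(T)

with the label entropy H in bits. RIG jointly captures a feature's lift
(`P(class | feature) / P(class)`) and its support (fraction of genes
covered). Numeric features are binarized at the RIG-optimal threshold.
Features are screened by an uncorrected Pearson chi-squared test
(p ≤ 1e-4), de-duplicated (identical or complementary columns carry the
same information), and greedily selected by RIG up to 300 features under a
redundancy cap.

**Models.** Logistic regression, random forests or gradient boosted trees
on the selected features; 20% stratified held-out evaluation with rocAUC,
accuracy, F1, and precision/recall of the minority class; cross-species
transfer by projecting a second proteome onto the trained feature space;
feature-set ablations (protein / sequence-only / genomic / unified).

**Family coherence.** Per-family regulated fractions with exact two-sided
binomial tests against the global prior, and a mode-assignment statistic:
predicting each gene's label by its family's majority label and testing
the success count with a one-sided exact binomial test against an
analytically computed null rate.

## Worked example

A fully synthetic study: 2,000 genes at a 75% regulated prior, 20 planted
keyword features (lift 1.5), noise keywords, label-shifted sequence
lengths and lysine content, and coherent families.

```r
library(protomir)
library(dplyr)

cfg    <- generator_config(n_genes = 2000, seed = 42)
study  <- simulate_study(cfg)
labels <- summarize_evidence(study$evidence, "synthetica") |>
  assign_labels(study$proteome$gene_name)
binary <- binarize_labels(labels, "weak_as_positive")

fm <- assemble_features(
  featurize_annotations(study$proteome, ngram_max = 1),
  featurize_sequences(study$proteome, k_range = NULL),
  genes = study$proteome$gene_name)
fm
#> <feature_matrix> 2000 genes x 2421 features (2374 binary, 47 numeric)

split <- split_train_test(binary$gene_name, binary, 0.2, seed = 42)
fit   <- fit_evaluate(fm, binary, split, family = "logistic", seed = 42)
fit$evaluation
#>   n_test prior_pos roc_auc precision_minority recall_minority    f1 accuracy
#> 1    400      0.76   0.846              0.672           0.427 0.883    0.812

tidy(fit$selection)[1:5, c("rank","feature_id","rig","support","lift_pos","lift_neg","chi2_p")]
#>   rank   feature_id    rig support lift_pos lift_neg   chi2_p
#> 1    1    aa_frac:K 0.0893 0.36188    0.763     1.75 4.08e-37
#> 2    2   aa_count:K 0.0596 0.22375    0.720     1.89 7.60e-27
#> 3    3   aa_count:M 0.0286 0.31000    0.848     1.48 4.02e-13
#> 4    4 fam:FAM01023 0.0246 0.00937    0.000     4.18 4.02e-12
#> 5    5   aa_count:R 0.0237 0.20563    0.815     1.59 2.03e-11

coherence_test(binary, filter(study$families, source == "treefam"))
#>   n_families_tested n_coherent coherence_fraction mode_successes mode_trials
#> 1               284        263             0.9261            997        1021
#>   null_rate binom_p_one_sided
#> 1    0.7922         1.286e-69
```

Reading the output: the held-out rocAUC of 0.846 means a randomly chosen
regulated gene outscores a randomly chosen unregulated one 84.6% of the
time. The top-ranked feature is the lysine composition fraction
(binarized at its optimal threshold): genes below it are 1.75× more likely
to be unregulated — the planted composition shift, rediscovered by the
ranker. The coherence test finds 92.6% of multi-member families
label-coherent, far above the 79.2% expected under independent labels
(p ≈ 1e-69).

`autoplot(fit$selection)`, `plot_ablation()` and
`plot_family_fractions()` provide the standard displays, and
`run_pipeline(pipeline_config(...), out_dir)` executes the whole workflow
and writes every report as TSV.

Real data are supported through `read_protein_table()` (UniProtKB-style
exports, via `uniprot_column_map()`), `read_evidence_table()`
(miRTarBase-style CSV/TSV with a configurable strong/weak experiment
vocabulary), genomic attribute and family-map TSVs, with strict case-folded
gene-name mapping across resources (`map_gene_names()`).

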