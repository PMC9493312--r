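---
title: "Predicting miRNA regulation from the proteome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA regulation from the proteome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

MicroRNAs repress target mRNAs mostly through 3′-UTR binding, and nearly
all target predictors therefore reason from the transcript: seed matches,
site conservation, folding energetics. `protomir` formalizes the
complementary question — *is this gene regulated by any miRNA at all?* —
as a binary classification problem over genes, using the encoded protein
as the primary information source. The premise is that coding regions and
their functional annotations are under much stronger purifying selection
than 3′-UTRs, so whatever makes a gene's product amenable (or hostile) to
post-transcriptional tuning should be legible from protein-level features
and should generalize across species better than fast-evolving binding
sites do.

The pipeline is: evidence-based labeling → feature generation → ranking
and selection → model fitting and evaluation → family-coherence analysis,
each stage an exported function on tibbles, orchestrated by
`run_pipeline()`.

## Labels from experimental evidence

Evidence rows carry an experiment descriptor and a reference; a
configurable vocabulary maps descriptors to *strong* (targeted
validation: reporter assays, Western blots, qRT-PCR) or *weak*
(high-throughput screens: CLIP-based sequencing, pSILAC, microarrays).
A gene is labeled

* `1` (regulated) with ≥ 1 strong experiment **or** ≥ 2 *unique* weak
  experiments,
* `0` (likely positive) with exactly one unique weak experiment,
* `-1` (negative) with no evidence row.

Uniqueness of a weak experiment is decided on an `experiment_key`: the
upper-cased descriptor joined to the reference id. The finest key
available in all common evidence exports is experiment type plus
publication, so two CLIP experiments from different papers count twice,
while a re-listed row counts once. Binarization treats likely positives
as positives by default (`weak_as_positive`); `exclude_weak` is exposed
because dropping them has been reported to sharpen models, and
`weak_as_negative` completes the lattice. The label-1 set is invariant to
this choice, which the tests assert.

## The feature space

Three generator families produce a long `(gene, feature, value)` tibble:

* **sequence** — numeric length, molecular weight, per-residue counts and
  composition fractions over the 20 canonical residues (ambiguity codes
  X/B/Z/U stay out of the 20 fractions, so fractions sum to ≤ 1), and
  binary presence of observed k-mers (default k in 1–3);
* **annotation** — binary incidence of each keyword, unordered keyword
  pairs (order ≤ 2 by default), GO terms per branch, family memberships,
  non-emptiness flags (PTM, disease, tissue, pharmaceutical), organ
  substrings of the tissue text, plus numeric annotation counts;
* **genomic** — transcript/CDS/UTR lengths, splice-variant counts,
  chromosomal position, nucleotide counts, chromosome identity,
  `has_utr3`, and optionally 3′-UTR n-grams of sizes 2–4 and 5–6.

`assemble_features()` unions the ids over the gene universe; absent binary
features become 0, absent numerics become `NA` with an
`is_missing(...)` companion indicator; binary columns supported by fewer
than `min_support_count` genes (default 5) and constant columns are
pruned. Missing numerics are imputed with the training median at model
time. No feature may derive from miRNA annotations or from the evidence
table itself — featurizers tag their provenance, and the pipeline never
routes evidence content into the matrix — so the label cannot leak into
the features.

The k-mer range and keyword n-gram order are configuration, not dogma:
they bound the candidate space at desk scale (a few thousand features per
organism rather than millions) while still covering single keywords,
keyword pairs, and short motifs.

## Ranking by relative information gain

For the binary label \(T\) and a binary feature \(a\),
\(IG(T,a) = H(T) - H(T\mid a)\) in bits. We report the normalized form
\(RIG = IG / H(T)\): normalization by the label entropy makes scores
comparable across organisms whose priors differ wildly (a 76% prior and a
3% prior give very different \(H(T)\)); the unnormalized IG is stored
alongside. RIG is complement-invariant, lies in [0, 1], and is zero
exactly at empirical independence — all property-tested against a
brute-force entropy oracle.

Numeric features are binarized label-aware: every midpoint between
consecutive distinct values is evaluated and the RIG-maximizing split is
kept, ties broken toward the smaller threshold; the feature-positive side
is the minority side of the winning split, which reads naturally for
sparse indicator-like features ("under 349 residues"-style thresholds).

Selection proceeds in three passes. A chi-squared screen (2×2 Pearson
statistic, 1 df, no continuity correction, uncorrected p ≤ 1e-4 — no
multiplicity adjustment, matching the screening character of the test)
removes unassociated features; degenerate tables (a zero margin) score
p = 1 with a warning. Exact duplicates and exact complements are grouped —
such columns are indistinguishable to any model — keeping the
lexicographically smallest id and recording the rest with their retained
proxy. Finally a greedy pass in descending RIG picks up to K = 300
features, skipping candidates whose binarized column exceeds an absolute
phi correlation of 0.95 with anything already selected. Near-ties in RIG
(within 1e-3, implemented as banding) are broken toward the feature with
fewer generator compositions — a keyword beats a keyword pair of equal
standing — favouring semantically simpler, more interpretable features at
negligible cost.

## Models and evaluation

Three families are supported: logistic regression (`glm`), random forests
(`ranger`), gradient boosted trees (`xgboost`). When a hyperparameter
grid is supplied, the configuration is chosen by stratified 5-fold
cross-validated rocAUC *inside the training split only*; feature scoring
and selection likewise see only training genes (`fit_evaluate()`), so the
held-out 20% stratified test set is untouched by any modeling decision.
With no feature surviving the screen the model degenerates to the
training prior — constant scores, rocAUC exactly 0.5 — which is the
correct behaviour under label shuffling and is what the permutation tests
check.

rocAUC is computed in rank form, equal (to 1e-12, tested) to the
probability that a random positive outscores a random negative with ties
counted one half. Accuracy is (TP+TN)/n and F1 is 2TP/(2TP+FP+FN) with
class 1 as positive; precision and recall are reported for the *minority*
class of the evaluated labels, the convention that stays informative when
the prior is far from one half in either direction. The default decision
threshold is 0.5. Exported prediction tables scale scores by 100.

**Cross-species transfer.** A model trained on organism A is evaluated on
the full proteome of organism B after projecting B's features onto A's
selected space; annotation vocabulary unseen in B is encoded as absent
(0), absent numerics take A's training medians. Incidence features are
open-vocabulary, so absence — not missingness — is the natural encoding.
The transfer experiments use a shared-vocabulary feature protocol
(keywords, flags, counts, tissue, GO, sequence statistics) that excludes
family-membership features: family identifiers are resource- and
species-bound vocabularies whose label associations cannot carry over,
and including them only dilutes the projected model. The in-species
reference rocAUC for transfer comparisons is computed under the same
protocol.

## Family coherence

`family_fractions()` gives each family's regulated fraction and an exact
two-sided binomial p against the global prior. Throughout the family
module the two-sided p is the *double smaller tail*,
\(\min(1,\, 2\min(P(X\le x), P(X\ge x)))\) — a transparent definition
that matches an independent summation oracle to 1e-12 (the
minimum-likelihood method of `binom.test` differs and is used only as a
cross-check of the tails).

`coherence_test()` asks whether families share a regulatory tendency:
(1) the fraction of families (≥ 2 members) whose members all carry one
label; (2) mode assignment — each gene's label predicted by its family's
majority, ties resolved toward the global majority label, a choice that is
conservative because it never credits a tie to family structure. Genes in
several qualifying families contribute exactly one trial, through their
lexicographically first family, keeping the binomial trials free of
multiplicity. (3) The success count is tested one-sided ("greater")
against an analytic null rate: for a family of size *s* with labels iid
at the global prior *p*, the expected per-member mode-match probability
is computed by enumeration over the binomial distribution of
within-family positives, and the rates are averaged with trial weights.
A label-shuffling simulation (`coherence_null_simulation()`) cross-checks
the analytic null; its p-values are approximately uniform, with the mild
conservatism expected from a margin-preserving permutation of a discrete
statistic. `unmatched_family_report()` contrasts genes lacking any family
assignment with the rest.

## The synthetic-data generator

`generator_config()` fixes the study conditions the package is validated
under; the defaults are chosen once to mirror a well-annotated
vertebrate-like study and are not tuned per experiment:

* 5,000 genes at prevalence 0.75 — the regulated fraction of a
  well-studied proteome, and large enough for stable held-out estimates;
* 20 planted keyword features of lift 1.5 with marginal support drawn in
  5–15%, against 2,000 label-independent noise keywords with support
  0.5–5%;
* families from a truncated power law (exponent 2.5, max 50 — most
  families are singletons), 90% of genes familied, family coherence 0.9;
* log-normal protein lengths (meanlog 6.0, sdlog 0.55 — median ≈ 400
  residues), with unregulated genes shifted shorter by 0.25 on the log
  scale; a +0.01 lysine composition excess in regulated proteins;
  log-normal 3′-UTRs with regulated genes shifted longer by 0.5;
* an evidence model in which half the positives carry strong evidence and
  the rest ≥ 2 unique weak experiments, 10% of regulated genes are
  observed only as a single weak experiment (label 0), and weak rows are
  sometimes duplicated verbatim.

**Calibrated lifts.** A planted feature with overall support *s* and lift
*l* for dominant class *c* is attached with probability \(l \cdot s\)
given the dominant label and \(s(1 - l\,P(c))/(1 - P(c))\) otherwise.
This keeps the marginal support at *s* and makes the configured lift
*exactly* the quantity `lift_and_support()` estimates, enabling direct
parameter-recovery tests. It also imposes the real constraint
\(l \le 1/P(c)\): at a 0.75 prior, lifts above 1.33 are only achievable
for the minority (unregulated) class — which is why substantial planted
lifts are minority-class features here, just as the large published lifts
at skewed priors belong to the minority class. Infeasible configurations
fail loudly, naming the feature.

**Second species.** `generate_second_species()` keeps the first
`round(overlap · n)` planted associations (same tokens, lifts, supports,
classes), retires the remaining tokens to label-independent noise at
their original support, and plants fresh private tokens in their place;
the noise vocabulary is shared, gene and family namespaces are not. The
label-linked numeric shifts (length, composition, 3′-UTR) are scaled by
the same overlap, so overlap 0 carries no transferable signal of any kind
and overlap 1 reproduces the first species' generative conditions — the
two endpoints the transfer tests pin down, with monotone behaviour in
between.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real keyword semantics and their correlation
structure, sequence homology within families, codon-level composition
effects, annotation-depth bias between well- and poorly-studied genes,
and evidence biases toward highly expressed transcripts. The synthetic
results validate the machinery (estimators, tests, selection, transfer
logic), not any biological claim.

## Numerical choices and degenerate inputs

Entropies use the 0·log 0 := 0 convention; RIG errors on pure labels
(normalization undefined). Thresholds are midpoints of consecutive
distinct values, ties toward the smaller cut. Chi-squared degenerate
tables give p = 1 with a warning rather than an error, so screening a
constant-ish column is safe. Empty selections fall back to a prior model.
Single-class test labels yield `NA` rocAUC; constant vectors yield `NA`
concordance, both with warnings. All stochastic steps flow from a single
run seed through fixed offsets; `ranger` and `xgboost` run single-threaded
under explicit seeds, which the byte-identity tests of the pipeline rely
on.

Problem sizes used by the test suite and the acceptance script — 5,000
genes for recovery/performance/transfer, 2,000 for the end-to-end
determinism runs, 200 shuffles for null calibrations — are the package's
chosen validation scale: large enough that binomial standard errors make
the planted-parameter checks sharp, small enough to keep the suite
routinely runnable.

## Known limitations

* Real-data ingestion covers delimited exports (CSV/TSV plus FASTA);
  spreadsheet files should be exported to CSV first, and full SwissProt
  flat files are out of scope.
* The feature space is deliberately bounded (no composite arithmetic
  features, no aggregation synthesis beyond keyword pairs); the
  generator-tag mechanism is the extension point.
* The redundancy pass is a transparent greedy phi-correlation cap, not a
  marginalized mutual-information scheme; with many near-collinear
  informative features the selected set depends on the (deterministic)
  ordering.
* Per-miRNA resolution is out of scope by design: the unit of prediction
  is the gene, "regulated by any miRNA".
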