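---
title: "Curating and generating negative data for ligand-based screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and generating negative data for ligand-based screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Bioactivity repositories are dominated by actives: positive findings get
published and deposited, inactive measurements mostly do not. Classifiers for
virtual screening therefore train against negatives that are either assumed
(random database samples, property-matched decoys) or absent. This package
implements the alternative: mine the repository's own *inactive* records for
compounds whose inactivity is broadly attested, expand that set with a
generative model, and measure what the choice of negatives does to a
classifier. This vignette explains the models and the decisions behind each
stage; the README shows the corresponding worked example.

## 1. The assay-diversity score

A compound that failed 70 times in one cell-viability panel is weak evidence
of general inertness; a compound that failed across enzymatic, cell-based and
binding assays against many targets is strong evidence. We therefore score
each compound's testing history along three categorical axes: a *cluster* of
the assay's free-text name, the annotated *assay type*, and the annotated
*target*. For one axis, let the compound's outcomes fall into categories with
counts $f(a_i)$, $N = \sum_i f(a_i)$ and $n$ distinct categories. With
$p(a_i) = f(a_i)/N$,

$$H = -\sum_{i=1}^{n} p(a_i)\,\log_2 p(a_i), \qquad
  H_{norm} = \frac{H}{\log_2 n},$$

and the assay-diversity score is the arithmetic mean of the three axis values,

$$D_{assay} = \tfrac13\left(H^{cluster}_{norm} + H^{type}_{norm}
  + H^{target}_{norm}\right) \in [0, 1].$$

Decisions a reader should know about:

* **Log base.** Both $H$ and the normalizer use base 2, so $H_{norm}$ is
  exactly $H/H_{max}$; the ratio is base-invariant as long as the bases
  match.
* **$n$ is per-compound.** $n$ counts the categories *observed for that
  compound*, not the global category vocabulary. Under the global reading a
  compound tested in, say, 40 of 9,000 clusters could never approach
  $H_{norm} = 1$ and typical scores would collapse toward 0, which is
  incompatible with median-scale cutoffs; the per-compound reading also
  matches the definition of $H_{max}$ as the entropy when observations are
  spread over the observed categories.
* **Degenerate axes.** $n \le 1$ gives $H_{norm} = 0$ (the $0/0$ in the
  normalizer is resolved to "no diversity"); an axis with no annotated assays
  (e.g. missing targets) contributes 0. Assays lacking a target annotation
  are ignored on the target axis rather than pooled into a "no target"
  pseudo-category, which would reward untargeted panels with spurious
  diversity.

## 2. Outcome curation

Outcomes arrive per (assay, compound) as `active`, `inactive`, `unspecified`
or `inconclusive` (case-insensitive; anything else is rejected). The
resolution policy is conservative toward activity:

1. Literature records annotated `unspecified`/`inconclusive` are classified
   from the reported AC50: **active iff AC50 ≤ 1000 µM**, otherwise (or with
   no AC50) inactive.
2. HTS records with those annotations have no curation path and are dropped,
   with a logged count. The repositories we emulate only resolve ambiguous
   records through literature review, so no label can be assigned to an
   ambiguous HTS row without inventing one.
3. Duplicate depositions are collapsed; then, within one assay, a compound
   annotated both active and inactive is **active** (one positive reading
   outweighs repeated negatives).

A compound becomes a *curated inactive compound* (CIC) when it clears three
conditions simultaneously: `n_assay` strictly above a testing-depth cutoff,
`d_assay` strictly above a diversity cutoff, and **no** active outcome
anywhere in its history. The default cutoffs are distribution-derived — a
nearest-rank percentile of `n_assay` (default the 93rd) and a quantile of
`d_assay` (default the median). Because testing depth is strongly multimodal
in real repositories (shallow single-panel testing versus deep profiling),
`derive_thresholds(method = "kde")` alternatively reports the rightmost local
maximum of a log-scale kernel density; both cutoffs also accept manual
overrides, and every threshold records its provenance.

## 3. Assay-name clustering

Assay names are embedded by a pluggable text-embedding backend (a pretrained
biomedical language model in production; deterministic shingle hashing in
tests, so no model download is ever required) and clustered by hierarchical
density clustering on mutual-reachability distances with
`min_cluster_size = 20` and `cluster_selection_epsilon = 0.03` — splits below
the epsilon scale are not resolved, and clusters are selected by excess of
mass. Two choices matter downstream:

* **Noise becomes singletons.** Density-unassigned assays are each given a
  fresh singleton category (configurable to a single bucket). One giant
  "noise" class would look like a single shared category and deflate the
  diversity of every compound tested in unclusterable assays — the exact
  compounds the metric is meant to rank.
* **Euclidean distance on raw embeddings**, no whitening; the embedding
  scale is what the epsilon refers to.

The 2-D UMAP projection (`project_2d`) is provided for inspection only and
carries no quantitative contract.

## 4. The SMILES generator

The generator is a character-level LSTM language model over SMILES tokens,
implemented in vectorized base R (this package has no deep-learning
dependency; model sizes here — tens of tokens, a few hundred hidden units —
are well inside what BLAS-backed matrix algebra handles, and the analytic
gradients are verified against finite differences in the test suite).

* **Tokenization** is atom-wise by default: bracket atoms, `Cl`/`Br` and
  `%nn` ring closures are single tokens, so detokenization is concatenation
  and round-trips exactly. A pure-character mode is available
  (`tokenizer = "char"`).
* **Augmentation** writes each training molecule as multiple randomized
  atom-order SMILES (2–500× in the reference sweeps; every augmented string
  canonicalizes back to its source, a property the suite asserts corpus-wide).
* **Training** uses teacher forcing on begin/end-delimited sequences, Adam
  ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning rate $10^{-3}$) for up to 300
  epochs, early-stopped on the cross-entropy of a held-out 10% of the
  augmented strings (min-delta 0.001, patience 10); the weights of the best
  epoch are restored. The monitored quantity is our choice of held-out
  cross-entropy — the natural early-stopping monitor for a language model.
* **Unstated sizes.** Hidden width (default 256) and embedding width
  (default 128) are package defaults, configurable; reference work fixes
  only the layer count (1 or 3). Sampled sequences are capped at 120 tokens,
  which covers realistic drug-like SMILES with margin.
* **Sampling** is ancestral with a temperature on the logits; temperature
  → 0 reduces to greedy decoding. A run aggregates samples into a frequency
  map keyed by *canonical* structure; syntactically invalid strings count
  toward the raw total only.

Post-generation filters remove canonical strings shorter than 15 characters
(character length of the canonical form, per the stated wording; the
token-count alternative is noted here for transparency), structures failing
the organic filter (must contain carbon; elements restricted to
H/B/C/N/O/F/P/S/Cl/Se/Br/I — excluding azides, halide salts and other
inorganics), and structures already in the reference set. Frequency tiers
then keep structures generated *strictly more than* 100/30/10/3/1 times;
"more than once" is read as frequency ≥ 2, consistent with the strict
inequality of the other tiers, and the tiers are nested by construction.

## 5. Generator evaluation

Five metrics on a fixed-size sample: validity (parseable fraction),
uniqueness (distinct canonical structures ÷ valid strings), novelty
(distinct structures absent from the reference), and the cosine similarity
of normalized Murcko-scaffold and BRICS-fragment frequency profiles between
generated and reference sets. Uniqueness and novelty operate on canonical
*structures*, the field's convention, rather than raw strings. Acyclic
molecules carry an explicit no-scaffold key so profile vectors stay
comparable. (Descriptions of this metric family sometimes count six metrics
while naming five; we implement the five named ones.)

## 6. Profiling and the benchmark harness

Standard chemistry goes through OpenBabel (via ChemmineR/ChemmineOB):
canonicalization, descriptors, SMARTS matching, and ECFP fingerprints.
Noteworthy conventions:

* **"ECFP4" means radius 2** (diameter 4); the radius is configurable. The
  4096-bit hashed fingerprints are folded to 1024 bits.
* **Ro5 compliance is zero-violation** by default (MW ≤ 500, logP ≤ 5,
  donors ≤ 5, acceptors ≤ 10, boundaries inclusive; acceptors counted as
  N + O); a one-violation mode exists. The logP estimate is OpenBabel's
  atomic-contribution model, and the estimator name is recorded on every
  property table.
* **PAINS**: the bundled catalog is a representative ~24-pattern subset of
  the published families (quinones, catechols, rhodanines, hydrazones, azo
  compounds, ...), user-replaceable by any catalog in the same TSV format.
* **Murcko scaffolds** are computed by iterative terminal-atom pruning
  (retaining exocyclic multiply-bonded atoms), **BRICS fragmentation** by the
  published retrosynthetic environment/compatibility table; both are checked
  against an independent toolkit in the suite. Fragments are compared as
  plain structures without dummy-atom attachment marks, an internal
  convention that cancels out of the cosine construction.
* **Tanimoto of two empty fingerprints is 0**; MCC with a zero denominator
  factor is 0; scaffold enrichment uses a 1-df chi-squared on each
  scaffold's 2×2 presence table without continuity correction,
  Benjamini–Hochberg adjusted at α = 0.05 by default (raw-p mode available),
  and degenerate margins are never flagged.

The benchmark harness trains a fingerprint random forest (ranger, 500 trees
by default, positive-class vote fraction as the score — forest size is our
choice and is recorded) per (endpoint × strategy × repeat) cell. The
hold-out test set (20%) is always drawn from the endpoint's verified actives
and inactives and is *identical across strategies* for a given
(endpoint, repeat): child seeds derive deterministically from the master
seed via a labelled counter, so strategy arms are paired. Negatives are
undersampled to at most twice the positives in **both** training and test
sets. Training negatives are resampled every repeat (the once-per-strategy
alternative would understate between-split variance). Comparative
statistics: two-sided paired Wilcoxon on per-endpoint means (exact null up
to n = 25 when free of ties and zeros, normal approximation with continuity
correction otherwise; all-zero differences return p = 1 with a warning) and
Spearman correlation between performance and the negative pool's mean
nearest-neighbor Tanimoto similarity to the verified compounds.

## 7. What the synthetic data emulates — and what it does not

The fixture generators make every stage testable offline:

* `synth_bioassay_tables()` ties the three category axes together through
  assay *families*, draws per-compound testing depth from a two-mode mixture
  (Poisson(3) and Poisson(150), mimicking the strongly multimodal depth
  distributions of public repositories at toy scale), and plants compounds
  that are redundant (all assays from one family, probability ρ), deeply and
  diversely tested, or carriers of active outcomes. At ρ = 1 every planted
  redundant compound has $D_{assay} = 0$ by construction; at ρ = 0 deeply
  tested compounds approach the maximum.
* `synth_smiles_corpus()` assembles molecules from ~40 ring cores and
  substituents over organic elements only, so every string parses and
  passes the organic filter by construction.
* `synth_endpoint()` builds actives and verified inactives over *shared*
  ring cores with different, deliberately overlapping substituent
  distributions — separable but not trivially so — plus negative pools whose
  mean nearest-neighbor similarity to the verified inactives decreases
  monotonically in a single offset parameter.

What passing tests on these fixtures shows: the pipeline's rules, formulas
and invariances are implemented correctly, and the directional claims (the
diversity score separates planted diverse from redundant compounds;
classifiers trained on negatives near the verified inactives outperform
those trained on distant ones) hold on data engineered to contain those
structures. What it does not show: that the same effect sizes appear on real
repository dumps, whose category structure, activity noise and chemical
diversity are far richer than the fixtures'.

## 8. Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, our choice of
sizes for a self-contained build: curation on ~90 synthetic compounds × 240
assays; the degenerate-corpus check trains a 64-unit, single-layer model on
one molecule at 100× augmentation and samples 300 strings; the corpus-scale
generator trains on 60 grammar molecules at 10× augmentation for up to 60
epochs and is evaluated on a 500-string sample (its validity at this scale —
roughly 20% — reflects a deliberately short training run; validity is the
metric that grows most with training budget); the benchmark sweeps 16–20
synthetic endpoints × 2 pool types × 3 repeats with 120–150 trees. Entropy
agreement with the brute-force oracle is exhaustive over all count multisets
with N ≤ 8 in up to 4 categories. Exact expectations are asserted at
tolerance 1e-12 where algebra is exact; stochastic directional checks assert
ordering, not magnitudes.

## 9. Known limitations

* The embedding backend for production use (a pretrained biomedical language
  model) is injected by the caller; the package ships only the deterministic
  fixture embedder.
* The bundled PAINS subset understates full-catalog PAINS rates; supply a
  complete catalog for screening-grade use.
* OpenBabel and other toolkits differ in aromaticity perception and
  canonical forms for exotic structures; cross-toolkit comparisons in the
  suite canonicalize both sides with the same toolkit before comparing.
* The LSTM is CPU-bound R; it is sized for curated sets of thousands of
  molecules, not for multi-million-string production sampling.
* Scaffold enrichment treats each molecule's single Murcko scaffold as its
  unit of presence; ring-system-level or generic-framework analyses are out
  of scope.
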