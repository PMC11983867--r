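# inertforge

Negative-data curation and generation for ligand-based virtual screening.

Bioactivity databases are skewed toward active compounds, so classifiers for
activity prediction are usually trained against *assumed* negatives — random
database samples or property-matched decoys. `inertforge` implements the
data-driven alternative end to end:

1. **Curate** compounds whose inactivity is broadly attested. Per-compound
   testing history is scored by the assay-diversity metric
   `D_assay = (H_norm^cluster + H_norm^type + H_norm^target) / 3`, the mean
   of normalized Shannon entropies `H_norm = −Σ p(aᵢ) log₂ p(aᵢ) / log₂ n`
   over three assay-category axes (a density cluster of the assay-name
   embedding, the annotated assay type, and the annotated target).
   Compounds with `N_assay` and `D_assay` strictly above
   distribution-derived cutoffs and **no** active outcome anywhere become
   curated inactive compounds (CICs). Conflicting within-assay annotations
   resolve to active; ambiguous literature records are classified by
   AC50 ≤ 1000 µM.
2. **Generate** new candidate inactives with a character-level LSTM SMILES
   generator trained on the curated set (randomized-SMILES augmentation,
   Adam, early stopping), then keep structures by generation frequency
   (strictly more than 100/30/10/3/1 occurrences) after validity, length,
   organic-element and reference-exclusion filters.
3. **Evaluate and profile**: validity / uniqueness / novelty and
   Murcko-scaffold / BRICS-fragment cosine similarity for the generator;
   Lipinski rule-of-five, PAINS substructure flags, ECFP4 (1024-bit)
   fingerprints with Tanimoto similarity, and chi-squared scaffold
   enrichment for any compound set.
4. **Benchmark** how the negative-label source changes a fingerprint
   random-forest classifier: per endpoint, strategies share an identical
   hold-out test set of verified compounds across repeated splits
   (negatives undersampled to ≤ 2× positives), compared by paired Wilcoxon
   tests and by the Spearman correlation between performance and the
   negative pool's nearest-neighbor Tanimoto similarity to verified
   inactives.

Every stage runs offline: seeded synthetic generators supply bioassay
tables with controllable redundancy, valid SMILES corpora from a fragment
grammar, a deterministic text embedder, and benchmark endpoints with
controlled similarity structure.

## Worked example

Curate inactives from a synthetic bioassay table, then train a toy
generator:

```r
library(inertforge)

syn      <- synth_bioassay_tables(synth_assay_config(seed = 7))
outcomes <- harmonize_outcomes(resolve_ambiguous_outcomes(syn$results))
emb      <- embed_assay_names(syn$metadata$name,
                              make_fixture_embedder(dim = 32, seed = 7))
cats     <- assign_categories(syn$metadata,
                              cluster_embeddings(emb, min_cluster_size = 10))
scores   <- compute_d_assay(build_compound_profiles(outcomes, cats))
head(scores[order(-scores$d_assay), ], 3)
#>    compound_id h_cluster h_type h_target d_assay n_assay any_active
#> 22       C0022         1      1        1       1       2      FALSE
#> 36       C0036         1      1        1       1       3       TRUE
#> 43       C0043         1      1        1       1       3      FALSE

(th <- derive_thresholds(scores, n_assay_percentile = 60))
#> curation thresholds (strict lower bounds):
#>   N_assay  > 38   [nearest-rank percentile 60 of n_assay]
#>   D_assay  > 0.963672   [quantile 0.5 of d_assay]
length(select_cics(scores, th))
#> [1] 21
```

`C0022` was tested in only 2 assays — maximally diverse ones, but far too
few: the joint `N_assay`/`D_assay` rule is what keeps it (and the
active-bearing `C0036`) out of the curated set of 21.

A generator trained to convergence on a single molecule must reproduce it;
this is the package's built-in degenerate-corpus check:

```r
gen <- train_generator("CCO",
         generator_config(n_layers = 1, augmentation_factor = 50,
                          hidden_size = 64, embed_size = 24,
                          max_epochs = 150, batch_size = 32, seed = 7))
sample_generator(gen, 200, seed = 11)
#> generation run: 200 sampled string(s)
#>   valid: 195 (97.5%), distinct structures: 12
#>   most frequent: CCO x 176
```

A thin command-line front end covers the same workflow
(`exec/inertforge simulate-bioassay | curate | train-gen | sample |
genmetrics | profile`).

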