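# mclprio

Genome-wide prioritization of candidate drug targets for **mesocorticolimbic
(MCL) disorders** — the group of mental disorders (depression, schizophrenia,
addiction-spectrum and eating disorders, Parkinson's disease, and others)
linked to altered function of the brain's reward circuit. The package is
aimed at computational biologists doing knowledge-driven drug repurposing:
it takes a curated knowledge base (protein interactome, pathway collections,
linear signaling chains, per-disorder biomarker and drug-target annotations)
and produces a ranked list of every protein's plausibility as a target for
the disorder group, together with honest cross-validated performance
estimates.

Because the curated commercial databases such pipelines typically run on are
not redistributable, the package ships a synthetic knowledge-base generator
with planted ground truth, so the entire pipeline can be exercised,
benchmarked and regression-tested end to end.

## Method

Every protein *i* in the universe receives complementary evidence scores:

**Knowledge-based (per disorder):**

* biomarker indicator: 1 if *i* is an annotated biomarker, else 0;
* interaction inference: upper-tail hypergeometric enrichment of *i*'s
  direct interaction neighbors in the disorder's biomarkers, scored
  −ln *p*;
* pathway enrichment: each pathway map *P* gets *s\_P* = −ln *p* for
  biomarker over-representation; *i* accumulates Σ *s\_P* over the maps
  containing it;
* consortium pathway count: number of curated disease-area pathways on
  which *i* appears (disorder-independent);
* linear-pathway ratio: of the ligand-to-transcription-factor signaling
  chains containing *i*, the fraction that also contain a biomarker.

**Network-based (seeded by the pooled disorder biomarkers):**

* network propagation, the fixed point of
  F\_t = α W′ F\_{t−1} + (1−α) Y with the symmetric degree normalization
  W′ = D^{−1/2} A D^{−1/2} and α = 0.8;
* random walk with restart, p\_t = (1−r) W p\_{t−1} + r p⁰ with
  column-stochastic W and restart r = 0.75;
* interconnectivity, ICN(i,j) = (2 e(i,j) + n(i,j)) / √(deg i · deg j)
  averaged over the seed set;
* neighborhood smoothing, FC′\_i = α FC\_i + (1−α) mean of neighbor levels,
  α = 0.5.

**Disease similarity:** candidate diseases are ranked by
−log₁₀ *p* of the hypergeometric overlap between their target sets and the
gold-standard target set; the top 15 sharing ≥ 3 targets each contribute a
binary is-a-target-there feature.

**Integration:** positive controls are the proteins that are drug targets
of ≥ 2 of the 13 disorders. A PLS classifier is trained inside a balanced
nested cross-validation (5 outer × 5 inner folds, 10 repeats, negatives
freshly sampled at 10× the positives in every outer fold). Recursive
feature elimination in the inner loop drops the least informative feature
one at a time and keeps the feature count minimizing held-out prediction
error (1 − AUC). Each outer-fold model scores the whole proteome; proteins
are only ever scored by models that did not train on them. Scores become
genome-wide ranks per repeat, and ranks are averaged across repeats into
the final prioritization. Each feature's selection count (0–50) measures
its importance.

Exact hypergeometric enrichment utilities (`hypergeom_tail()`,
`enrich_terms()`) support functional annotation of top-ranked target sets.

## Worked example

```r
library(mclprio)

gen <- generate_kb(synth_config())   # benchmark conditions, seed 7
kb  <- gen$kb
kb
#> <mcl_kb>
#>   proteins:           2000
#>   interactions:       5994
#>   pathway maps:       150
#>   consortium maps:    40
#>   linear pathways:    200
#>   disorders:          13
#>   similar diseases:   25

positives <- define_positive_controls(kb)   # 50 multi-indication targets
features  <- build_feature_matrix(kb)       # 2000 proteins x 72 features
result    <- nested_cv_prioritize(features, positives, cv_config(rng_seed = 7))

glance(result)
#> # A tibble: 1 × 7
#>   n_proteins n_features n_positives repeats outer_folds recovery_auc
#>        <int>      <int>       <int>   <int>       <int>        <dbl>
#> 1       2000         72          50      10           5        0.949

head(tidy(result), 5)
#> # A tibble: 5 × 4
#>   protein_id final_score is_positive  rank
#>        <int>       <dbl> <lgl>       <int>
#> 1          6         1.4 TRUE            1
#> 2          5         3.5 TRUE            2
#> 3          2         4.1 TRUE            3
#> 4         13         7.2 TRUE            4
#> 5        502         9.9 TRUE            5
```

The cross-validated recovery AUC of 0.949 says the integrated model ranks
planted multi-indication targets far above background; `final_score` is the
average genome-wide rank across the 10 repeats (low = best), and here the
five best-ranked proteins are all true planted targets. Feature selection
counts identify which evidence channels carried the signal (the
similar-disease binaries and network diffusion scores dominate on synthetic
data):

```r
dplyr::slice_max(result$selection_counts, count, n = 3)
#> # A tibble: 3 × 2
#>   feature                       count
#>   <chr>                         <dbl>
#> 1 sim.atherosclerosis              50
#> 2 sim.mild_cognitive_impairment    50
#> 3 sim.traumatic_brain_injury       50

autoplot(result)          # prediction-error-vs-features curve
plot_roc(result$scores, positives)
```

`run_pipeline(out_dir)` chains the whole thing — simulate, score,
integrate, evaluate, annotate — and writes TSV/JSON artifacts plus a
manifest with config hashes for reproducibility.

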