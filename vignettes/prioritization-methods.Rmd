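---
title: "Multi-evidence target prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence target prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the scoring
models and their assumptions, every tunable parameter with its default and
rationale, what the synthetic knowledge base does and does not emulate, the
numerical conventions, and the design decisions that were genuinely open.

## The prioritization problem

Thirteen mental disorders tied to the mesocorticolimbic reward circuit are
treated as one therapeutic group. Given a curated knowledge base — a
protein interactome with effect/mechanism labels, pathway maps, linear
signaling chains, per-disorder biomarker and drug-target annotations, and
candidate similar-disease target sets — every protein in the universe is
scored by complementary evidence channels, and the channels are combined by
a supervised integration step trained on the proteins already known to be
drug targets for at least two of the disorders (the *positive controls*).
The output is a genome-wide ranking: averaged rank is the final score, low
is best.

The working assumption throughout is *guilt by association*: proteins that
are topologically and functionally close to the established biomarkers of
the disorder group are more plausible targets. Every evidence channel
operationalizes "close" differently, which is exactly why integration with
learned weights beats any single channel.

## Knowledge-based scores

Four scores are computed per disorder, one globally:

* **Biomarker indicator** — 1 if the protein is an annotated biomarker of
  the disorder. The crudest but most direct channel.
* **Interaction inference** — the protein's direct interaction neighbors
  are tested for biomarker over-representation with an upper-tail
  hypergeometric test against the full protein universe; the score is
  −ln *p*. Isolated proteins score 0: no neighborhood, no neighborhood
  evidence.
* **Pathway enrichment** — each pathway map gets a score
  *s* = −ln *p* for biomarker over-representation; a protein sums the
  scores of the maps containing it. Summation (rather than max or mean)
  deliberately rewards proteins recurring across many disease-relevant
  maps.
* **Linear-pathway ratio** — among ligand-to-transcription-factor chains
  containing the protein, the fraction that also carry at least one
  biomarker. The 0/0 case (protein on no chain) is defined as 0: absence
  from the chain collection is absence of evidence, not evidence of
  irrelevance. The ratio lies in [0, 1] by construction.
* **Consortium pathway count** — the number of curated disease-area
  pathways on which the protein appears; disorder-independent, capturing
  how central the protein is to nervous-system biology at large.

Two conventions apply to all log-transformed p-values and were genuinely
open choices:

* *Natural log.* The log base only rescales a feature column and the
  downstream classifier standardizes columns anyway, so the choice is
  cosmetic; natural log is used everywhere and stated here once.
* *One-sided upper tail,* P(X ≥ observed). This is the convention under
  which the published molecular-function enrichment worked examples
  reproduce exactly (see the enrichment section below), so the same kernel
  is used for all enrichment computations in the package.
* *Universe.* The background for these tests is the full protein universe
  of the knowledge base. An annotated-only universe is equally defensible;
  it is what the published enrichment tables use (N = 15,288 annotated
  genes), and `enrich_terms()` follows that convention because its inputs
  dictate it, while the score channels use the full universe because their
  feature semantics are genome-wide.

p-values are clamped below at 1e−300 before logging, so scores are finite
and non-negative; p near 1 clamps to a score of exactly 0.

## Network scores

All four operate on the undirected simple interactome: effect and
mechanism labels are retained as edge metadata but the scoring formulas are
orientation-free, so direction is deliberately ignored. Isolated proteins
stay in the graph — prioritization is genome-wide, and a protein without
interactions can still earn knowledge or similarity scores.

* **Network propagation** (global): iterate
  F_t = α·W′·F_{t−1} + (1−α)·Y to its fixed point, Y the 0/1 seed
  indicator. W′ is the *symmetric* degree normalization
  a_ij/√(deg i · deg j), the standard reading of degree-compensated
  diffusion; α = 0.8 weights how far flow spreads before the prior
  re-injects.
* **Random walk with restart** (global): p_t = (1−r)·W·p_{t−1} + r·p⁰
  with *column-stochastic* W = a_ij/deg j and restart r = 0.75; p⁰ is
  uniform over the seeds. The two methods intentionally use different
  normalizations — one symmetric, one stochastic — because they model
  different processes (flow diffusion vs. a Markov walker). A degree-zero
  column is made self-absorbing so W stays stochastic; the converged
  vector sums to 1 within 1e−10 by construction and the suite asserts it.
* **Interconnectivity** (local):
  ICN(i,j) = (2·e(i,j) + n(i,j)) / √(deg i · deg j), averaged over the
  seed set. The square-root degree normalization mirrors the propagation
  normalization and is recorded here as a deliberate convention. Pairs
  involving a degree-zero node contribute 0.
* **Neighborhood smoothing** (local):
  FC′_i = α·FC_i + (1−α)·mean(FC over neighbors), α = 0.5, with seed
  level 1 on biomarkers. A degree-0 node keeps only its self term α·FC_i
  (its neighbor mean is undefined; dropping the term entirely would make
  an isolated biomarker score 0, which contradicts the self-weight
  semantics). A constant field is a fixed point on any graph without
  isolated nodes.

Convergence for the two iterative methods: max-norm change below
tol = 1e−8 (configurable), hard cap 1000 iterations with an explicit error
carrying the iteration count. Both fixed points equal direct linear solves
— F = (1−α)(I−αW′)⁻¹Y and p = r(I−(1−r)W)⁻¹p⁰ — and the test suite
verifies the iterative and closed-form routes agree within 1e−6 on random
graphs up to 200 nodes.

**Seeding.** The default seed set pools the biomarkers of all disorders:
the disorder group is treated as one entity, which is the premise of the
whole analysis. Per-disorder seeding (one network-score block per
disorder) is available via `build_feature_matrix(per_disorder_network =
TRUE)` for users who want disorder-resolved network features; pooled is
the default because it keeps the feature count near the published scale
(72 columns at 13 disorders) and avoids 13 strongly collinear blocks.

## Disease similarity

Similarity between two gene sets in a universe of size N is
−log₁₀ P(X ≥ |A∩B|) under the hypergeometric null — symmetric, monotone in
overlap, clamped at 0. Candidate diseases are ranked against a reference
set and the top k = 15 among those sharing at least 3 genes with the
reference are selected; each contributes a binary is-a-target feature
column.

The reference defaults to the pooled positive-control target set (the
gold-standard training labels), which is what the ≥ 3-shared-targets rule
is stated against. Whether to overlap biomarker sets or target sets is
genuinely ambiguous in the field; the package resolves it by making the
reference an explicit argument (`select_similar_diseases(candidates,
reference, ...)`), so either convention is one call away, and the wrapper
`score_similarity()` applies the target-set default.

Ties in similarity break lexicographically by disease name, making
selection deterministic.

## Integration

* **Labels.** Positives = proteins in ≥ 2 disorders' target sets, any
  development status (validated, candidate and exploratory all count; the
  multi-indication requirement is the quality filter, and status-filtering
  would shrink an already small label set). Negatives = a fresh uniform
  sample of non-positives, 10 per positive, drawn independently in every
  outer fold so the arbitrariness of the choice averages out.
* **Model.** PLS regression on standardized features, used as a binary
  classifier, 2 latent components by default. Two components is the
  smallest count that can capture one dominant evidence direction plus one
  correction; the setting is exposed in `cv_config()`. The PLS1/NIPALS
  kernel is implemented in-package for speed (the elimination loop refits
  it thousands of times) and is validated against an independent PLS
  implementation in the test suite.
* **Feature standardization** uses whole-universe column means and
  standard deviations. This is unsupervised — no label information leaks —
  and keeps the genome-wide scoring scale identical across folds. Constant
  columns are dropped with a warning before modeling.
* **Nested cross-validation.** 5 outer × 5 inner stratified folds, 10
  repeats. The inner loop runs recursive feature elimination: drop the
  feature with the smallest mean |PLS coefficient| across inner folds, one
  per step, down to the component count, recording held-out prediction
  error at every feature count. *Prediction error* is 1 − AUC on the inner
  validation folds: threshold-free and consistent with the final
  evaluation metric (a misclassification-rate alternative is available in
  `cv_config()`). The feature set minimizing error wins; ties go to fewer
  features.
* **Genome-wide scoring without leakage.** Each outer-fold model scores
  the entire proteome, but a protein's per-repeat score averages only the
  fold models that did not train on it. Unlabeled proteins are scored by
  all five models; labeled ones by the models where they were held out. A
  protein sampled as a negative in every fold of a repeat (rare) falls
  back to the all-model average. The label-shuffle canary in the test
  suite (pseudo-positives at the same size, AUC ≈ 0.5 over ten seeds) is
  the operational proof that no leakage path exists.
* **Rank aggregation.** Scores become genome-wide ranks within each
  repeat (ties get average ranks — deterministic and order-independent),
  and ranks are averaged across repeats. Selection counts per feature
  accumulate over the 50 elimination rounds (10 repeats × 5 outer folds).

Determinism: one seed in `cv_config()` governs fold splits and negative
sampling; identical inputs and seed give byte-identical ranked outputs.

## Enrichment statistics

`hypergeom_tail(r, R, n, N)` is the shared kernel:
p = Σ C(n,x)·C(N−n,R−x)/C(N,R) for x from r to min(R,n), evaluated via
R's `phyper` with a log-scale option that stays finite for universes up to
10⁶ even where the tail underflows doubles. The upper-tail convention was
validated against two independently hand-checkable published rows — the
r = n single-term tail, which has the closed form
(R·(R−1)·(R−2))/(N·(N−1)·(N−2)) at r = n = 3 — and the package reproduces
all 39 published molecular-function rows to three significant figures from
their printed (r, R, n, N) inputs. No multiple-testing correction is
applied by default (published tables print raw p); `enrich_terms(bh =
TRUE)` adds a Benjamini–Hochberg column.

`enrich_terms()` treats annotation sets as flat gene sets (no ontology
graph propagation) and uses the genes-with-≥1-annotation universe, which
is what makes printed N values like 15,288 reproducible as inputs.

## The synthetic knowledge base

The generator emulates the statistical structure the analysis assumes,
with planted ground truth for recovery benchmarking:

* a **scale-free interactome** grown by preferential attachment (3 edges
  per new node → ~6,000 edges at 2,000 proteins; protein interaction
  networks are approximately scale-free, and the heavy tail is asserted in
  tests: max degree ≥ 5× median);
* **disorder modules**: 60-protein BFS balls around random roots, one per
  disorder — connected neighborhoods in which that disorder's biology
  concentrates; modules may overlap, as comorbid disorders' biology does;
* **biomarkers**: 35% of each module plus 4 background proteins
  (annotation noise);
* **planted targets**: 50 proteins, each placed in a home module and
  annotated for 2–4 disorders; all other targets are globally unique, so
  the ≥ 2-indication positive-control set equals the planted set *by
  construction* and the count is exact;
* **pathway collections**: 150 maps of 10–60 members, 60% drawn from a
  random disorder module and the rest background; 40 consortium maps at a
  50% mixing rate;
* **linear chains**: 200 simple random-walk paths of length 4–10,
  endpoints flagged as the ligand/receptor and transcription-factor ends;
* **similar diseases**: 15 real candidates whose target sets draw 5–15
  genes from the disorder targets (at least 3 from the planted set, so the
  ≥ 3-shared selection rule is always exercisable), plus 10 decoy diseases
  sharing ≤ 2 — the selection rule must actually reject something.

Scale and signal defaults are the package's benchmark conditions: 2,000
proteins keeps a full nested-cross-validation run under a minute while
leaving a 40:1 background-to-positive ratio, and the in-module enrichment
rates are set where a curated disease knowledge base plausibly sits —
strong but noisy clustering of annotations around disease biology. No
public measurement of how strongly true targets cluster near biomarkers in
commercial knowledge bases exists, so these rates are declared arbitrary
rather than estimated; they are fixed defaults, not fitted quantities.

What the generator does **not** emulate: curation biases (well-studied
proteins accrue more annotations of every kind — a major confounder in
real knowledge bases), protein complexes and families as network objects,
edge-direction semantics, annotation cross-correlations beyond shared
module origin, and the true scale (~18,500 proteins, 1,300+ pathway maps).
A recovery AUC near 0.95 on synthetic data therefore demonstrates that the
pipeline's machinery is correct and leak-free — not that comparable
accuracy is attainable on any particular real knowledge base.

## Problem sizes and runtime

The test suite and the acceptance script run the full benchmark (2,000
proteins, 13 disorders, 72 features, 10 repeats ≈ 50 feature-selection
rounds of ~70 elimination steps × 5 inner folds) in well under a minute,
and the label-shuffle null at 1 repeat per seed. These sizes are the
package's chosen benchmark conditions; everything is configurable upward
through `synth_config()` and `cv_config()`.

## Known limitations

* The evidence channels are only as good as the knowledge base; on real
  data the biomarker indicator and similarity binaries inherit curation
  bias directly, and the integration step will happily learn that bias.
* PLS is the only learner, by design — the integration is deliberately
  linear and interpretable (selection counts, coefficients); nonlinear
  learners are out of scope.
* The similarity module exposes which gene-set type to overlap, but the
  package does not attempt ontology-aware disease similarity.
* Fold enrichment of a top-K list uses the plain observed/expected
  formula; published fold-enrichment figures computed by other (sometimes
  unstated) conventions will not necessarily match it, and the package
  reports its own formula's value rather than asserting agreement.
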