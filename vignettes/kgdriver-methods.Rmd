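---
title: "Driver gene discovery with dynamic-mapping knowledge-graph embeddings"
author: "kgdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver gene discovery with dynamic-mapping knowledge-graph embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgdriver)
```

## The problem

Cancer driver genes are usually prioritised from DNA aberrations and
gene-interaction networks alone, yet recurrent RNA alterations carry
complementary evidence, and in breast cancer the relevant question is
often not just *whether* a gene drives tumours but *in which intrinsic
subtype* (Luminal A/B, HER2-enriched, Triple-negative, Normal-like) it
does so.  Integrating these sources is awkward because their formats and
statistical behaviour differ: per-sample variant calls, a continuous
expression matrix, an undirected interaction network, categorical sample
annotations and a curated driver list.

`kgdriver` resolves the format heterogeneity by *splicing* everything
into one knowledge graph of `(head, relation, tail)` facts:

| fact | head | relation | tail |
|---|---|---|---|
| DNA aberration | sample | one of 17 variant classes | gene |
| RNA aberration | sample | `over_expression` / `under_expression` | gene |
| interaction | gene | `interaction` | gene |
| synonym | gene | `synonym` | gene |
| subtype | sample | `belongs_to` | subtype |
| supervision | gene | `is_driver` | the single node `D` |

Keeping each aberration *type* as its own relation (rather than a
generic "mutated" edge) is deliberate: the type identity is information,
and the ablation operator `ablate_confuse_types()` exists precisely to
measure its contribution.

## The embedding model

The *fusing* step learns a vector `v_x` for every entity and relation so
that true facts are short translations.  The recovery loss of a fact
under relation `r` is

$$\mathrm{Dis}^{(r)}(h, t) = \lVert \mathrm{map}_r(v_h) + v_r -
\mathrm{map}_r(v_t) \rVert_p ,$$

with four nested choices of the mapping into relation space:

* **nomap** — identity (the TransE translation model);
* **planemap** — projection on a relation hyperplane with unit normal
  $\omega_r$: $v - (\omega_r^\top v)\,\omega_r$ (TransH);
* **staticmap** — a full relation matrix $M_r v$ (TransR);
* **dynmap** (default) — a *dynamic*, relation- and entity-specific
  rank-one-plus-identity map $(\omega_r \omega_e^\top + I)\, v_e$
  (TransD).  Each triplet thus gets its own projection, which is what
  lets one gene behave differently under `missense mutation`,
  `interaction` and `is_driver` relations.

The metric defaults to L1 for its sparsity-inducing behaviour; L2 is
available for ablation.  The three simpler variants are exact special
cases of dynmap (set $\omega = 0$, or $M_r = I$), which the test suite
checks to machine precision — a useful guard that all four scorers share
one consistent implementation.

### Training objective

Minimising the summed recovery loss of observed triplets alone is
degenerate: the all-zero embedding is a global optimum.  We therefore
train the standard margin-ranking surrogate of the translational-model
family,

$$\sum_{(h,r,t) \in \mathcal{G}} \sum_{(h',r,t') \notin \mathcal{G}}
\max\{0,\ \gamma + \mathrm{Dis}^{(r)}(h,t) - \mathrm{Dis}^{(r)}(h',t')\},$$

with corrupted triplets drawn by replacing the head or tail (uniform
side choice among feasible sides) with a random entity of the same kind,
rejecting corruptions that are themselves graph members (*filtered*
sampling).  Optimisation is mini-batch Adam.  Entity vectors are
projected onto the unit ball after every update and hyperplane normals
are renormalised — the usual collapse guards.

### Numerical choices

* **Initialisation**: coordinates uniform in $[-6/\sqrt{d}, 6/\sqrt{d}]$.
  Dynmap *entity* projections start at zero, so training starts exactly
  at the nomap reduction point; dynmap *relation* projections start
  random.  Starting both at zero looks natural but is a stationary
  point: every gradient of $\omega_e$ carries a factor $\omega_r$ and
  vice versa, so an all-zero start never moves.  (For planemap the
  normals start as random unit vectors.)
* **L1 subgradient at 0** is taken as 0; a finite-difference check
  (`check_gradients()`) validates all eight variant × metric gradient
  paths away from the kinks to ≤ 1e-4 relative error.
* **Tail iterate averaging**: the returned parameters are the average of
  the final 25% of epochs.  Stochastic negative sampling leaves the
  final iterate wobbling around its basin; averaging damps that noise,
  which matters here because downstream gene *rankings* are read off a
  single model.  (Averaged entity vectors stay inside the unit ball by
  convexity; planemap normals are renormalised once after averaging.)
* **Determinism**: initialisation, batch order and negative sampling all
  draw from R's RNG, and every string sort uses C-locale (radix)
  collation, so a seed fixes every downstream artifact byte-for-byte
  regardless of platform locale.

### Defaults

Embedding dimension 50, 350 epochs, batch 512, Adam step 1e-3, margin 2,
5 negatives per positive, tail averaging 0.25.  The margin and
negative-sample count are larger than the classical single-negative,
margin-1 recipe: on graphs of this size (a few thousand triplets, a few
hundred entities) a single corrupted sample per fact gives the ranking
loss very little contrast per epoch, so several corruptions and a wider
margin are used to sharpen the learned separation.  All values are
arguments of `kge_fit()`.

## Discovery and subtype indication

Candidate genes are ranked by `Dis(gene, is_driver, D)` — genes whose
supervision fact is "recovered" with a short translation are the
strongest candidates — with lexicographic tie-breaking for
reproducibility.  Subtype-specificity is indicated per gene as the
arg-min over `Dis(gene, belongs_to, S)` across subtypes.  There is no
score threshold: the contract is the full ranking, and the package
reports a subtype indication for every ranked gene.

## Evaluation

Known-driver supervision is the only labelled signal, so evaluation uses
5-fold cross-validation over the driver triplets: each fold's
`is_driver` facts are removed from the training graph, a model is
trained on the remainder, and the held-out drivers are scored by that
model.  An assertion inside `cv_driver_discovery()` verifies the
held-out facts are really absent from every training graph.

Concatenating scores across folds requires care because each fold
trains a different model with its own score scale, and a concatenation
protocol must decide how non-benchmark genes are scored.  We score
non-benchmark genes under **every** fold model and average (they are
supervision-free in all folds); a `negatives_from = "first_fold"` switch
gives the single-model alternative.  To remove the residual scale
mismatch between a single fold model (positives) and a five-model
average (negatives), `cv_driver_discovery(concatenate = "percentile")`
(the default) converts each fold's scores to within-fold percentiles
before concatenation; `concatenate = "raw"` keeps raw recovery losses.
Percentile concatenation is a rank transform within each model, so it
cannot manufacture signal that a fold model does not already have — it
only makes scores from different models commensurable.

A held-out driver is still scored by a *single* model while every
negative is an average of five, leaving the positives with the larger
score variance.  `cv_driver_discovery()` therefore trains an `ensemble`
(default 3) of models per fold — same training graph, hence the same
leakage guarantee, different training seeds — and averages each gene's
within-fold percentiles over the ensemble, which puts positives and
negatives on comparable noise levels.

ROC curves sweep a threshold over the concatenated scores (lower =
predicted driver); TPR is the recovered fraction of benchmark drivers,
FPR the called fraction of the remaining genes.  The trapezoidal area
equals the Mann–Whitney statistic with ties counted one half, which the
tests verify against an exhaustive pairwise oracle and against pROC.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the method
assumes, with every input table and a ground-truth ledger emitted from a
single seed:

* samples drawn uniformly over `n_subtypes` subtypes; planted drivers
  assigned home subtypes round-robin;
* a driver is DNA-aberrant at rate `driver_mut_rate` (default 0.35)
  *within its home subtype*; its rate elsewhere is derived so that the
  expected fraction of its aberrant samples confined to the home subtype
  equals `subtype_exclusivity` (default 0.8).  The derivation is the
  feasibility-respecting reading of these two parameters: a cohort-wide
  rate of 0.35 cannot put 80% of aberrant samples into a subtype holding
  ~20% of a uniformly-assigned cohort (it would need a per-sample
  probability of 1.4), whereas the home-rate reading realises the
  requested exclusivity exactly in expectation;
* passengers aberrant uniformly at 0.03; variant classes uniform over
  the 17-class vocabulary (no class carries extra semantics);
* expression is N(0,1) baseline with a ±4 shift in mutated driver cells
  with probability `rna_coupling` = 0.5 (direction equiprobable); RNA
  aberrations are then *called* from the emitted matrix by the same
  robust z-rule the pipeline uses (|z| ≥ 2 with MAD scaling), so the
  RNA layer carries realistic false calls (~4.6% of baseline cells) as
  well as the planted signal;
* interactions are Bernoulli per gene pair, 0.3 among drivers versus
  0.01 background, mimicking the dense interconnection of driver genes
  in curated networks;
* 60% of planted drivers are revealed as the "known" list; the hidden
  rest can only be found from data structure.

What the generator does **not** emulate: real mutation spectra and
hotspots, expression covariance between genes, batch effects, network
degree heterogeneity beyond the driver/background split, or cohort sizes
of real tumour studies.  Passing recovery tests on these cohorts shows
the machinery extracts exactly the kinds of signal the generator plants
— not that it would reach the same operating point on real data.

## Problem sizes used in the checks

The automated checks run the full pipeline at the generator defaults
(200 samples × 300 genes, 20 planted drivers, 5 subtypes, ~5,000–6,000
triplets) with 5-fold cross-validation over 5 replicate seeds for the
dynamic-mapping and plain-translation variants, plus smaller cohorts
(40 × 60) for the structural and determinism tests.  These sizes were
chosen so a replicate trains in seconds on one CPU while keeping
~300-gene rankings statistically meaningful.

## Known limitations

* `Dis` scores are ranking devices, not calibrated probabilities.
* Subtype indication has no benchmark even in the real-data setting; the
  synthetic check (assignment accuracy ≥ 2× chance on revealed drivers)
  is a weak-consistency test only.
* The trainer is single-threaded; graphs of millions of triplets would
  need batching beyond what this package targets.
* Synonym facts are kept as relations; entity merging (normalising
  synonymous symbols to one node) is deliberately out of scope.
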