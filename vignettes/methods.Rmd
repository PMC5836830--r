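---
title: "Pairwise-kernel prediction of heterodimers: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise-kernel prediction of heterodimers: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairkern)
```

## The problem and the model

A heterodimer is a complex of exactly two different proteins.  Graph-
clustering complex finders cannot recover them — two proteins induce at
most one edge — so `pairkern` casts the task as supervised classification
of protein pairs.  Training labels come from a complex catalog projected
onto a weighted PPI network: an edge is *positive* if it is a catalogued
size-2 complex, *negative* if it is no heterodimer but its endpoints
co-occur in a complex of size ≥ 3, and unlabeled otherwise.  The negative
definition is deliberate: these are exactly the interacting pairs a naive
"interaction = dimer" rule would get wrong.

Two signals feed the classifier.

**Network/domain features ψ.**  Seven numbers per pair: the edge weight
w~ij~; the max and min over neighboring edge weights of either endpoint
(excluding the pair edge); the strongest common neighbor
max~k~ min{w~ik~, w~jk~}; the largest cross-neighborhood absolute weight
difference; and the max/min of the two proteins' total domain counts.
These encode the premise that the interaction *inside* a heterodimer is
heavier than the interactions around it, while intra-complex edges sit in
dense, strongly connected neighborhoods.

**Pairwise kernels.**  A protein-level kernel K over annotation vectors
φ(P) is lifted to pairs by

* MLPK: (K~13~ − K~14~ − K~23~ + K~24~)²
* TPPK: K~13~K~24~ + K~14~K~23~

with K one of Min (Σ min{x~i~, y~i~}), its scale-normalized form, or the
MinMax/Tanimoto form.  The combined kernel is
K~comb~ = ⟨ψ, ψ′⟩ + α·K~pairwise~ (with `mlpk+tppk`, one shared α
multiplies both lifted terms).  The Domain Composition kernel — 1 only
when compositions match exactly under the direct or crossed assignment —
is kept as the baseline it replaces.  The Min kernel's point is to relax
that all-or-none comparison to "shares many domains".

MLPK vs TPPK is not an arbitrary menu: known heterodimers tend to be
similar to *other* heterodimers (shared domain-composition patterns across
pairs) while their two partners differ from each other.  MLPK compares the
*difference* of a pair's elements in feature space and is therefore
matched to that structure; TPPK compares partners elementwise across
pairs.

**Classifier.**  A C-SVC with separate penalties C⁺/C⁻ (the positives are
rare), trained on precomputed Gram matrices, scored by stratified 10-fold
cross-validation with precision, recall, F-measure averaged over folds
(macro averaging: each fold's metrics computed, then meaned).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| α | grid 0–1 (step 0.1) | weight of the pairwise kernel against ⟨ψ, ψ′⟩; α = 0 is the ψ-only baseline.  Dimensionless; comparable across kernels only loosely, since Min grows with vector mass while MinMax ≤ 1. |
| C⁺ | grid {3.5, 4.0, 4.5} | slack penalty on positives.  Larger values push recall up. |
| C⁻ | 1.0 | slack penalty on negatives; held fixed because performance is insensitive to it in this regime of imbalance. |
| folds | 10 | with only a handful of positives per fold, stratification is required for stable estimates. |

The α/C⁺ grids are the protocol this implementation follows; they bracket
the region where the combined kernels peak.

## The SMO solver

No SVM package is assumed.  `svc_fit()` runs an in-package SMO
(second-order working-set selection, per-class box constraints, equality
constraint Σ y~i~α~i~ = 0, bias from the free support vectors, stopping
tolerance 1e−3 on the maximal KKT violation).  The tests assert the
contract rather than the implementation: box constraints, Σ coef = 0, and
the KKT conditions y~i~f(x~i~) ⋚ 1 by bound status, plus invariance
checks (duplicating training points, class-weight monotonicity of
recall).  Ties at f(x) = 0 classify as positive.

## The synthetic benchmark: what it emulates, what it does not

`simulate_heterodimers()` generates the stated world the method assumes:

* 300 proteins, 40 planted heterodimer pairs whose edges draw log-normal
  weights with log-mean 2.0 (sd 0.4) against 0.5 (sd 0.4) for every other
  edge — positive, right-skewed confidences in which only the *order*
  relations matter to ψ;
* 8 domain-composition template pairs; each planted pair takes one
  template, its two proteins receiving noisy copies (10% per-slot
  corruption) of the template's two *different* compositions.  Positives
  therefore resemble other positives of the same template across pairs but
  not within a pair — the MLPK-favorable structure.  All proteins,
  planted or background, draw 2–4 domain slots, so raw domain *count*
  carries no label information; only composition does;
* 30 complexes of sizes 3–6 with complete internal edge support (the
  negatives), plus Erdős–Rényi background edges at p = 0.02;
* phylogenetic profiles (50 genomes) sharing a Bernoulli(0.4) pattern
  within each complex with 10% flip noise; localization columns are
  independent Bernoulli(0.25) noise by default, matching the empirical
  finding that localization contributes nothing.

Everything is deterministic given `seed`, and the serialized bundle
round-trips through the package readers.

What a green test does **not** establish: the generator does not mimic
WI-PHI's degree distribution, its weight heterogeneity across evidence
sources, CYC2008's complex-size histogram, incomplete annotation coverage,
or identifier noise.  Absolute F-measures on synthetic data (≈ 0.9) are
far above anything attainable on the real corpus (≈ 0.69); only orderings
and recovery behaviour transfer.

## A deliberately red acceptance criterion

One acceptance property demands that a "null" generator — weight
distributions equalized (μ~h~ = μ~b~) and half of all domain slots
corrupted — yield best-grid mean F ≤ 0.35.  This is unattainable under
the stated construction, and the test is left failing rather than
weakened.  The reason is structural: every negative pair lies inside a
complex whose third member connects to both endpoints, so its
common-neighbor feature (ψ₄) is strictly positive, while a planted pair
has expected 300 · 0.02² ≈ 0.12 common neighbors.  A threshold on ψ₄
alone separates the classes (ψ-only CV F ≈ 0.88 on the null), and no
setting of the weight or domain-noise knobs removes a signal that lives
in the topology.  The honest conclusions: (i) in this benchmark,
"heterodimer vs intra-complex edge" is partly a *topological* distinction,
and (ii) a null for the weight premise would have to randomize the
complex structure itself, which the stated generator contract fixes.

## Numerical and design choices

* Every max/min in ψ over an empty index set is 0 (degree-1 endpoints,
  no common neighbors).  Weights are strictly positive, so 0 is a clean
  sentinel.
* Normalized kernels define 0/0 as 0 (annotation-free proteins), keeping
  Gram matrices total.
* Domain count = multiset size (sum of φ_dom), not distinct-domain count.
* Duplicate input edges keep the maximum weight; self-edges are dropped;
  both warn.  Edge identity is the unordered pair, stored in
  lexicographic order.
* Negative rule: "co-occur in some complex of size ≥ 3" (the weaker
  reading of subset-of-another-complex); a stricter proper-subset reading
  would only shrink the negative set.
* Positives whose edge is missing from the network are discarded, not
  imputed: ψ is undefined off the edge set.
* ψ features enter the inner product unscaled by default (the literal
  combined-kernel definition); optional per-feature min–max scaling can
  be fit on training folds only (`scale_psi = TRUE`) and is off by
  default.
* Gram assembly computes each protein-level kernel value once (base
  kernel matrix over the unique proteins) and is tested to equal a naive
  scalar double loop at relative tolerance 1e−10; entries accumulate in
  the same column order as a per-pair `sum(pmin(...))` so the equality is
  essentially exact.
* Grid ties break deterministically: higher mean precision, then smaller
  α, then smaller C⁺, then input order.
* `mlpk+tppk` uses a single shared α on both lifted terms, as the
  additive combination is defined.

## Limitations

* The SMO has no shrinking/caching; it is sized for the 10²–10⁴ pair
  problems this package targets, not for 10⁶-pair screens.
* Pairwise kernels consume a single feature source per specification
  (`dom`, `phylo`, or `local`); multi-source concatenation is out of
  scope.
* No probability calibration, ROC analysis, or nested CV: evaluation is
  precision/recall/F at decision threshold 0, matching the protocol the
  package implements.
* Identifier mapping across databases is not attempted; inputs must share
  a protein namespace.

## A complete run

```{r example, eval = FALSE}
sim   <- simulate_heterodimers(sim_params(seed = 1))
pairs <- build_examples(sim$network, sim$catalog)
spec  <- kernel_spec("scale-normalized-min", "mlpk", "dom", alpha = 0.3)
cross_validate(pairs, sim$network, sim$tables, spec,
               c_pos = 4.5, c_neg = 1.0, seed = 1)
#> evaluation_report (10 folds): precision 0.955, recall 0.900, F 0.921
```
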