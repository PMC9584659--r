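---
title: "Hybrid immune feature selection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid immune feature selection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfia)
```

## The problem

Expression datasets routinely carry thousands to tens of thousands of
features for only tens of samples per class. Classifiers built on the raw
matrix are swamped by uninformative dimensions, and exhaustive subset
search is hopeless at $2^q$ candidates. `hfia` implements a two-stage
hybrid: a cheap univariate *filter* cuts the space to a fixed-size
candidate set, then a *wrapper* — an improved clonal-selection immune
algorithm — searches that set for a minimal subset with high
cross-validated accuracy.

## Stage 1: the Fisher filter

For feature $i$, with class sizes $n_k$, per-class means $u_{ki}$,
per-class population variances $\sigma^2_{ki}$ and overall mean $u_i$,

$$F_i \;=\; \frac{\sum_{k=1}^{c} n_k\,(u_{ki}-u_i)^2}
                 {\sum_{k=1}^{c} n_k\,\sigma^2_{ki}},$$

the ratio of between-class to within-class dispersion. `fisher_scores()`
computes all $q$ scores vectorised; `select_top_k()` keeps the top
`fisher_k` (default 200), breaking ties at the cut rank by ascending
column index so the retained set is deterministic.

Two conventions are deliberate:

* **Population variances** (divide by $n_k$). The score weights each
  class by $n_k$ and must tolerate singleton classes, for which the
  unbiased variance is undefined.
* **Floored denominator.** A feature with zero within-class variance but
  distinct class means would score infinity; the denominator is floored
  at $10^{-12}$, which keeps scores finite, totally ordered, and
  serialisable, while still ranking such features above every
  finite-variance feature. A constant feature scores exactly 0.

Scores are computed once, on the full dataset, before the wrapper runs.
This mirrors the two-stage design but means the filter sees the same
samples later used for cross-validation inside the search — a selection
bias shared by all such pipelines; we note it rather than correct it.

## Stage 2: the immune search

A candidate subset is an *antibody*: a binary vector over the $m$
retained features, bit 1 meaning "selected". Its quality is the fitness

$$\mathrm{fitness} \;=\; \omega\,E_r + (1-\omega)\,\frac{p}{q},$$

where $E_r$ is the KNN cross-validation error of the masked matrix, $p$
the active-gene count, and $q$ the size of the evaluated space (the
filtered space, $m$). Lower is better; *affinity* is its negation.
$\omega$ defaults to 0.99 — almost all weight on accuracy, with the size
term breaking ties toward smaller subsets.

One iteration of the loop, at iteration $t$ of $T_{\max}$:

1. **Schedule.** $\delta = 0.5 - t/T_{\max}$ (0.5 down to $-0.5$) and
   $\theta = t/T_{\max}$ (0 up to 1).
2. **Select.** The $n = \mathrm{round}(c_r N)$ lowest-fitness antibodies,
   ascending (ties: fewer genes, then position).
3. **Clone.** Rank $i$ contributes $\mathrm{round}(\beta N / i)$
   independent copies (minimum 1, halves away from zero) — the classical
   clonal-selection allocation.
4. **Mutate.** Every locus of every clone draws a standard Cauchy
   number; loci whose draw exceeds $\delta$ mutate, so falling $\delta$
   recruits more loci over time. While the best fitness improved in the
   previous iteration the operator is *lethal*: active mutation loci are
   switched off and inactive ones left alone, a one-way pressure toward
   smaller subsets. On stagnation it reverts to plain bit-flips to
   restore exploration.
5. **Update.** $N$ fresh antibodies are generated by the same Cauchy
   threshold rule at threshold $\eta + \theta$ — newcomers grow sparser
   as the run progresses — then the union of current population, mutated
   clones and newcomers is truncated to the $N$ fittest. The incumbent
   best is always in the union, so the best-fitness trajectory is
   non-increasing by construction.

Initial antibodies activate each locus when a standard Cauchy draw
exceeds $\eta = -0.2$, giving expected density
$1 - F(-0.2) \approx 0.563$; the Cauchy's heavy tails are the point —
they produce more varied codes and larger jumps than a Gaussian rule
would. Any all-zero code (initialisation or mutation) is repaired by
activating one uniformly random locus, keeping the fitness defined
without biasing any particular feature.

## The KNN evaluator

`knn_cv_error()` is deliberately deterministic end-to-end:

* stratified `cv_folds`-fold assignment (default 5) derived from
  `fitness_config(seed=)` over sorted sample ids, so it is invariant to
  row order and identical for identical masks — which makes the fitness
  cache exact, not approximate;
* automatic leave-one-out fallback when any class is smaller than the
  fold count;
* Euclidean distances on the masked columns, $k = \min(5,
  \text{training size})$, majority vote with ties broken toward the
  smallest class label under the sorted label order;
* optional z-scoring uses training-fold statistics only (default off:
  raw expression values, the common convention for this kind of
  comparison).

The reported `final_accuracy` of a run is computed on freshly seeded
folds, not the folds the search optimised against, so it is not an
optimistically re-used estimate (it remains an internal CV estimate, not
external validation).

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `Tmax` | 50 | iterations of the clonal loop |
| `N` | 10 | population size |
| `c_r` | 0.5 | select rate; elite pool is `round(c_r*N)` |
| `eta` | -0.2 | Cauchy activation threshold at initialisation |
| `beta` | 1 | clone factor in `round(beta*N/rank)` |
| `fisher_k` | 200 | filter size (stage-1 cut) |
| `omega` | 0.99 | fitness weight on the error term |
| `knn_k` | 5 | neighbours in the evaluator |
| `cv_folds` | 5 | stratified CV folds |

All randomness derives from one master seed: the search stream runs
under it, fold assignment uses `fitness_config$seed` (default master +
1000), and the final re-evaluation uses master + 2000. Fixed seed, fixed
result, bit for bit.

## What the synthetic generator emulates — and what it does not

`make_dataset(synthetic_spec(...))` plants `n_informative` columns whose
class-$k$ mean is $k \cdot \texttt{mean\_shift}$ (in noise-SD units)
among i.i.d. Gaussian noise columns. Defaults — 100 samples, 2000
features, 10 informative, 2 classes, shift 3 — reproduce the regime the
method targets: a few strongly class-informative features hidden among
thousands of irrelevant ones, with few samples per class. The generator
returns the ground-truth indices so recovery is measurable.

It does *not* emulate microarray-specific structure: probe effects,
heteroscedastic noise, correlated gene blocks, batch effects, or
label noise. Passing tests on this generator show the pipeline does what
its mechanism promises under its own model assumptions (Gaussian
class-conditional means, equal variances — the setting in which both the
Fisher criterion and KNN are consistent); they do not certify
performance on real tumour panels.

## Numerical and design choices

* **Rounding.** Clone counts and the elite-pool size round halves away
  from zero (`floor(x + 0.5)`), not banker's rounding.
* **Tie-breaks.** Everywhere a sort can tie (elite selection,
  truncation, votes, the filter cut), the tie-break is explicit —
  fitness, then fewer genes, then earlier origin; votes to the smallest
  label — so results are reproducible across platforms.
* **Stagnation dynamics.** With the flip rule, late-run exploration
  (when $\delta$ is near $-0.5$) inverts most loci of a sparse
  antibody, producing dense, usually poor candidates; exploration then
  relies mainly on the progressively sparser newcomers. A consequence
  is that a stagnated run can keep one or two redundant features that a
  longer lethal phase would have pruned; reduction stays far above 99%
  either way.
* **Problem sizes in the test suite.** Unit tests run on scaled-down
  planted data (tens of samples, hundreds of features) chosen to
  exercise every code path quickly; the end-to-end checks and the
  acceptance script use the full study condition (100 x 2000, 20 seeded
  runs) where a single default run takes a few seconds.
* **Filter pass-through.** `fisher_k >= q` makes stage 1 the identity;
  the search then explores the full space, and the CLI notes the
  pass-through.
* **`Tmax = 0`** returns the best antibody of the initial population;
  the trajectory has a single point.

## Known limitations

* The wrapper optimises an internal CV estimate; with tiny sample
  sizes the selected subset's accuracy estimate is optimistic relative
  to truly held-out data even when re-evaluated on fresh folds.
* Feature interactions invisible to the Fisher score can be filtered
  out in stage 1 before the wrapper ever sees them; `fisher_sweep()`
  shows how accuracy responds to the cut size on a given dataset.
* The evaluator is KNN-only by design; no other classifier is wired in.
* Runtime scales with `Tmax * (clones + N)` fitness evaluations; the
  mask-keyed cache removes exact repeats only.
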