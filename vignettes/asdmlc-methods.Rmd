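---
title: "Methods: imbalance-aware ensemble classification with asdmlc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware ensemble classification with asdmlc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdmlc)
```

## The problem

Clinical tabular datasets — diabetes screening cohorts, protein
localization panels, thyroid function tests — are usually imbalanced: the
clinically interesting class is the rare one. Plain classifiers trained on
such data buy accuracy by ignoring the minority, and plain SMOTE-style
oversampling interpolates blindly, including across regions dominated by
the other class. `asdmlc` implements a pipeline built around oversampling
that is *adaptive* to local learning difficulty, combined with wrapper
feature selection and a heterogeneous soft-voting ensemble.

The stages, all fit strictly on training data:

1. **ADASYN oversampling.** With minority and majority counts $m_s \le m_l$,
   the degree of imbalance is $d = m_s / m_l$. If $d$ is below the
   tolerance $d_{th}$, the total synthetic budget is
   $G = (m_l - m_s)\beta$. For each minority point $x_i$, the hardness
   ratio $r_i = \Delta_i / K$ counts the majority members among its $K$
   nearest neighbours (all classes, Euclidean distance). Normalized
   ratios $\hat r_i = r_i / \sum r_i$ allocate $g_i = \hat r_i G$
   synthetics (rounded per point), each synthesized as
   $s = x_i + (x_{zi} - x_i)\lambda$, $\lambda \sim U[0,1]$, with $x_{zi}$
   drawn from $x_i$'s minority-only neighbours. Hard-to-learn points thus
   receive more synthetic support.
2. **Min-max normalization.** Each feature is mapped affinely so the
   training extrema land on $[0, 1]$ (configurable to $[-1, 1]$).
3. **VPSO feature selection.** Binary particle swarm optimization over
   bitmasks of features, with classification accuracy of a surrogate
   classifier (internal stratified 3-fold CV) as the fitness. The
   canonical velocity update uses a linearly decaying inertia weight
   $w = (w_{max} - w_{min})(I_{max} - I)/I_{max} + w_{min}$; instead of a
   hard velocity clamp, components beyond $\pm v_{max}$ are repeatedly
   damped by $\alpha$ ("velocity equalization"), keeping every dimension
   exploring at a comparable scale and delaying premature convergence.
4. **Averaging ensemble.** Three dissimilar members — a first-order Sugeno
   ANFIS, a probabilistic neural network (Parzen classifier), and
   clustering-based decision trees (k-means partition, one gain-ratio tree
   per cluster) — each emit per-class probabilities; the ensemble is their
   unweighted arithmetic mean, and the label is the argmax (ties to the
   lower class code).

Evaluation is stratified 10-fold cross-validation with *every* stage
refit inside each training fold; held-out folds are only normalized and
mask-restricted, never oversampled, so reported metrics cannot be
inflated by synthetic points leaking into the test set.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `adasyn_k` | 5 | neighbour count for hardness ratios and interpolation partners |
| `beta` | 1 | balance level; 1 brings the minority up to the majority size |
| `dth` | 0.75 | tolerance on $d = m_s/m_l$; above it no oversampling happens |
| `norm_low`, `norm_high` | 0, 1 | normalization target range |
| `swarm_size`, `imax` | 20, 100 (40 in the pipeline) | swarm size and iterations |
| `c1`, `c2` | 2, 2 | cognitive/social acceleration constants |
| `wmax`, `wmin` | 0.9, 0.5 | inertia bounds of the linear decay |
| `vmax`, `alpha` | 4, 0.5 | velocity cap and equalization damping factor |
| `pnn_sigma` | 0.1 | Gaussian kernel spread on $[0,1]$-normalized features |
| `cbdt_k` | 3 | k-means clusters for the tree member |
| `anfis_epochs`, `anfis_lr` | 50 (10 in the pipeline), 0.01 | hybrid training schedule |

`dth = 0.75` is the conventional preset of the adaptive-oversampling
literature; it is exposed because the right tolerance is
domain-dependent. The PNN spread 0.1 is calibrated to unit-range
features: it makes a point roughly "visible" to neighbours within a
tenth of each feature's range. `cbdt_k = 3` keeps clusters large enough
to grow non-trivial trees on datasets of a few hundred rows.

## Design choices where the design was open

* **Stage order.** ADASYN runs on raw features by default and
  normalization afterwards; since ADASYN is distance-based this makes it
  scale-sensitive, so the alternative order is available via
  `adasyn_after_norm = TRUE`.
* **Velocity equalization.** The equalization rule is implemented as
  conditional damping: any updated component with $|v| > v_{max}$ is
  multiplied by $\alpha$ until it is in range (e.g. 9.6 → 4.8 → 2.4 with
  $v_{max} = 4$, $\alpha = 0.5$). A hard clamp — classic binary PSO — is
  available with `equalize = FALSE` for comparison.
* **Binary transfer.** Positions are re-binarized by the standard
  sigmoid/Bernoulli rule $P(\text{bit}=1) = 1/(1+e^{-v})$; an all-zero
  mask is repaired by setting one random bit, since an empty feature set
  is not a candidate.
* **Fitness ties** break toward fewer selected features, so among
  equally accurate masks the parsimonious one wins.
* **Fitness surrogate.** The default surrogate is the PNN: it is
  deterministic, has no training loop, and one mask evaluation is a few
  matrix operations, which matters inside a swarm that scores thousands
  of masks. `surrogate = "ensemble"` scores masks with the full
  three-member ensemble at much higher cost. Fitness is the pooled
  accuracy over the internal stratified folds (folds are equal-sized to
  within one instance, so this coincides with the fold mean up to that
  rounding).
* **Selection scope.** Feature selection runs once per outer training
  fold, never on test data, to avoid selection bias.
* **ANFIS completion.** The architecture is grid-partitioned with 2
  Gaussian membership functions per input (hence $2^n$ rules),
  first-order consequents solved by ridge-stabilized least squares
  (ridge $10^{-6}$, for rank-deficient designs), premises updated by one
  batch gradient step per epoch against a 0/1 class target; multi-class
  data uses independent one-vs-rest heads renormalized at predict time.
  Because the rule count doubles per input, the ensemble trains its
  ANFIS member on at most `anfis_max_inputs` (default 6, i.e. 64 rules)
  features — when more survive selection, the member sees the subset
  most correlated with the class label, while the PNN and tree members
  always see all selected features. Direct calls to `fit_anfis()` keep a
  hard cap of 8 inputs and point the user to feature selection instead.
* **"C4.5-style" trees** are realized as entropy/gain-ratio binary trees
  (max depth 10, minimum leaf 2, Laplace-smoothed leaf frequencies)
  rather than bit-exact Quinlan C4.5; none of the pipeline's claims
  depend on the exact split heuristic, and the gain-ratio criterion is
  the part that matters for the cluster-wise trees.
* **Positive class.** The minority class is the "positive" class for
  precision/recall, because it is the clinically interesting one; with
  more than two classes, metrics are macro-averaged one-vs-rest. A
  multi-label mode (`asdmlc_cv_multilabel()`) binarizes a label matrix
  one label at a time and macro-averages.

## Numerical details and degenerate inputs

* Distance ties in neighbour searches break toward the lower row index.
* $\sum r_i = 0$ (no minority point has majority neighbours): the
  allocation falls back to uniform, preserving the $\beta = 1$ balance
  contract rather than dividing by zero.
* Per-point allocations are rounded independently
  ($g_i = \lfloor \hat r_i G + 0.5 \rfloor$), so $\sum g_i$ may differ
  from $G$ by up to $m_s/2$; remainders are deliberately not
  redistributed.
* A minority singleton has no minority neighbours; it is duplicated with
  a warning.
* Constant features map to the lower normalization bound and are
  reported, never silently dropped; test-set values outside the training
  extrema are clipped so kernel distances stay bounded.
* PNN scores are computed in log space with max-subtraction, so
  $\sigma \to 0$ degrades gracefully to the 1-nearest-neighbour rule
  instead of underflowing to the class priors.
* Empty k-means clusters are dropped (with a message) and the cluster
  count reduced.
* All randomness flows through explicit seeds; fits, selections and
  cross-validation reports are bit-reproducible given the seed.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` produces class-conditional Gaussian clusters:
informative features whose class means are `class_separation` standard
deviations apart (the mean difference is split across the informative
axes, so the parameter is the Euclidean distance between class
centroids), noise features common to both classes, class sizes set
deterministically by the requested imbalance ratio, and the informative
column indices recorded as ground truth. This is the right harness for
testing the pipeline's *contracts*: balance after oversampling, hull
containment of synthetics, recovery of informative features, direction
of the selection ablation.

It does not emulate several properties of real clinical tables:
correlated or redundant features, heavy-tailed and discrete
measurements, label noise, missingness mechanisms, or subpopulation
structure inside a class. Passing tests on these fixtures therefore
demonstrate correctness of the algorithms, not expected accuracy on any
particular clinical dataset; absolute benchmark numbers depend on
hyperparameters and data idiosyncrasies that must be tuned per cohort.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: oversampling balance
on a 600-instance, imbalance-5 cohort; feature recovery on 400-instance,
15-feature fixtures with 3 informative features and centroid separation
6 (five seeds); swarm-vs-exhaustive comparison on 6 features (all 63
masks enumerable); and the selection ablation as 10-fold
cross-validation on the recovery fixture over three seeds. These sizes
were chosen to make every claimed property measurable with comfortable
margins while keeping a full run in minutes on one core.

## Known limitations

* ADASYN and the ablation driver are binary-only; multi-class data must
  disable oversampling (the loader accepts it, distance-based stages
  refuse it explicitly).
* The wrapper fitness is a surrogate: masks that suit the PNN are not
  guaranteed optimal for the full ensemble (the `ensemble` surrogate
  removes the mismatch at quadratic cost).
* ANFIS equivariance under label flips is exact only up to the ridge
  stabilizer (the penalty is not invariant under target reflection);
  the discrepancy is at the $10^{-3}$ probability level.
* Grid-partition ANFIS is exponential in inputs; beyond ~8 inputs a
  different rule-induction scheme (e.g. subtractive clustering) would be
  needed, which is out of scope here.
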