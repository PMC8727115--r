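---
title: "Information-theoretic feature selection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic feature selection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndcrfs)
```

## The problem

High-dimensional, small-sample classification tables — microarray and other
omics panels are the canonical case — contain many features that are
irrelevant to the class label, many that duplicate each other, and a few
whose value only shows jointly with another feature. Filter-style feature
selection scores features from data statistics alone, independent of any
classifier, which keeps it cheap and transferable. This package implements a
family of such filters built entirely from plug-in information measures on
discrete variables, together with the greedy forward search that turns a
per-candidate score into a ranked subset.

All estimators are maximum-likelihood ("plug-in") frequency-count estimates
in bits: entropy $H(X) = -\sum_x p(x)\log_2 p(x)$, mutual information
$I(X;Y)$, conditional mutual information $I(X;Y\mid Z)$, and the interaction
information $I(X;Y) - I(X;Y\mid C)$, whose sign separates redundancy
(positive) from synergy (negative). No smoothing or bias correction is
applied: the comparator criteria in this family are all defined on plug-in
estimates, and applying different corrections per criterion would change the
comparison being made. Degenerate cells follow the standard
$0\log 0 := 0$ convention, and floating-point negatives above $-10^{-9}$ are
clamped to zero.

## The criteria

Let $F$ be the feature set, $S \subset F$ the features selected so far,
$f_k$ a candidate and $C$ the class. The eight criteria are:

| name | score of candidate $f_k$ |
|---|---|
| `mim`    | $I(f_k;C)$ |
| `cife`   | $I(f_k;C)-\sum_{s\in S}\left[I(f_k;s)-I(f_k;s\mid C)\right]$ |
| `jmi`    | as `cife` with the sum replaced by its mean |
| `cmim`   | $I(f_k;C)-\max_{s\in S}\left[I(f_k;s)-I(f_k;s\mid C)\right]$ |
| `dwfs`   | $W(f_k)\cdot I(f_k;C)$, $W \mathrel{*}= \frac{2(I(f_k;C\mid s)-I(f_k;C))}{H(f_k)+H(C)}+1$ |
| `drjmim` | $\min_{s\in S}\; I(f_k;s;C)\left[I(f_k;C)+\mathrm{CR}(f_k,s)\,I(s;C)\right]$ |
| `dwur`   | $W(f_k)$, $W \mathrel{*}= (1-\beta I(f_k;s))\left[I(f_k;C)+\mathrm{CR}(f_k,s)\,I(s;C)\right]$ |
| `ndcrfs` | $I(f_k;C)-\max_{s\in S} CU(s,f_k)\left[I(f_k;s\mid C)-I(s;C)\right]$ |

with the dynamic-relevance ratio
$\mathrm{CR}(f_k,s) = 2\,(I(f_k;C\mid s)-I(f_k;C))/(H(f_k)+H(C))$ and the
information gain factor $CU(s,f_k) = 2/(H(s\mid C)+H(f_k\mid C))$.

The NDCRFS penalty reads $I(f_k;s\mid C) - I(s;C)$: a candidate that remains
strongly dependent on an already-selected feature *within* each class — the
signature of a copy — is penalised in proportion to how much that dependence
exceeds the selected feature's own relevance, and $CU$ rescales the penalty
by how much class-conditional uncertainty the two features actually have.
When both features are deterministic functions of the class the $CU$
denominator vanishes; $CU$ is then defined as 0, so such candidates are
ranked by relevance alone rather than through an undefined ratio.

A worked example on the bundled eight-sample fixture (`f2` duplicates `f1`
exactly; `f3` is class-balanced):

```{r toy}
d <- toy_duplicate_data()
score_candidates(d[c("f1", "f2", "f3")], d$class, "ndcrfs", selected = "f1")
select_features(class ~ ., d, criterion = "ndcrfs", k = 3)$order
```

The duplicate scores $\approx -0.579$ bits and is rejected in favour of the
marginally useless but non-redundant `f3` ($\approx -0.135$).

## Conventions the formulas leave open

Several points are under-determined by the printed formulas; the package
fixes them as follows and tests against these choices:

* **Empty selected set.** Sums, maxima and minima over $S=\varnothing$ are 0,
  so every criterion's first pick is the max-relevance feature. This matches
  a forward search seeded with the top-MI feature and makes the eight
  criteria comparable from a common starting point.
* **Weight-based criteria.** `dwfs` and `dwur` are written as multiplicative
  weight recurrences. The package ranks `dwfs` candidates by
  $W\cdot I(f_k;C)$ (weights start at 1, so the first step is the relevance
  ranking); `dwur`'s multiplier already contains the relevance term, so its
  ranking score is $W$ itself after the first step. After each selection,
  every remaining candidate's weight is updated against the newly selected
  feature only.
* **`drjmim` grouping.** The minimum is taken over the whole product
  (interaction term times the bracketed relevance), not the interaction term
  alone; the alternative grouping would let a single near-zero interaction
  erase the relevance term entirely.
* **`dwur` redundancy factor.** The $(1-\beta I(f_k;s))$ factor is included
  with $\beta = 0.5$ by default, exposed as a parameter since no canonical
  value exists.
* **Ties and degenerate scores.** Ties break to the lowest column index, so
  runs are deterministic and subset comparisons are well defined. Candidates
  whose score is non-finite are ranked last: an undefined penalty must never
  win selection.
* **Cost.** Pairwise statistics are computed only against the newly selected
  feature and memoized, so selecting $T$ of $n$ features costs at most
  $T\cdot n$ pairwise-table evaluations (each linear in the sample count);
  an instrumentation counter in the result (`n_pair_stats`) lets tests
  assert this bound.

## Behaviour worth knowing about

Two properties of the NDCRFS penalty follow directly from its form and are
worth stating plainly, because they differ from what one might expect of a
criterion with "interaction" in its ancestry:

* **Conditional dependence is read as redundancy, not synergy.** For a
  parity (XOR) pair, the partner of an already-selected member has
  $I(f_k;s\mid C) = 1$ bit and (for a marginally silent selected member)
  $I(s;C)=0$, so the partner is penalised a full $CU$ unit while an
  independent noise bit is penalised nothing. `cmim`, `cife` and `jmi`, by
  contrast, *reward* the partner (their penalty term
  $I(f_k;s)-I(f_k;s\mid C)$ is $-1$ bit). The synthetic-data tests document
  this: after one pair member is selected, the conditional-penalty criteria
  immediately select the partner, NDCRFS does not.
* **Redundancy is rejected only when it exceeds the source's relevance.**
  The penalty is positive only where $I(f_k;s\mid C) > I(s;C)$. A noisy copy
  of a *strongly* relevant feature (say $I(s;C)\approx 0.7$ bits) keeps
  $I(f_k;s\mid C)$ well below that and therefore still outranks noise — an
  arguably correct outcome, since the copy does carry class information.
  Exact duplicates of modestly relevant features (the fixture above) are
  rejected.

## Discretization

The information estimators require categorical data, so continuous columns
are discretized first, by class-attribute interdependence maximisation
(CAIM) by default. The implementation reconstructs the standard greedy
scheme: candidate boundaries are midpoints between consecutive distinct
values; starting from one interval, the boundary maximising
$\mathrm{caim} = \frac{1}{r}\sum_{i=1}^{r} \frac{(\max_c q_{ci})^2}{M_i}$
(over the quanta matrix $q$ of class-by-interval counts) is added until the
criterion stops improving and at least as many intervals as classes exist.
Equal-width and equal-frequency binning (5 bins by default) are provided as
explicitly labelled fallbacks so that results never silently depend on the
CAIM reconstruction. Constant columns collapse to a single bin; coding is
monotone, and out-of-range values clamp to the edge bins.

In cross-validated evaluation the schemes are fitted on training folds only
and applied to the held-out fold (`discretize_folds = "per_fold"`, the
default, with `"once"` available for strict mimicry of protocols that
discretize the full table up front). The per-fold fitted schemes are
attached to the result so leakage-safety is testable, and the test suite
asserts it.

## Evaluation harness

`cross_validated_accuracy()` evaluates a fixed ranking over nested subset
sizes with stratified k-fold assignment (within each class, indices are
shuffled under the stored seed and dealt round-robin; a class with fewer
than two samples raises a stratification error). Classifier adapters wrap
the host ecosystem's standard implementations — k-nearest-neighbour
(`class::knn`, $k=3$ by default), a classification tree (`rpart`), and an
SVM (`e1071`, radial kernel) — with hyperparameters exposed because no
canonical values exist for this protocol. `benchmark()` ranks once per
criterion, evaluates every curve, and reports best accuracy with the
smallest subset size attaining it, the Jaccard matrix between final
subsets, and per-size wins/ties/losses against a reference criterion at
3-decimal precision. Subset agreement uses the Jaccard index
$|S_1\cap S_2|/|S_1\cup S_2|$; for equal-size subsets of size $K$ it can
only take the values $i/(2K-i)$, a grid the tests exploit.

## The synthetic generator

`generate_dataset(planted_design(...))` builds tables with known ground
truth: a uniformly drawn class; *relevant* features that copy the class with
each value re-sampled uniformly with probability $\rho$ (uniform
re-sampling rather than bit-flipping, so the scheme generalises beyond
binary alphabets); *redundant* noisy copies of designated relevant features;
*interacting* pairs $(X, (C - X) \bmod m)$ — XOR for binary — whose members
are marginally independent of the class but jointly determine it; and
uniform *irrelevant* noise. Roles are returned in metadata and written to a
JSON sidecar, never into the CSV, so a pipeline cannot accidentally read
them. For a binary class, `expected_mi()` gives the closed-form
$I(f;C) = 1 - H_b(\rho/2)$ for a relevant feature (uniform re-sampling at
rate $\rho$ is a symmetric channel with flip probability $\rho/2$), and the
chained value for redundant copies; tests check Monte-Carlo convergence to
these values.

Default design — 500 samples, binary class, 5 relevant features at
$\rho = 0.1$, 5 redundant copies at the same noise, one interacting pair,
20 irrelevant features — reflects a small-sample, low-noise planted-signal
regime in which relevance is clearly estimable ($I \approx 0.71$ bits
against a noise floor of a few thousandths) but finite-sample MI noise is
still visible. What the generator does **not** emulate: real microarray
marginal distributions, correlated noise between irrelevant features, or
continuous measurements (features are generated directly on the class
alphabet). Passing tests on this generator therefore demonstrate the
criteria's decision structure — relevance ordering, duplicate handling,
synergy handling — not performance on any particular biological dataset.

## Problem sizes in the test suite

The suite exercises the estimator oracle on 200 random triples of up to 30
samples and 4 categories (checked against literal definition sums to
$10^{-9}$), the criteria on the 8-sample worked fixture and random tables of
tens of samples, and the selection/recovery properties on 20 seeded
500-sample synthetic datasets of about 30 features. These sizes are chosen
so that each property is measured well inside its asymptotic regime while
the whole suite remains quick to run; the package itself has no intrinsic
size limits beyond memory ($O(Tn)$ cached pairwise tables).

## Known limitations

* Plug-in MI is positively biased at small $n$; rankings among equally
  irrelevant features are noise, which is why tie-behaviour and recovery
  properties are stated over seed ensembles.
* The NDCRFS conditional-relevance penalty does not reward synergy (see
  above); on parity-structured signals the conditional-penalty criteria
  (`cmim`, `cife`, `jmi`) recover pairs more readily once a member is
  selected.
* CAIM is a reconstruction from its standard published definition; the
  unsupervised fallbacks are the guard against over-reliance on it.
* MI between multi-category variables is not bounded by 1; interpretations
  that read $I = 1$ as "fully redundant" only hold for binary alphabets and
  are not enforced anywhere.
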