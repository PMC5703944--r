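---
title: "Screening synergic gene pairs by rank conversion and t-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening synergic gene pairs by rank conversion and t-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synpair)
library(dplyr)
```

## The problem

In a case/control expression study `{Y_i, X_ij}` (n samples, m genes,
`Y ∈ {0, 1}`), a per-gene t-test finds the *individually discriminant*
genes. It cannot find *synergic* pairs: genes whose joint distribution
separates the classes while each margin is uninformative. The canonical
example is a phenotype driven by `|X1 − X2|` with uniform marginals —
every one-dimensional projection of the data looks like noise, yet the
pair separates the classes almost perfectly along the diagonal band of
their scatterplot.

The information-theoretic score for this is the interaction information
`I(X1;X2;Y) = I(X1,X2;Y) − I(X1;Y) − I(X2;Y)` (positive = synergy,
negative = redundancy). Estimating it for all m(m−1)/2 pairs is costly
and hinges on how the continuous expression values are discretized.

## The method

`synpair` screens pairs with a two-step conversion strategy instead:

1. **Rank transform** (`rank_transform`): each gene's values are
   replaced by their within-gene sample ranks `R_ij ∈ [1, n]`. Ranks are
   robust to per-gene background and quantization differences and make
   pair features comparable across gene pairs.
2. **Pair conversion** (`convert_pair`, `scan_pairs`): each canonical
   pair (p < q) is collapsed into one feature vector Z by a conversion
   type: `sum` (`R_p + R_q`), `diff` (`R_p − R_q`), `mul` (`R_p R_q`),
   `sign` (`1[R_p ≥ R_q]`), or `abs` (`|R_p − R_q|`). Every Z is scored
   by a two-sample t-score against the labels and pairs are ranked by
   |t|.

The four classical doublet conversions capture patterns that are largely
visible marginally; `abs` is the conversion matched to the diagonal-band
synergy: `|R_p − R_q|` is small where the genes agree and large where
they disagree, so a class split along the band becomes a plain
location shift of Z that a t-test sees immediately. Because the pattern
it matches is invisible to marginal statistics, the genes it surfaces
are largely disjoint from a marginal screen's — `overlap_matrix()`
quantifies this on any pair of screens.

The full scan is exhaustive but cheap: for a fixed reference gene the
converted features of a block of partner genes are a single vectorized
matrix expression, and the t-score needs only per-class sums and sums of
squares of Z. `scan_pairs` therefore processes partner genes in blocks
of `block_size` (default 512) rows, retaining a top-N pool rather than
the O(m²) score vector. A 10⁴-gene study (≈5×10⁷ pairs) is a flat pass
over sufficient statistics — no per-pair discretization, grid search, or
density estimation, which is what makes the exhaustive scan affordable
where information-theoretic pair scans are not.

### Numerical conventions

* **t variant**: Welch (unequal variances) by default; the pooled
  Student t is available (`t_variant = "pooled"`). The two rankings are
  essentially identical in practice; Welch is the safer default when a
  converted feature has different spreads in the two classes.
* **Sign**: t = mean(class 0) − mean(class 1); ranking uses |t| since
  both directions of association are informative in a screen.
* **Degenerate features**: a Z constant within both classes scores 0
  when the class means agree, and a signed infinity sentinel (ranked
  above all finite scores) when they differ — a perfectly separating
  feature.
* **Ties**: equal |t| is broken by the lexicographically smaller (p, q),
  so output is deterministic and blockwise output is bit-identical to a
  double-loop scan.
* **Rank ties**: average ranks by default, which keeps every rank row
  summing to n(n+1)/2 exactly; competition ("min") ranking is available.
  With continuous expression values ties are rare and the choice is
  immaterial.
* **Screening scope**: ranks and screens are computed on *all* samples
  by default, and cross-validation then evaluates fixed feature sets.
  This mirrors common practice for this screen but is optimistically
  biased as an estimate of selection + classification performance;
  `run_scheme_comparison(nested = TRUE)` repeats ranking, scanning and
  rank transformation inside every training fold (held-out samples are
  ranked by insertion into the training values) when an unbiased
  protocol is wanted. The two modes are never mixed in one result table
  (`attr(result, "mode")` names the protocol).

## The reference synergy measure

`interaction_information` is a deliberately plain estimator: equal-
frequency binning (default 4 bins per gene), plug-in (maximum
likelihood) mutual information in bits, no bias correction. It exists to
*verify* on small examples that what the abs screen finds is synergy in
the information-theoretic sense, not to run genome-wide. Plug-in MI is
nonnegative and positively biased at small n, which inflates the joint
term most; interpret small positive interactions at small n with care.
Two exact anchors pin the implementation down: the XOR of two fair coins
scores (0, 0, 1) bits for the two marginal and the joint terms, hence
interaction exactly +1; and independent variables score ≈ 0 at large n.

## The simulator

`simulate_table4(k, n, seed, n_noise)` draws 2k causal columns i.i.d.
U(0, 1), sets `y = Σ_j |X_{2j−1} − X_{2j}|`, and labels samples above
the midpoint median of y as class 1 — an exact 50/50 split for even n
(ties occur with probability zero for continuous draws). Defaults match
the study conditions used throughout the package: n = 200 samples, no
noise genes, k ranging over 1..10. `simulate_mixed` prepends additive
individual genes (`y = X1 + ... + |Xa − Xb| + ...`) for experiments that
mix both kinds of signal, and `n_noise` appends uniform columns
unrelated to y.

What the simulator emulates is precisely the synergy geometry (uniform
marginals, abs-pair structure, balanced classes). What it does *not*
emulate about real expression data: correlated genes, heavy-tailed and
heteroskedastic intensities, batch effects, unbalanced classes, and
class-conditional marginal shifts. Passing the simulation suite
therefore shows the machinery is correct and that the abs screen finds
what it is designed to find; it does not by itself certify performance
on any particular real dataset.

## The evaluation harness

`run_cv` is a stratified, seeded 5-fold cross-validation over a
classifier registry chosen to span model families: four LIBSVM-style
SVMs via e1071 (RBF, linear, polynomial degree 3, sigmoid; cost 1,
library-default kernel parameters), `randomForest` (500 trees), `nnet`
(one hidden layer of 16 units, weight decay 5e-4, ≤200 iterations), and
`rpart` (CART). Accuracy is `(TP+TN)/(TP+FP+TN+FN) × 100`, averaged over
folds (and over seeds in the study functions); it is the right summary
here because every simulated dataset is exactly class-balanced.

Features are rescaled inside each fold from training-fold statistics
only. The default is standardization (zero mean, unit variance), the
convention the SVM kernels assume; min–max to [0, 1] and no scaling are
options. We verified on the k-pair ladder that standardization is also
the convention under which the unconverted-feature SVM results are
reproduced most faithfully, whereas min–max scaling noticeably degrades
the unconverted RBF cells; it is therefore the package default rather
than a tuning knob.

`run_table5_experiment` runs the converted-versus-unconverted contrast
over the k ladder: for each (k, seed) it simulates a dataset and
cross-validates every classifier on the k true converted features
{Z1..Zk} and on the 2k raw columns {X1..X2k}, with shared fold
assignments so the contrast is paired. Two robust findings, both
asserted in the test suite at the study size (k ∈ {1, 2, 5, 10},
n = 200, 20 seeds — sizes chosen so the full grid runs in minutes on a
single CPU while seed-averaged cell accuracies are stable to well under
a percentage point):

* **Dominance**: converted features are at least as accurate as
  unconverted ones in every (k, classifier) cell.
* **Degradation**: with unconverted features, kernels without the
  flexibility to represent Σ|X_{2j−1} − X_{2j}| (linear, low-degree
  polynomial) decay to chance as k grows, while converted features keep
  every classifier near-perfect. This is the practical point of the
  screen: even a classifier that *could* use the raw pair members
  usually does not, so synergic genes must be converted to Z before
  being fed to a model.

`run_scheme_comparison` builds the applied feature schemes — top-N
individual genes (raw expression), top-N converted pairs per conversion
type, and their union — and `label_randomization` re-runs any scheme on
permuted labels as a leakage control (accuracies must collapse to
chance).

## Design choices that were genuinely open

* **Scoring pairs by |t| versus signed t**: a screen should catch both
  orientations of a feature; |t| is the default and the sign is
  reported.
* **sign conversion at rank ties**: ties score 1 (the `≥` branch),
  matching the conversion's definition.
* **Median split**: strictly-greater-than the midpoint median defines
  class 1. For continuous phenotypes this is exact and unambiguous;
  which side is called "1" is immaterial to every statistic used.
* **Equal-frequency binning** for the reference estimator: the simplest
  defensible choice, and the package documents that it is *not* any of
  the published dendrogram/MIC discretizations — results are anchored by
  closed-form cases instead.
* **Classifier hyperparameters** are library defaults on purpose: the
  harness compares *feature schemes*, not tuned models, and the
  dominance/degradation conclusions are insensitive to tuning. All knobs
  are exposed as arguments for users who want to tune.

## Known limitations

* The pairwise scan ranks raw |t| scores; it deliberately provides no
  p-value calibration or multiple-testing correction across the m(m−1)/2
  pairs. Downstream validation (held-out accuracy, randomization tests,
  external evidence) is the intended follow-up.
* Plug-in interaction information is biased at small n; it is a
  reference measure, not a screener.
* The default all-samples screening protocol overstates combined
  selection-plus-classification accuracy; use `nested = TRUE` for an
  honest estimate when the screen itself is part of the pipeline under
  evaluation.
* `abs` targets the diagonal-band synergy geometry. Synergies of a
  different shape (e.g. XOR-like corner patterns on heavily bimodal
  genes) map onto ranks differently and may be better served by `sign`
  or by the reference information measure on candidate pairs.

## A compact end-to-end run

```{r}
ds <- simulate_mixed(n_ind = 2, n_syn_pairs = 2, n_noise = 14,
                     n = 100, seed = 2024)
scan_pairs(ds, "abs", top_n = 3)
rank_individual(ds, top_n = 3)
res <- run_scheme_comparison(ds, top_ind = 2, top_syn = 2,
                             conversions = "abs", seed = 1)
res |> group_by(scheme) |> summarise(accuracy = mean(accuracy))
```
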