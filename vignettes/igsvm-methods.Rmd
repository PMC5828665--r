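---
title: "Hybrid filter/SVM gene selection: models, defaults and design notes"
author: "igsvm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid filter/SVM gene selection: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsvm)
```

## The problem

Two-class expression studies (tumour vs normal tissue, disease subtypes)
routinely measure thousands of genes on a few dozen samples. Classifying
such data with all genes is both statistically fragile and biologically
uninformative; the goal of gene selection is a handful of genes that carry
the class signal. `igsvm` implements a two-stage hybrid:

1. **Filter stage.** Every gene receives a univariate relevance score and
   the top `nFilter` (default 150) genes are kept. The primary score is
   *information gain*, \(g(Y, X) = H(Y) - H(Y \mid X)\), the reduction in
   class entropy once a gene's (discretized) expression is known. Gain
   ratio, reliefF and point-biserial correlation are provided as
   comparators.
2. **Wrapper stage.** A linear soft-margin SVM is trained on the
   surviving genes and recursive feature elimination (RFE) repeatedly
   discards the gene with the smallest squared weight \(\omega_j^2\) until
   `kFinal` (default 3) genes remain.

The selected genes are then assessed by stratified 10-fold
cross-validation of an RBF-kernel SVM, with pooled accuracy reported in
percent.

## Entropy scoring needs discretization

Information gain is defined for discrete variables, so continuous
expression values must be binned first. The default is supervised
recursive binary discretization with the minimum-description-length
(MDL) stopping rule: within an interval of \(N\) samples the candidate
cut with the largest class-information gain is accepted only when

\[
\mathrm{gain} > \frac{\log_2(N-1) + \log_2(3^k - 2)
  - [\,k H(S) - k_1 H(S_1) - k_2 H(S_2)\,]}{N},
\]

where \(k, k_1, k_2\) count the classes present in the interval and its
two halves. Candidate cuts are restricted to class-boundary midpoints:
a midpoint between two runs of tied values is skipped only when both runs
are pure and of the same class, which provably cannot host an
entropy-optimal cut. All entropies are in bits (base-2 logarithms);
on a two-class problem this puts information gain on the familiar
\([0, 1]\) scale. A gene for which no cut clears the MDL threshold is
coded into a single bin and scores exactly zero — on null data most genes
score 0, which is the intended behaviour, with ranking ties broken by the
canonical (input) gene order. Unsupervised equal-frequency binning
(default 10 bins) is available as `discretization = "eqfreq"` for
sensitivity analyses.

## The SVM stages

`trainSvm()` solves the usual soft-margin dual

\[
\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j}
\alpha_i \alpha_j y_i y_j K(x_i, x_j),
\qquad 0 \le \alpha_i \le C,\quad \textstyle\sum_i \alpha_i y_i = 0,
\]

through LIBSVM (via `e1071`), with no internal rescaling (`scale =
FALSE`) so that the package's own normalization is the only
transformation applied. The model object keeps the full-length dual
coefficients \(\alpha_i y_i\), so the test suite can check dual
feasibility directly, and compares trained objective values against an
exhaustive KKT-pattern enumeration on small problems.

Two deliberate kernel choices:

* **RFE uses the linear kernel** even though final classification uses
  the RBF kernel. Per-gene weights \(\omega_j = \sum_i \alpha_i y_i
  x_{ij}\) exist only for the linear kernel, and the linear kernel is the
  limiting special case of the RBF family, so the elimination criterion
  stays consistent with the final classifier. This is the standard
  (Guyon-style) reading of "the SVM removes redundant genes"; a
  single-pass variant (rank once by \(\omega_j^2\), cut to `kFinal`)
  can be emulated with `svmRfe(..., step = nFilter - kFinal)`.
* **Evaluation uses the RBF kernel** with LIBSVM defaults \(C = 1\) and
  \(\gamma = 1/p\), \(p\) the number of genes evaluated.

Exact weight ties in RFE (which arise for duplicated genes, whose weight
the SVM splits evenly) are broken by removing the later gene in canonical
order, keeping the run deterministic.

## Cross-validation protocol

Folds are stratified: within each class, samples are shuffled under the
given seed and dealt round-robin, with the fold counter carried across
classes so total fold sizes also differ by at most one. With `k = m` this
degenerates to leave-one-out. If a class is smaller than `k`, strict
stratification is impossible; the package warns and proceeds (some folds
then lack the minority class in their test portion).

Two protocol flags matter for interpretation:

* By default, selection is performed **once on the full dataset** and the
  selected genes are then cross-validated. This mirrors the common
  practice in the filter/wrapper literature but is optimistically biased,
  because the test folds participated in selection. Honest assessment
  re-runs selection inside each training fold; the building blocks
  (`stratifiedKFold()`, `hybridSelect()`, `crossValidate()`) make that a
  short loop, and `normalizeWithinFold = TRUE` applies the same hygiene
  to the z-score statistics. A leak-canary test (an extreme test-fold
  outlier must not move training-side statistics) guards the within-fold
  path.
* Normalization statistics are computed on all samples by default,
  matching the apparent protocol of the studies this package emulates.

## The synthetic generator

`generateExpression()` draws a Gaussian class-shift model: noise genes
are \(N(0, \sigma)\); each planted informative gene is
\(N(\pm\,\mathrm{effect}\cdot\sigma/2, \sigma)\) by class, so `effect` is
the between-class shift in pooled-standard-deviation units. Class counts
are exact (`round(m * classBalance)` positives at seeded positions), so
the Table-shaped presets reproduce the classic designs precisely:
`colon-like` (2,000 × 62, 40/22), `lung-like` (7,129 × 96, 86/10),
`leukemia-like` (7,129 × 72, 25/47). The colon benchmark is occasionally
listed with 20,006 genes; the classic matrix has 2,000 and the preset
uses that. An optional correlated block clones an informative gene at a
chosen correlation (redundant-gene model), and `logNormal = TRUE`
exponentiates the field for heavy-tailed intensities.

What the generator does *not* model: probe-level noise, batch effects,
heteroscedastic genes, and correlation structure beyond the single
optional block. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under a clean shift model, not
performance on real microarray data.

Default study conditions used by the test suite and the acceptance
script: the colon-like preset with 3 planted genes at effect 2.5 for
recovery experiments; 20 planted genes at effect 2.5 for the
filter-sweep curve (a realistic differential-expression burden for a
tumour/normal contrast, and the regime in which the curve's plateau is
informative); effect 0 for null controls. Replicate counts (10–20 seeds)
keep every experiment's Monte-Carlo error below the decision margins
while staying desk-scale.

## A known limit of RFE recovery

Planted informative genes are mutually correlated through the class
variable (about 0.6 at effect 2.5 with a 40/22 design), i.e. they are
partially *redundant* — and redundancy elimination is exactly what
SVM-RFE does. In roughly one replicate in five at effect 2.5, the linear
SVM's final rounds trade one of three redundant planted genes for a noise
gene that happens to separate the few margin samples; the package's
recovery rate is statistically indistinguishable from the canonical
scikit-learn `RFE(SVC(kernel="linear"))` on identical exported data, and
the per-round weights agree to solver tolerance. Users who need
all-of-set recovery should either raise `kFinal` or inspect the
`RfeTrace`: the planted genes are essentially always in the last ten
survivors even when not in the final three. Classification accuracy is
unaffected (the substituted trio still separates the classes).

## Numerical conventions

* \(0 \log 0 = 0\) throughout; information gain is clipped at zero
  against floating-point round-off.
* Gain ratio of a constant (single-bin) gene is 0 by convention;
  likewise the correlation score of a constant gene.
* z-score normalization uses the population (1/m) variance; constant
  genes map to zeros and are flagged rather than producing NaNs.
* Label mapping: the lexicographically smaller class name becomes −1,
  and the mapping is echoed on load.
* Every stochastic step (fold shuffles, generator draws, reliefF
  sampling) runs under an explicit seed through an RNG-preserving
  wrapper, so library calls never disturb the caller's random stream.
* ReliefF uses Euclidean distance on min–max-scaled values for the
  neighbour search and the standard range-normalized per-gene difference
  for the weight update; with the default "all instances" iteration it is
  fully deterministic.

## Worked example

```{r example, eval = FALSE}
fx <- makeFixture("colon-like", seed = 1)
ds <- zscoreNormalize(fx$dataset)
genes <- hybridSelect(ds, "ig", nFilter = 150, kFinal = 3)
cv <- crossValidate(ds, genes, k = 10, seed = 1)
genes
fx$informative
cvAccuracy(cv)
```

On this draw the three selected genes are exactly the planted ones and
the 10-fold accuracy is in the high nineties; the README shows the
printed output.

## Limitations

* Binary problems only; multi-class extensions (of reliefF, of the SVM
  stage) are out of scope.
* The default evaluation protocol shares the selection step across
  folds (see above); treat headline accuracies as comparative, not
  absolute.
* MDL discretization is recursive-binary; globally optimal multi-way
  discretization is not attempted.
* No probe-level preprocessing: inputs are assumed to be expression
  matrices ready for per-gene normalization.
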