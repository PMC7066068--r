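---
title: "Selecting compact biomarker panels with mRMR and incremental feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting compact biomarker panels with mRMR and incremental feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmrIFS)
```

## The problem

Single-cell RNA-seq of a tumor and its surrounding tissue yields thousands
of genes measured in thousands of cells, with two properties that defeat
naive marker selection: expression is sparse (dropout zeros), and the genes
that separate tumor-core from periphery cells come in large correlated
families. A t-test-style screen returns hundreds of interchangeable hits;
a clinically useful biomarker panel needs to be short and non-redundant.
This package implements the standard information-theoretic answer — mRMR
ranking followed by classifier-based incremental feature selection — as a
tested, seeded, end-to-end pipeline.

## The model and its pieces

### Discretization and mutual information

All mRMR quantities are plug-in mutual informations between discrete
variables, so each gene is binned first. The default is the 3-bin
mean-sigma scheme of the classical mRMR literature: with sample mean
$\mu$ and sample standard deviation $s$ (the $n-1$ form), values below
$\mu - \alpha s$ go to the low bin, values above $\mu + \alpha s$ to the
high bin, the rest to the middle, with $\alpha = 0.5$ by default. A
constant gene lands entirely in the middle bin and consequently has zero
mutual information with everything — constant genes can never be ranked
as markers, which is the behaviour one wants. An equal-frequency scheme
is available for heavy-tailed data where the mean-sigma cutpoints would
put nearly everything in one bin.

Mutual information is the plug-in estimate
$$\hat I(X;Y) = \sum_{a,b}\hat p(a,b)\,\ln\frac{\hat p(a,b)}{\hat p(a)\hat p(b)},$$
in nats, with $0\ln 0 = 0$. Nats rather than bits is a pure convention:
the base rescales every relevance and redundancy identically and cannot
change any ranking. No bias correction (Miller–Madow) or continuous
(kNN) estimator is offered; the binary label bypasses discretization
entirely. The estimator is validated in the test suite against an
independent triple-loop implementation to $10^{-12}$, along with its
identities ($\hat I \ge 0$, symmetry, $\hat I(x,x) = \hat H(x)$, and
monotonicity under bin merging).

### mRMR ranking

With relevance $D(g) = I(g, t)$ against the tissue label $t$ and
redundancy $R(g) = \frac1m \sum_{g_i \in \Omega_s} I(g, g_i)$ against the
$m$ genes already selected, each greedy step moves the candidate
maximizing $D(g) - R(g)$ (the difference/MID form, not the quotient) from
the candidate pool into the ranked list. The first pick has an empty
selected set; its redundancy is defined as 0, reducing step one to pure
maximum relevance.

Ties are resolved by higher relevance, then lexicographically smaller
gene identifier. Scores are compared at 12 significant digits so that
scores which are mathematically equal but computed through different
floating-point summation orders still tie — without this, "exact ties"
(e.g. duplicated genes) would be broken by rounding noise and the ranking
would not be reproducible across BLAS builds. The greedy loop is
validated against a brute-force re-scanning implementation on dozens of
random instances, including the tie rule.

The pairwise MI needed for redundancy is computed lazily — each newly
selected gene is scored against the remaining candidates once — giving
$O(n_\text{select} \cdot n_\text{genes})$ MI evaluations rather than the
full gene × gene table.

### Cross-validated evaluation and the IFS curve

Nested prefixes $S_k$ (the top-$k$ genes, $k = 1 \dots K$) are each
evaluated with a support vector machine under cross-validation:
leave-one-out by default (every cell predicted exactly once by a model
trained on the other $N-1$), or seeded stratified $k$-fold as a scalable
stand-in for large matrices. The curve stores its CV scheme so reports
never silently mix the two. The SVM configuration is the back-end's
default — radial kernel, cost 1, kernel width $1/\text{n features}$,
features standardized on the training fold only — each exposed in
`classifier_spec()`. No class weighting is applied; imbalance is handled
at the metric level by MCC.

The panel is the smallest $k$ attaining the maximal MCC, a parsimony
tie-break: among equally good panels, prefer the cheaper assay. The
reported confusion matrix replays the curve's stored point at the
selected $k$ rather than refitting, so the report is internally
consistent by construction.

### Overlap testing

Panels are compared with reference signatures by the exact upper-tail
hypergeometric probability $P(X \ge o)$ of the observed overlap $o$,
with population = an **explicit** universe size, successes = the
reference set, draws = the panel. The universe is a required parameter
(defaulting, in the pipeline, to the number of genes in the matrix)
because overlap p-values are meaningless — and published ones
irreproducible — when the universe is implicit. Identifiers are
upper-cased before matching; no alias resolution is attempted.

## The synthetic generator

`generate_synthetic()` emulates the statistical shape of a two-class
single-cell experiment with a roughly 2:1 class imbalance: negative
binomial counts (mean `base_mean`, variance $\mu + \alpha\mu^2$ with
overdispersion $\alpha$ = `dispersion`), a minority of informative genes
whose class means are `base_mean`·$2^{\pm \text{lfc}/2}$ (directions
alternating so both over- and under-expressed markers occur), groups of
redundant genes built as Poisson-jittered copies of informative templates
(highly but not perfectly correlated after discretization — the regime
in which the redundancy penalty actually matters), and independent
Bernoulli dropout applied last. Everything is reproducible from one seed,
which is restored on exit so the caller's RNG state is untouched.

The frozen reference scenario (`default_recovery_scenario()`) is 200
tumor + 120 periphery cells, 500 genes, 20 informative at log2 fold
change 2, five redundant groups of three copies, base mean 5,
overdispersion 0.5, dropout 0.3, seed 20200305. These sizes were chosen
once as a realistic desktop-scale analogue of a tumor/periphery
single-cell study — strong but noisy markers, one-in-25 genes
informative, a third of entries zeroed — and are not revisited. On this
scenario the package's acceptance checks require: top-30 mRMR recall of
planted markers ≥ 80%, LOOCV peak MCC ≥ 0.9, panel size ≤ 30.

What the generator does **not** emulate: batch effects, cell-cycle or
subpopulation structure, library-size variation, gene–gene correlation
beyond the planted redundant groups, and the heavy right tail of real
single-cell counts. Passing the recovery checks therefore demonstrates
that the machinery is correct and sensitive under controlled conditions,
not that any particular biological data set will yield a panel this
clean.

One check deserves a note: the generator's class-mean fidelity test
compares the *group* mean of the informative genes sharing a target
(per class and direction) to `(1 - dropout) * target` within 15%. Per-gene
means at these sample sizes have sampling error comparable to the band
itself, so a per-gene check would fail by chance for some gene regardless
of correctness; the group mean makes the band a genuine correctness probe.

## The null control

With `n_informative = 0`, any panel the pipeline selects is pure
selection noise — but not noise centred where a naive permutation of the
*final* predictions would put it, because the observed peak MCC inherits
two selection effects: mRMR ranks genes on the full data, and the peak is
a maximum over $K$ curve points. The control therefore re-runs the entire
pipeline on 20 label-permuted copies of the null data and asks whether
the observed peak MCC lies within mean ± 3 sd of those distributionally
matched replicates. This runs at a scaled-down size (100 genes, 75 + 45
cells, $K = 15$, stratified 5-fold CV) so 21 pipeline executions remain
cheap.

## Numerical and design choices

* **Expression transform.** Whether ranking/classification should see raw
  counts, CPM, or log counts is genuinely open; the pipeline default is
  `log1p` of counts (recorded in every output header), with a flag to
  disable. The discretization cutpoints and SVM geometry both behave
  better on the compressed scale.
* **MCC degeneracy.** Any zero factor in the denominator makes MCC 0/0;
  the package defines it as 0, the common convention for a classifier
  with an empty margin. The numerator is computed in doubles (exact for
  counts up to $2^{26}$-ish products) to avoid integer overflow.
* **Zero-denominator metrics.** Sensitivity/specificity/accuracy raise an
  error naming the empty margin instead of returning `NaN`.
* **Seeds.** One master seed drives the synthetic generator and the CV
  fold shuffle through independent derived streams (`seed`, `seed + 1`),
  so changing the CV plan never changes the data. Fold shuffling and
  generation scope their RNG state and restore the caller's.
* **Problem sizes.** The shipped validation uses the frozen 500 × 320
  scenario with $K = 40$ LOOCV for recovery, and the scaled-down null
  scenario above; both were sized once as comfortable desktop workloads.

## Known limitations

* The plug-in MI estimator is biased upward at small $n$; rankings are
  fine (the bias is shared), but absolute relevance values should not be
  compared across data sets of different size.
* LOOCV over thousands of cells times 100 prefixes is cluster-scale by
  design of the original method; the stratified k-fold stand-in is the
  intended desktop path for full-size matrices.
* The hypergeometric test assumes both sets are drawn from the same
  identifier namespace; it warns on empty intersection but cannot detect
  partial namespace mismatches (e.g. mixed symbol versions).
* No HDF5/loom input, no GEO client, no GO/KEGG databases bundled: the
  overlap machinery is generic over user-supplied GMT files.
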