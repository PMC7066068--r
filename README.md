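# mrmrIFS

Compact biomarker-panel discovery for two-class expression data, built for
the single-cell setting where thousands of sparse, mutually redundant genes
must be reduced to a short, non-redundant diagnostic panel. The motivating
use case is discriminating tumor-core from periphery cells in glioblastoma
scRNA-seq, but nothing in the package is specific to that system: any
genes × cells matrix with a binary per-cell label works.

## The method

Differential-expression tests return hundreds of correlated hits; a usable
biomarker panel needs few genes and little redundancy. The pipeline:

1. **mRMR ranking.** Each gene's expression is discretized (default:
   3 bins at mean ± 0.5 sd) and scored by plug-in mutual information.
   With relevance *D(g) = I(g, t)* against the tissue label *t* and
   redundancy *R(g) = (1/m) Σ<sub>gᵢ∈Ω<sub>s</sub></sub> I(g, gᵢ)*
   against the *m* already-selected genes Ω<sub>s</sub>, the greedy
   step selects

   &nbsp;&nbsp;&nbsp;&nbsp;max<sub>g∈Ω<sub>t</sub></sub> [ *D(g) − R(g)* ]

   (the MID, "difference", variant), producing a ranked list in which a
   gene's position reflects the trade-off between class association and
   redundancy with everything ranked above it.
2. **Incremental feature selection (IFS).** For k = 1…K the top-k prefix
   is evaluated with a cross-validated SVM (radial kernel, the defaults of
   `e1071::svm`) — leave-one-out by default, every cell predicted once by
   a model that never saw it.
3. **Panel selection.** The panel is the smallest k maximizing the
   Matthews correlation coefficient

   &nbsp;&nbsp;&nbsp;&nbsp;MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

   the confusion-matrix correlation that stays honest under the class
   imbalance typical of tumor/periphery designs.
4. **Overlap testing.** Panels are compared against reference signatures
   (GMT files) with an exact upper-tail hypergeometric test over an
   explicit gene universe.

A seeded synthetic generator (negative-binomial counts, planted
informative genes, jittered redundant copies, dropout zeros) provides
ground truth for validating every stage end to end.

## Worked example

```r
library(mrmrIFS)

d <- generate_synthetic(default_recovery_scenario())  # 500 genes, 320 cells
cfg <- run_config(n_select = 100, K = 40, seed = 1)
res <- run_pipeline(d$matrix, d$labels, cfg, output_dir = "run1")

res$peak
#> $k
#> [1] 17
#> $peak_mcc
#> [1] 0.9667435

head(res$ranking, 3)
#>   rank  gene_id relevance redundancy mrmr_score
#> 1    1 INFO_012 0.1529031 0.00000000 0.15290311
#> 2    2 INFO_005 0.1375066 0.03021588 0.10729071
#> 3    3 INFO_004 0.1431661 0.04383555 0.09933053
```

The ranking lists each gene with its relevance (MI with the label, nats),
its mean MI with the genes ranked above it, and their difference — the
score that earned it its position. `res$peak` says the leave-one-out MCC
over nested top-k panels peaked at 0.967 with a 17-gene panel; with 20
informative genes planted, the panel is almost entirely made of true
markers (`mean(res$panel$gene_ids %in% d$truth$informative_gene_ids)`).
`run1/` holds the ranked list, the IFS curve and its plot, the panel, the
metrics report, and the resolved YAML config.

Published confusion-matrix counts can be fed straight into the metric
layer:

```r
cm <- confusion_counts(TP = 2220, FN = 123, FP = 181, TN = 1065)
round(c(mcc = mcc(cm), sens = sensitivity(cm),
        spec = specificity(cm), acc = accuracy(cm)), 3)
#>   mcc  sens  spec   acc
#> 0.812 0.948 0.855 0.915
```

A command-line wrapper with `simulate` / `rank` / `ifs` / `evaluate` /
`overlap` / `run` subcommands is installed at
`inst/scripts/biomarker-pipeline.R`.

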