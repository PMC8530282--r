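---
title: "Isoform-aware neural networks for RNA-seq classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-aware neural networks for RNA-seq classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomapnet)
```

## The problem

Most expression-based classifiers use gene-level summaries and discard
splicing. Yet many exposures and disease states alter *which* isoforms of a
gene are produced while leaving the gene's total output unchanged —
differential isoform usage. Exon-level counts see this signal: when usage
shifts from one isoform to another, the exonic parts private to each isoform
move in opposite directions even though their sum is constant. isomapnet
builds binary classifiers (the motivating application is predicting current
smoking status from blood RNA-seq) that exploit this latent signal by
wiring transcript annotation directly into the network architecture.

## Exonic parts and relationship matrices

The annotation module flattens each gene's transcripts into **exonic
parts**: maximal genomic intervals over which the set of covering
transcripts is constant (the same counting bins used by exon-level
differential-usage tools). Flattening is per gene; overlapping genes are
flattened independently, and exons that overlap *within* one transcript are
merged first with a warning (they are malformed but recoverable).
Coordinates are 1-based inclusive throughout, matching GTF.

Two binary **relationship matrices** connect exon-level features to the
rest of the annotation:

* isoform map \(R \in \{0,1\}^{E \times I}\), \(R_{ij} = 1\) iff exonic
  part \(i\) is contained in isoform \(j\);
* gene map \(R \in \{0,1\}^{E \times G}\) with exactly one 1 per row, in
  the column of the part's gene.

Every row of a valid relationship matrix is nonzero (a part always belongs
to at least one transcript), entries are exactly 0/1, and ids are
duplicate-free. Part ids are `gene:NNN` with three-digit zero padding,
stable and sortable; identical input yields byte-identical output.

## Network layers

The model is a feed-forward binary classifier with three special layers
(plus ordinary dense layers and a single sigmoid output unit):

* **Feature Selection Layer (FSL)** — one non-negative multiplicative
  weight \(w_k \ge 0\) per input feature, output \(x_k w_k\), no bias or
  activation, penalized by \(\lambda \sum_k |w_k|\) with
  \(\lambda = 0.0005\). The weights double as importance scores.
  Non-negativity is enforced by projection (clipping at zero after each
  optimizer step) — the simplest contract satisfying a non-negative
  learnable weight; because a weight parked at zero receives only the
  penalty gradient, it stays at zero.
* **Isoform Map Layer (IML)** — a dense layer whose weights are multiplied
  elementwise by the fixed exon×isoform mask:
  \(h = \mathrm{ReLU}\big((R \odot W)^\top x + b\big)\). Only annotated
  exon→isoform connections are learnable; because the mask enters the
  forward pass, masked gradients are identically zero and no post-hoc
  clamping is needed. The **Gene Map Layer (GML)** is the same construction
  with the exon×gene mask.
* An FSL may appear only as the first layer; a map layer only immediately
  after the input or the FSL; dense widths must decrease strictly along
  the stack (the constraint under which architectures are searched).

Initialization is Glorot-uniform for dense/masked weights, zeros for
biases, ones for FSL weights, all from a caller-supplied seed. Dropout
(global rate 0.2) is applied to hidden dense activations only; applying it
to map-layer outputs was evaluated during development and degraded both
accuracy and interpretability, so the restriction stands. The loss is mean
binary cross-entropy plus the FSL penalty (the penalty participates in
training only, not in cross-validated model selection).

## Preprocessing

The pipeline mirrors standard bulk RNA-seq practice:

1. **Filtering** (`filter_features`): a feature is removed if its mean CPM
   is below 0.2 or it fails CPM > 0.5 in at least 50 subjects; features
   with CPM > 50,000 in at least one but fewer than 50 subjects are removed
   as extreme. CPM uses raw library sizes of the full pre-filter matrix,
   and filtering is applied per input matrix (per feature resolution).
2. **Normalization** (`tmm_factors` / `uq_factors`): trimmed mean of
   M-values with the canonical constants — reference sample by
   75th-percentile CPM closest to the mean, M/A over doubly-expressed
   features, two-sided trims of 0.3 (M) and 0.05 (A), precision-weighted
   mean, factors rescaled to geometric mean one. Upper-quartile
   normalization is available behind the same interface.
3. **log2-CPM** (`log2_cpm`): \(\log_2\!\big((c + 0.5) / (L f + 1) \cdot
   10^6\big)\) with effective library size \(Lf\); the prior count 0.5
   keeps zeros finite.
4. **Quantile normalization** (`quantile_normalize`): every column's sorted
   values are mapped onto the across-sample mean of order statistics; ties
   receive the average of the reference values at the tied ranks.
   Normalization precedes covariate adjustment.
5. **Covariate adjustment** (`adjust_covariates`): per feature, an OLS fit
   on intercept + class label + covariates; only the covariate
   contributions are subtracted, so the class effect is retained.
   Categorical covariates are one-hot encoded with first-level reference.
   The operation is a projection (idempotent).

`split_dataset` partitions samples into train/validation/test sets of
exactly the requested sizes and assigns five near-equal cross-validation
folds within the training set. Both steps are stratified by label: the
per-split class proportions match the global proportion to within one
sample, which reproduces the balanced split characteristics typical of
large cohort studies.

## Training protocol

`train` uses Adam (learning rate 0.0003, \(\beta_1 = 0.9\),
\(\beta_2 = 0.999\), \(\epsilon = 10^{-8}\)), up to 40 epochs, seeded
minibatch reshuffling each epoch, and early stopping: training halts when
validation accuracy has not strictly increased for 10 epochs (ties do not
reset patience) and the parameters from the best epoch are returned.
Accuracy thresholds the sigmoid output at 0.5. The last partial minibatch
of each epoch is used. For the simulated cohorts shipped with the package
(hundreds of samples rather than the thousands of a cohort study) the batch
size is 32, so an epoch contains a comparable number of gradient updates;
all other settings are unchanged.

`architecture_search` is a greedy layer-by-layer grid search: widths 2, 4,
…, 512 for the first dense layer, scored by mean 5-fold cross-validation
accuracy; each added layer searches widths strictly below the previous
layer's, rebuilding the whole network from scratch for every candidate
(earlier layers are reinitialized); the search stops when depth stops
helping. Ties break toward the smaller width (parsimony).

Baselines: `fit_logistic` (Newton–Raphson, optional ridge, gradient
max-norm tolerance \(10^{-8}\), perfect separation detected and warned)
and `fit_elastic_net` (proximal gradient with backtracking on
mean BCE \(+\, \lambda_1\|\beta\|_1 + \lambda_2\|\beta\|^2\), default
weights 0.0005 each; the objective decreases monotonically and slopes are
exactly zero under a dominant L1 penalty).

## Evaluation

`roc_auc` is the Mann–Whitney estimator with midrank tie handling (ties
count one half), computed in \(O(n \log n)\); `roc_curve` sweeps the unique
thresholds and its trapezoidal area equals the estimator exactly.
`delong_test` compares two correlated AUCs on the same samples with
DeLong's structural components; p-values are two-sided normal without
continuity correction. Degenerate zero-variance comparisons return p = 1
when the AUCs are equal and p = 0 with a warning otherwise.

## Interpretation

`saliency_importance` scores feature \(k\) by the mean absolute gradient of
the *pre-sigmoid* logit with respect to \(x_k\) over a reference cohort
(training samples by default), with dropout disabled; differentiating the
logit rather than the probability avoids sigmoid saturation.
`fsl_importance` exports the learned FSL weights. `top_fraction` selects
the \(\lceil qn \rceil\) highest-scoring features (default q = 0.2), ties
at the cutoff broken by lexicographic feature id.

## The synthetic isoform-switch generator

The generator exists so that every claim of the package can be tested
without downloading cohort data. It emulates the hypothesized signal
regime — widespread differential isoform usage with class-invariant
gene-level totals — in its cleanest falsifiable form:

* toy annotation: per gene, each isoform shares `parts_per_isoform - 1`
  exonic parts with all other isoforms and owns one private part;
* class-0 usage per gene is symmetric Dirichlet(5); in effect genes,
  class 1 moves `switch_delta` of usage mass from isoform 1 to isoform 2
  (clamped and renormalized, with a warning, when a draw leaves no room);
* per-gene baselines are log-normal (meanlog \( \log 100\), sdlog 1,
  typical of filtered bulk counts), per-sample library factors log-normal
  with CV 0.2, counts negative binomial with dispersion
  \(\phi = 0.1\) (variance \(\mu + \phi\mu^2\)); a Poisson flag provides
  the \(\phi \to 0\) limit;
* gene counts are emitted as the exact sum of the gene's isoform counts,
  so gene totals of effect genes carry **no** class signal by construction;
  exon-part counts are independent draws at the mask-weighted isoform
  means (length weighting is available but off by default);
* the defaults — 60 genes, 2 isoforms each, 15 effect genes,
  `switch_delta` 0.35, 300 samples per class — define the reference study
  conditions used throughout the tests.

What the generator does *not* emulate: read-level sampling, positional and
GC bias, correlated dispersion structure, per-sample usage variability
(usage is fixed within a class), and overlap between genes. Passing tests
therefore demonstrate that the method recovers pure isoform-usage signal
under idealized counting noise, not that it meets real-data performance.

## Validation workflows and problem sizes

The shipped checks run the full pipeline at sizes chosen to finish in
minutes on one CPU: flattening and mask oracles on 200 random toy genes
(spans under 10 kb, checked base by base), TMM against an independent
reference implementation on 50 random matrices at \(10^{-8}\), DeLong
calibration over 2,000 simulated null datasets of 100 samples, a
paired-bootstrap variance oracle with 20,000 replicates, and the planted
signal study over ten simulated cohorts of 600 samples (exon+IML versus a
gene-level network) plus a no-switch null cohort of 300 samples. The
sparse recovery study uses 120 genes × 5 parts (600 exon features) with 8
effect genes, i.e. 16 informative private parts.

## Known limitations

* **Importance concentration.** In the sparse recovery study the network
  reliably *detects* the planted signal (held-out AUC well above 0.9), but
  its importance scores concentrate on a minimal sufficient subset of
  effect genes: informative exons come in within-gene redundant pairs
  (a usage switch always moves at least two private parts), and once the
  classes are separated the remaining gradient is too small to lift the
  redundant partner while the L1 penalty keeps shrinking it. Top-20%
  recall of planted informative exons therefore saturates near 50% under
  the fixed 40-epoch protocol. Users who need exhaustive feature recovery
  should aggregate importance over several seeds or use univariate
  statistics alongside the network scores.
* Early stopping monitors accuracy, a discrete metric; on small validation
  sets it plateaus quickly and the returned best epoch is coarse.
* The pure-R training engine is intended for the panel-sized feature sets
  the method targets (hundreds to tens of thousands of features), not for
  genome-wide inputs.
* Novel, unannotated isoforms are out of scope: masks come from the
  supplied annotation only.
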