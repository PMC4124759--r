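---
title: "Predicting protein function from InterPro signatures: balancing, Area-2 selection and the weighted-IPR transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from InterPro signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipr2go)
library(dplyr)
```

## The problem

Automated function annotation asks: given which InterPro (IPR) signatures a
protein carries, which Gene Ontology (GO) terms does it have? Both sides are
naturally binary incidence matrices — proteins by IPR signatures and
proteins by GO terms. A single-species extraction has a characteristic
pathology: the matrices are extremely sparse, most IPR columns are nearly
all-zero, and for any single GO term the positives are a small minority
(tens of proteins against thousands of negatives). `ipr2go` treats each GO
term as an independent binary classification problem and implements four
ingredients around that:

1. **Undersampling** (`undersample()`): negatives are drawn uniformly
   without replacement to match the positive count, so a learner cannot win
   by predicting "absent" everywhere.
2. **Area-2 feature selection** (`select_features()`): IPR columns dominated
   by joint absence are dropped using the four-state IPR/GO contingency.
3. **The weighted-IPR transform** (`weighted_transform()`): the binary
   profile of each protein is re-encoded as continuous weights driven by
   feature-feature correlations — the package's core computation.
4. **An evaluation grid** (`run_grid()`): AdaBoost, an RBF SVM and a linear
   SMO-type SVM, each with and without selection and weighting, scored by
   stratified 10-fold cross-validated error.

## The weighted-IPR transform

Pairwise column correlations of the 0/1 matrix are phi coefficients
(`phi_correlation_matrix()`, computed by `stats::cor`). For protein $p$ the
features split into the group $G_1$ it carries and the group $G_0$ it lacks.
Within a group $g$ each member's raw weight sums its correlations with the
other members,

$$ w_i = \sum_{j \in g,\, j \ne i} \operatorname{corr}(i, j), $$

and the group's total mass of $0.5$ is shared proportionally:

$$ \text{weightsum}_i = 0.5 \cdot \frac{w_i}{\sum_{k \in g} w_k}. $$

Three boundary rules complete the definition and each is exercised by the
bundled 5-protein, 6-feature example:

* a **singleton group** gets the full 0.5 (the ratio is taken as 1);
* a **negative group total** is used as-is — individual weights may then be
  negative or exceed 0.5, while the group still sums to 0.5;
* a **zero group total** (only possible when every pairwise correlation in
  the group cancels) falls back to equal shares of 0.5 and flags the
  protein in `zero_denominator`. This choice preserves the conservation
  invariant below; it cannot occur in the worked example.

Zero-variance columns correlate 0 with everything by convention, so they
never perturb the weights of other features.

```{r worked-example}
X <- build_matrix(read_annotations(
  system.file("extdata", "table3_ipr.tsv", package = "ipr2go"), "IPR"))
C <- phi_correlation_matrix(X)
wt <- weighted_transform(X, C, keep_weights = TRUE)
round(wt$values, 4)
```

The invariant worth internalising: for every protein, the weights of each
same-value group sum to exactly 0.5 (up to floating point), so every row
sums to 1 when both groups are present. Correlations are carried at full
floating-point precision; rounding a correlation table to 4 decimals before
transforming shifts the third or fourth decimal of the output, which is why
the reference example tables for this construction are reproduced here to
within one unit in the fourth decimal place rather than digit-for-digit.

The transform is *data-dependent*: the correlation matrix is estimated from
whatever rows it is given. Inside cross-validation the package therefore
re-estimates correlations from each training fold and applies them to the
held-out fold; duplicating a protein row changes other rows' encodings, and
a test documents this deliberate non-invariance. Whether to estimate
correlations on a full matrix or per balanced subset is the caller's
choice — `weighted_transform()` takes `C` explicitly, and `run_grid()`
always fits per training fold to avoid leakage.

## Feature selection

For one IPR column against one GO label vector there are four states:
both present, only the IPR, only the GO, neither
(`four_state_counts()`). Conditioning on IPR status gives four
probabilities whose sum (`conditional_profiles()`) is exactly 2 for any
column observed in both states and less for degenerate columns; in a
balanced per-term subset the overwhelming majority of columns are all-zero
and fall in this degenerate "Area 1". The implemented Area-2 criterion
keeps columns observed in the subset with at least `min_cooccur`
co-occurrences with positive proteins (default 1; a score threshold
`area2_score_min` is also available). The denominator convention
conditions on IPR status — the only reading under which the four ratios
are conditional probabilities; the literal GO-conditioned variant is
exposed via `condition = "go"` for comparison but its ratios can exceed 1.

With very sparse background columns, a floor of 1 co-occurrence admits
chance hits that are then *positively biased* noise for margin learners;
the test suite uses a floor about three standard deviations above the
expected chance co-occurrence (3, for 30 positives at background density
0.02) when asserting that selection does not hurt the SVMs. For real data
the floor should scale with the positive count.

## The evaluation grid

`method_grid()` enumerates the 12 cells. Design choices where the
procedure is genuinely open:

* **SVM vs SMO.** Both are soft-margin SVMs at $C = 1$: the `svm` cell is
  libsvm's RBF machine (`e1071::svm`), the `smo` cell a linear kernel fitted
  by kernlab's SMO-type solver (`kernlab::ksvm`). This keeps the two cells
  distinct in kind (kernel) without inventing unstated hyperparameters.
* **AdaBoost.** Discrete AdaBoost over depth-1 decision stumps, 50 rounds —
  the classical configuration; implemented in the package and scale-free
  per feature, so it runs identically on binary and weighted encodings.
* **Standardisation.** The margin learners see per-column standardised
  features (training-fold mean/sd). The weighted encoding shrinks with
  group size, and kernel machines at fixed $C$ and bandwidth are not
  scale-invariant; AdaBoost stumps are unaffected.
* **Folds.** Stratified 10-fold splits (each class must have at least $k$
  members), seeded; the default 20-positive support cut-off for trainable
  terms keeps at least two positives per fold. Error is the mean of fold
  error rates; `pooled = TRUE` gives the pooled misclassification fraction
  instead (they coincide when fold sizes are equal).
* **Combining selection and weighting.** Selection runs first on the binary
  training columns; the transform is then computed on the selected columns.
* **Leakage.** Preprocessing is fitted strictly inside each training fold.
  `leak_preprocessing = TRUE` exists only to demonstrate the optimistic
  bias of full-data selection, and a test asserts that bias is real.
* **Undersampling repeats.** One draw per term by default; the draw, its
  seed and the protein ids are recorded in the `balanced_dataset` so
  repeated draws with different seeds are trivial to script.

## The synthetic generator

`generate_annotation_data()` emulates the data pathology: background cells
are Bernoulli at `background_density`; each GO term gets exactly
`round(positive_fraction * n_proteins)` positives and owns a disjoint set
of informative columns that are Bernoulli at `assoc_strength` for its
positives. The defaults — 2,000 proteins, 500 IPR columns, 5 terms,
background density 0.01, 10 informative columns per term, association
strength 0.8, positive fraction 0.05 — mirror the shape of a real
single-species extraction (thousands of proteins, thousands of mostly
empty columns, positives a few percent) scaled roughly 2× down so the full
pipeline runs in seconds. The planted truth map makes selector recovery
directly scorable.

What the generator does *not* emulate: correlated domain co-occurrence
(real IPR columns are phylogenetically clustered), hierarchical GO labels,
and annotation noise. Passing tests therefore demonstrate that the
machinery is correct and calibrated, not that real-data error rates will
match any published figure; per-term error on a real extraction depends on
that extraction.

Typical problem sizes used by the test suite: balanced sets of 40–200
proteins, 25–500 features, 10–50 seeds per property.

## Known limitations

* Oversampling is deliberately absent; terms with more positives than
  negatives are rejected.
* The GO graph is ignored: no propagation of predictions to ancestor
  terms, no consistency across terms.
* Per-label independence: no multi-label coupling.
* The zero-denominator fallback and the zero-variance correlation
  convention are conventions; alternative choices would change outputs
  only on degenerate inputs.
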