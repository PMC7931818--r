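---
title: "Methods: reference-based deconvolution with entropy signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-based deconvolution with entropy signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldecon)
```

# The problem and the model

A bulk expression profile is a transcript pool drawn from many cell types at
once. Given a reference matrix $A$ (genes $\times$ $K$ purified cell-type
profiles) and a bulk sample $b$ (genes $\times$ 1), `celldecon` models $b$
as a non-negative linear combination of the reference columns and solves the
constrained least-squares problem

$$\hat{x} = \arg\min_{x \ge 0} \lVert A x - b \rVert_2^2$$

with no intercept and no penalty, reporting fractions
$f_k = \hat{x}_k / \sum_j \hat{x}_j$. Two assumptions matter. First,
additivity: bulk expression of a gene is the abundance-weighted sum of its
expression in the constituent cell types, which holds for linear-scale
(never log-transformed) data. Second, completeness: the reference spans the
cell types actually present; mRNA from types missing in the reference is
absorbed by whichever profiles resemble them. The reported values are mRNA
fractions — the share of transcripts attributable to each cell type — not
cell-count proportions; converting between the two would require per-cell
mRNA content, which the package deliberately does not model.

Raw regression on full transcriptomes is dominated by platform effects,
ubiquitously expressed genes, and magnitude differences. The pipeline
therefore runs four preparation stages, in a fixed order: gene
harmonization, quantile normalization, signature selection, row scaling.

# Quantile normalization

Reference and mixture matrices usually come from different platforms, so the
pipeline maps every column of both matrices onto one target distribution
before anything else is computed. The target is the mean of the sorted
reference columns — the reference's "starting distribution" — so the
reference is only reshaped gently while mixture columns are pulled onto the
reference scale. After the transform, every column of both matrices has
exactly the target as its sorted value vector, and ranks within each column
are untouched.

Two numerical choices are not forced by the construction and were fixed by
design:

* **Target definition.** The mean-of-sorted-columns target is the standard
  quantile-normalization target; an alternative reading ("the pooled values
  of the entire reference") gives nearly identical targets and was not
  adopted.
* **Ties.** Tied values within a column receive the average of the target
  values at the tied rank positions. This keeps the transform deterministic
  and invariant to row permutations. Columns without ties take the exact
  rank-indexed target values.

Normalization happens once, before the matrices are reduced to signature
genes; it is not re-applied after reduction.

# Signature-gene selection

Genes expressed in a cell-type-specific way constrain the regression far
more than ubiquitous genes. Selection works on the normalized reference
only; mixtures are never consulted, so signatures can be reused across
experiments.

Two guards run first. Genes with zero expression in **half or more** of the
cell types are excluded (the boundary is inclusive: with $K$ types, a
zero-count of at least $K/2$ removes the gene), because observed zeros in
purified profiles usually reflect detection limits and make unstable
signatures, particularly for single-cell-derived references. Remaining zeros
are then imputed with the smallest nonzero value of the matrix so that
ratio- and entropy-based scores stay finite. Filtering precedes imputation.

Each surviving gene's expression vector across the $K$ types is converted
into probabilities $p_i = x_i / \sum_j x_j$ and scored. The default score is
Shannon information entropy in bits,

$$H = -\sum_{i=1}^{K} p_i \log_2 p_i,$$

which is $\log_2 K$ for a perfectly uniform gene and approaches 0 as
expression concentrates in a single cell type; low entropy marks a specific
gene. The score is invariant to scaling and to permuting the cell types, and
the logarithm base affects no ranking. Five alternative specificity scores
are provided under their conventional definitions (these conventions are
this package's, chosen for determinism and simplicity): `MeanRat`
(max / mean of the other types), `MeanDiff` (max − mean of others), `ZScore`
((max − mean) / sd over all types), `fsRat` (highest / second highest),
`fsDiff` (highest − second highest). For every method the gene is assigned
to the cell type in which it is maximally expressed; argmax ties go to the
first tied column and the gene is flagged.

Selection uses two parameters. `num_sigs` (default 50) sets the budget: on
average `num_sigs` genes per cell type, i.e. `num_sigs` × $K$ in total.
`min_sigs` (default equal to `num_sigs`) guarantees each cell type that many
of its own best markers; when `min_sigs < num_sigs`, the remaining budget is
filled with the globally best-ranked unselected genes regardless of cell
type, so types with many highly specific genes can exceed the average. The
fill step ranks by the active scoring method's desirability rather than
always by entropy — a deliberate choice so that a single method governs a
run end to end. Score ties at a selection boundary are broken by gene
symbol, making selection independent of input row order.

Defaults (`Entropy`, `num_sigs = 50`, `min_sigs = num_sigs`,
`row_scale_p = 0`) follow the package's cross-reference simulations, where
the 50-gene entropy configuration was the most accurate region of the
parameter space (see the sweep reproduced by `scripts/acceptance.R`).

# Row scaling

Signature genes still span orders of magnitude of expression, and ordinary
least squares weights residuals absolutely, so highly expressed genes would
dominate. Each signature-gene row is therefore transformed as

$$X_{new} = \frac{X_{old} - \min}{\max - \min} \cdot \max{}^{p},$$

with the minimum and maximum taken over that gene's values in **both**
matrices jointly (all $K$ reference columns and all $M$ samples). At the
default $p = 0$ every row spans exactly $[0, 1]$, equalizing gene influence;
at $p = 1$ with a zero minimum the transform is the identity, preserving
magnitudes; intermediate $p$ interpolates. Because the extrema include the
mixture columns, predictions for one sample can depend on which other
samples were submitted in the same batch — this is documented behavior, the
per-run manifest records the batch, and users who need batch-independent
results should submit samples one at a time. Constant rows are mapped to
all-zeros with a warning instead of being dropped, preserving gene
alignment; a constant row contributes nothing to the fit either way.

Note that a convex combination survives the $p = 0$ map exactly: since the
weights sum to one, the per-gene affine offsets cancel, so row scaling
itself introduces no recovery error for true mixtures.

# Regression and fraction normalization

Each sample is fit independently by exact non-negative least squares
(Lawson–Hanson active set, via `pracma::lsqnonneg`), which is the exact
solution of the stated constrained problem; the test suite cross-checks it
against both an exhaustive simplex grid search and `glmnet` run with a lower
bound of zero, no penalty and no intercept. Coefficients are normalized to
fractions by dividing by their sum. If every coefficient is zero (possible
only for pathological inputs such as an all-zero sample), the sample is
flagged degenerate and uniform fractions $1/K$ are reported rather than
failing the batch. Rank-deficient references (e.g. duplicated columns) are
fitted but flagged, since the minimizer may then be non-unique.

Two post-processing helpers operate on fraction tables. Subtype aggregation
sums the fractions of fine-grained subtypes into a parent type (naive +
memory B cells into B cells) and provably preserves row sums. Multi-reference
combination takes, per sample and cell type, the median prediction across
runs with different references (fewer when a cell type is absent from some
references) and renormalizes each sample to sum to one.

# Building references

Two construction rules cover the common sources. From clustered single-cell
data, a pseudo-bulk profile per cluster is the arithmetic mean over member
cells; no library-size normalization is applied before averaging by default
(an option scales each cell to a fixed total first, for data where sequencing
depth varies strongly between clusters). From bulk replicates, profiles of
the same cell type are merged by the per-gene median, with the midpoint
convention for even group sizes. Duplicate gene symbols in input tables are
collapsed by keeping the row with the highest mean (`max_mean`, the default,
suited to transcript-level tables) or by summing rows (`sum`, suited to
counts); both are order-independent.

# The simulator: what it emulates and what it does not

`simulate_reference()` generates a reference of $K$ well-separated cell
types: a shared log-normal baseline (meanlog 4, sdlog 1.2 — a right-skewed,
bulk-like linear-scale distribution spanning roughly four orders of
magnitude) with 8% of genes per cell type upregulated by fold changes of
$2^{U(2,6)}$, i.e. 4–64-fold, the range typical of strong marker genes.
These values were fixed once as field-realistic defaults. The default size
(1200 genes, 10 cell types) keeps the full test suite and the acceptance
script at desk scale — seconds per run — while leaving roughly a hundred
marker genes per cell type, enough for the 50-per-type default budget.

`simulate_mixtures()` draws, per sample, a subset of cell types and
flat-Dirichlet proportions (all concentration parameters 1, uniform on the
simplex — a deliberately uninformative stand-in, since no canonical mixture
prior exists), forms the exact convex combination of reference columns, and
optionally multiplies each value by independent log-normal noise with unit
mean and a requested coefficient of variation (multiplicative, because
expression noise scales with magnitude). Cross-platform stress is emulated
by `perturb_reference()`, which multiplies each gene row of the
*deconvolution* reference by a log-normal factor (default log-sd 0.3),
mimicking per-gene platform biases between the matrix that generated the
data and the matrix used to deconvolve it.

Two realism gaps matter when reading benchmark numbers. First, a noiseless
simulated mixture is an exact convex combination, so its dynamic range is
*compressed* relative to purified profiles (averaging shrinks extremes);
quantile normalization then stretches the mixture's tails back onto the
reference target, and that rank-mapping distortion — not the regression,
which is exact to machine precision without normalization — is what bounds
same-reference recovery accuracy at roughly a mean absolute error of 0.01
on these conditions, as the acceptance harness measures. Real bulk samples
have platform noise of their own, against which the same normalization is
protective; the simulation's clean mixtures make normalization look costlier
than it is in practice. Second, the per-gene log-normal bias model captures
multiplicative platform effects but not probe saturation, missing genes, or
compositional artifacts of real cross-platform pairs, so passing
cross-reference tests demonstrate trend-level behavior (more signatures help;
entropy scoring is competitive), not field accuracy.

# Numerical choices and degenerate inputs

* Quantile normalization requires at least two genes; a single shared gene
  is an error, and fewer than 20 shared genes triggers a warning.
* The gene intersection being empty, an all-zero reference, and an all-zero
  post-filter signature pool are fatal errors rather than silent results.
* All tie-breaks (argmax ties, score ties, median of even groups) are
  deterministic and permutation-invariant; the whole pipeline is
  deterministic given its inputs, and the simulator is reproducible from its
  seed alone.
* Problem sizes used by the shipped tests and acceptance script: references
  of 1200 genes × 10 types, 100–200 simulated mixtures per check, 50 NNLS
  oracle instances at 20 genes, and one 10,000-gene normalization check —
  the package's chosen desk-scale study conditions.

# Known limitations

* No batch correction: combining references measured on different platforms
  into one matrix is explicitly out of scope, and quantile normalization
  alone does not remove gene-level platform biases.
* No regularization, weighting, or confidence intervals on fractions; the
  regression is the exact unpenalized NNLS.
* Fractions are relative within the reference's cell-type universe; an
  abundant cell type missing from the reference biases all reported
  fractions upward.
* Gene symbols are matched case-sensitively with no alias or cross-species
  mapping; inputs must share a gene namespace.
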