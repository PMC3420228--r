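---
title: "Correlation kernels, spectrum repair, and the cross-validation harness"
author: "corrkernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation kernels, spectrum repair, and the cross-validation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrkernels)
```

## The model

Expression classification problems hand us a `p × n` matrix `X` (genes in
rows, samples in columns) with `p` in the thousands and `n` in the tens, and
a binary phenotype per sample. Rather than learn in the p-dimensional
feature space, the kernels here compare samples by their correlation: for
the mean sample `X̄ = rowMeans(X)`,

$$c_{ij} \;=\; \frac{(X_i-\bar X)^\top (X_j-\bar X)}
  {\|X_i-\bar X\|\;\|X_j-\bar X\|}.$$

Writing `T` for the matrix whose columns are `(Xi − X̄)/‖Xi − X̄‖`
(`unit_centered_embedding()`), the correlation matrix is `TᵀT`: a Gram
matrix, hence positive semidefinite with no further assumptions. That single
observation drives the whole package.

Four kernels are derived from `c`:

* **UC** — `exp(−γ(1 − c_ij))`. Equivalently the Hadamard scaling
  `e^{−γ} · e^{∘γc}`; since the entrywise exponential of a PSD matrix is PSD
  (Schur), UC inherits positive semidefiniteness from `corr(X)`. `γ`
  controls how fast similarity decays with correlation distance; the default
  `γ = 1` is the value that dominates the alternatives on the microarray
  benchmarks, and the harness wires the grid `{0.1, 1, 10}` for comparison.
* **PC** — the correlation matrix used directly as the kernel. No
  parameters, PSD automatically; the "parsimonious" choice.
* **CB** — `1 − exp(−c_ij)` entrywise (the "1" is the all-ones matrix; a
  matrix-exponential reading is inconsistent with the entrywise display of
  its scaled form and is rejected). Its diagonal is the constant
  `1 − e^{−1}`, and `CB = (1 − e^{−1})·K1CB` defines the unit-diagonal
  scaled variant. CB is *generally indefinite* — the monotone map
  `1 − e^{−t}` is concave, and concave entrywise maps do not preserve
  positive semidefiniteness.
* **DCB** — CB after spectrum repair: eigendecompose
  `CB = U P Uᵀ`, replace negative eigenvalues by zero (`clip`, the
  denoising transform), reconstruct `U P̃ Uᵀ`. PSD by construction, and the
  identity on CB whenever CB was already PSD.

### The spectrum-repair family

`transform_spectrum()` implements the four standard repairs for an
indefinite similarity matrix, acting on eigenvalues only:

| method    | action                        | parameter |
|-----------|-------------------------------|-----------|
| clip      | `max(p_i, 0)`                 | — |
| flip      | `|p_i|`                       | — |
| diffusion | `exp(t·p_i)`                  | `t > 0`, default 1 |
| shift     | `p_i + η`                     | `η ≥ −p_min`, default exactly `−p_min` (0 on PSD input) |

Design choices worth stating: clip zeroes *strictly negative* eigenvalues
only — near-zero positive eigenvalues are never thresholded, so no spectral
mass is discarded beyond what indefiniteness forces. Diffusion's default
`t = 1` is a convention; the transform is cited in the indefinite-learning
literature without a canonical parameter. Eigenvector orientation is not
canonical, so every invariant in the test suite is stated on eigenvalues or
reconstructed matrices, never on eigenvector signs; repeated eigenvalues are
handled implicitly for the same reason.

### Two centring conventions

The defining formula above subtracts the *common* mean sample from both
columns; the classic Pearson correlation between samples instead centres
each column by its own scalar mean. Both yield symmetric unit-diagonal PSD
matrices, and the literature uses both readings, but they differ
numerically. The package implements both (`correlation_matrix(mode =)`) and
defaults to the common-mean form because the `TᵀT` factorization — the PSD
proof — is exact in that convention. Which convention produced the published
benchmark tables is not recoverable from them; the equicorrelated block in
the synthetic generator exists partly so tests can confirm the two modes
genuinely differ on realistic data.

A sample exactly equal to the centring vector has no direction and its
correlation is undefined; the constructors raise an error naming the sample
rather than silently emitting zeros, which would break the unit diagonal.
All eigenvalue checks symmetrize as `(M + Mᵀ)/2` first, guarding against
accumulated floating-point asymmetry, and correlations are clamped into
`[−1, 1]` after the quotient.

## Classification and the cross-validation protocol

`svm_fit_predict()` trains a soft-margin C-SVM on the train × train
submatrix of a precomputed kernel (kernlab's SMO solver) and predicts
held-out samples from the test × train block. The benchmark protocol is
10 repetitions of stratified 5-fold cross-validation: repetition `r` draws
its fold assignment from seed `seed + r`, each sample is tested exactly once
per repetition, per-run accuracy is pooled over folds (`correct / n`), and
the reported figure is the mean over repetitions. Stratification is the
default because the benchmark datasets are imbalanced (e.g. 11 vs 27);
plain 5-fold assignment risks single-class training folds, which the SVM
must reject.

Open protocol details were fixed as follows, as this package's own
conventions:

* **SVM cost** `C = 1` (the libsvm default), exposed as a flag — published
  benchmark accuracies do not state it, which is one reason they are only
  approximately reproducible.
* **Fold handling of the kernel** — `transductive` (default): correlation,
  kernel and denoising are computed once on all `n` samples and folds slice
  the matrix; this matches benchmarking practice with precomputed n × n
  kernels. `inductive`: the mean sample and norms come from training columns
  only, test columns are centred with the training mean, and for DCB the
  cross-kernel block is projected through `U D Uᵀ` (`D_ii = 1` iff
  eigenvalue i was retained) — the out-of-sample extension appropriate for
  genuine deployment. On strong-signal synthetic data the two modes agree to
  within a few accuracy points; results are labelled with their mode.
* **KNN** — Euclidean distance on feature columns, `K ∈ {1, 5, 10}`; a tied
  vote decrements `K` until strict majority, equal distances resolve to the
  lower sample index. Fully deterministic.
* **Decision tree** — CART with Gini impurity, unpruned (`cp = 0`,
  `minsplit = 2`), via rpart. Deterministic given the data.

`corrsvm()` packages the inductive machinery as a standard R model object:
fit once, then `predict()` embeds new samples into the trained (possibly
repaired) kernel geometry.

## The synthetic generator

`generate_two_class()` emulates the standardized microarray matrices the
kernels target: `n_informative` of `p` Gaussian features receive a class
mean shift of `effect_size` standard deviations (±δ/2 per class), optionally
sharing a per-sample latent factor so the informative block is
equicorrelated at `block_correlation`; everything is then passed through the
same instance-wise-then-feature-wise standardization applied to the public
benchmark files (population divisor, matching "standard normal"
normalization; a flag switches to the n−1 convention). Defaults mirror the
colon-tumour benchmark's shape — 2000 genes, 40 vs 22 samples — with a
50-gene informative block at δ = 1, ρ = 0.3, values a practitioner would
call a moderate, realistic signal.

What the generator does *not* emulate: heavy-tailed intensity noise, batch
effects, missingness, or count data. Passing tests on it therefore
demonstrates correctness of the constructions and the harness, and signal
recovery under the stated Gaussian conditions — not performance claims on
real tumour panels. `generate_indefinite_case()` guarantees a correlation
matrix whose CB kernel has a negative eigenvalue (random low-rank draws,
with the alternating-sign matrix `0.999·ssᵀ + 0.001·I` as a deterministic
fallback), so the repair path is always exercisable.

## Numerical choices and problem sizes

Tolerances follow the quantity's conditioning: exact identities
(factorization, Hadamard/scaling forms, oracle equivalence) are asserted at
`1e−12`; eigendecomposition round-trips at `1e−8`; PSD certification accepts
eigenvalues down to `−1e−8` for constructions that are PSD in exact
arithmetic and `−1e−10` for clip output, which is PSD up to one
reconstruction's rounding. `psd_certified` on a kernel object is always the
result of an actual eigenvalue check, never an assumption, so a
pathologically conditioned input is caught at construction.

The test-suite and acceptance problem sizes — 200 random matrices with
`p ∈ [3, 50]`, `n ∈ [2, 30]` for certification; `p = 500`, `n = 60`, a
20-feature δ = 2 block for signal recovery; the colon-shaped default for
dominant-eigenvalue reporting — were chosen as the smallest scales at which
each property is informative, and run in seconds.

## Known limitations

* The published benchmark accuracies on the three public tumour datasets
  depend on an unstated SVM cost and fold scheme, so they can be bracketed
  but not reproduced digit-for-digit; the harness reproduces the protocol
  and exposes every free parameter instead. The corresponding external-data
  checks require the libsvm-hosted files, which the package does not bundle.
* Binary classification only; no multiclass reduction, no probability
  calibration, no feature selection, no kernel combination.
* `K1CB` is provided for the scaling identity and is not evaluated as a
  standalone kernel.
* Dense eigensolvers only — appropriate for the few-hundred-sample regime
  these kernels address.
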