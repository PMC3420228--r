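Package: corrkernels
Title: Correlation-Derived Kernels for Support Vector Machine Classification
    of Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sample-by-sample similarity kernels from the correlation
    structure of high-dimensional expression matrices (p features, n samples,
    p >> n) and classifies samples with a precomputed-kernel support vector
    machine. Implements the usual correlation (UC) kernel exp(-gamma*(1-corr)),
    the parsimonious correlation (PC) kernel corr(X) itself, the
    correlation-based (CB) kernel 1-exp(-corr) together with its scaled form,
    and the denoised correlation-based (DCB) kernel obtained by repairing the
    CB spectrum. Provides the full spectrum-repair family for indefinite
    similarity matrices (clip, flip, diffusion, shift), positive-semidefinite
    certification, a repeated stratified k-fold cross-validation harness with
    k-nearest-neighbour and decision-tree baselines, a reader/writer for the
    libsvm sparse sample format, and a generator of two-class synthetic
    expression data with known signal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    kernlab,
    rpart,
    stats,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
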