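# Synthetic two-class expression data with known signal structure, and a
# guaranteed witness that exercises the indefinite-kernel repair path.

#' Specify a synthetic two-class expression dataset
#'
#' Describes a p x n Gaussian expression matrix (p >> n) in which
#' `n_informative` features carry a between-class mean shift of
#' `effect_size` standard deviations (+/- effect_size/2 per class) and may be
#' mutually equicorrelated at `block_correlation`; the remaining features are
#' independent noise. Defaults mirror the shape of the classic colon-tumour
#' microarray benchmark: 2000 genes, 40 positive vs 22 negative samples, a
#' modest informative block.
#'
#' @param n_pos,n_neg samples per class (positive class is labelled +1).
#' @param p number of features (genes).
#' @param n_informative number of mean-shifted features, in \[0, p\].
#' @param effect_size between-class mean shift delta, in units of the noise
#'   standard deviation (nonnegative; 0 gives null data).
#' @param block_correlation equicorrelation rho in \[0, 1) among the
#'   informative features.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_pos = 40, n_neg = 22, p = 2000,
                           n_informative = 50, effect_size = 1,
                           block_correlation = 0.3, seed = 0) {
  stopifnot(n_pos >= 1, n_neg >= 1, p >= 2,
            n_informative >= 0, n_informative <= p,
            effect_size >= 0,
            block_correlation >= 0, block_correlation < 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 p = as.integer(p), n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class expression matrix
#'
#' Draws the dataset described by a [synthetic_spec()]: informative features
#' are Normal(+delta/2, 1) in the positive class and Normal(-delta/2, 1) in
#' the negative class, sharing a per-sample latent factor when
#' `block_correlation` rho > 0 (feature i = sqrt(rho) * factor +
#' sqrt(1-rho) * noise, giving pairwise correlation rho within the block);
#' uninformative features are i.i.d. standard normal. The matrix is then
#' passed through [zscore_samples()] and [zscore_features()], mirroring the
#' instance-wise-then-feature-wise standardization used on the microarray
#' benchmarks.
#'
#' @param spec a `"synthetic_spec"`.
#' @return list with `x` (p x n standardized matrix, positive-class columns
#'   first), `labels` (+1/-1) and `spec`.
#' @export
generate_two_class <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must come from synthetic_spec()")
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  x <- matrix(rnorm(spec$p * n), spec$p, n)
  ni <- spec$n_informative
  if (ni > 0) {
    rho <- spec$block_correlation
    if (rho > 0) {
      shared <- rnorm(n)   # latent per-sample factor shared by the block
      x[seq_len(ni), ] <- sqrt(rho) * matrix(shared, ni, n, byrow = TRUE) +
        sqrt(1 - rho) * x[seq_len(ni), , drop = FALSE]
    }
    shift <- spec$effect_size / 2
    x[seq_len(ni), seq_len(spec$n_pos)] <- x[seq_len(ni), seq_len(spec$n_pos)] + shift
    x[seq_len(ni), spec$n_pos + seq_len(spec$n_neg)] <-
      x[seq_len(ni), spec$n_pos + seq_len(spec$n_neg)] - shift
  }
  x <- zscore_features(zscore_samples(x))
  list(x = x, labels = c(rep(1, spec$n_pos), rep(-1, spec$n_neg)), spec = spec)
}

#' A correlation matrix whose CB kernel is indefinite
#'
#' Produces a valid n x n correlation matrix (symmetric, unit diagonal, PSD)
#' whose correlation-based kernel `1 - exp(-corr)` has at least one negative
#' eigenvalue, guaranteeing the spectrum-repair path is exercised. Random
#' low-dimensional draws (3 features) are searched first; if none is
#' indefinite the deterministic alternating-sign witness
#' `0.999 * s %o% s + 0.001 * I` with `s = (-1)^(0:(n-1))` is used (for n = 2
#' this is the strongly anticorrelated pair, always a witness).
#'
#' @param n number of samples, >= 2.
#' @param seed integer seed for the random search.
#' @return an n x n `"corr_matrix"`.
#' @export
generate_indefinite_case <- function(n = 2, seed = 0) {
  if (n < 2) stop("n must be at least 2")
  set.seed(seed)
  for (i in seq_len(50L)) {
    x <- matrix(rnorm(3 * n), 3, n)
    cc <- tryCatch(correlation_matrix(x), error = function(e) NULL)
    if (!is.null(cc) && min_eigenvalue(unclass_kernel(cb_kernel(cc))) < -1e-6) {
      return(cc)
    }
  }
  s <- (-1)^(0:(n - 1))
  cc <- 0.999 * tcrossprod(s)
  diag(cc) <- 1
  structure(cc, class = c("corr_matrix", "matrix", "array"), mode = "synthetic")
}
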