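# Sample-by-sample correlation of a feature-by-sample matrix, and its
# separable unit-norm embedding T with t(T) %*% T == corr(X).

#' Mean sample vector
#'
#' The length-p average of the sample columns: entry j is the mean of feature
#' j over all n samples. This is the common centring vector used by the
#' default (`"common-mean"`) correlation mode.
#'
#' @param x p x n numeric matrix, samples as columns.
#' @return numeric vector of length p.
#' @export
mean_sample <- function(x) {
  .check_sample_matrix(x)
  rowMeans(x)
}

#' Sample-by-sample correlation matrix
#'
#' Computes the n x n matrix of correlations between the sample columns of a
#' p x n expression matrix. Two centring conventions are supported:
#'
#' * `"common-mean"` (default): every column is centred by the single mean
#'   sample vector \eqn{\bar{X}} before the cosine is taken,
#'   \deqn{c_{ij} = \frac{(X_i-\bar X)^\top (X_j-\bar X)}
#'     {\|X_i-\bar X\|\,\|X_j-\bar X\|}.}
#'   This is the centred cosine similarity; it admits the factorization
#'   `corr = t(T) %*% T` with `T` from [unit_centered_embedding()], which is
#'   what makes the matrix provably positive semidefinite.
#' * `"pearson"`: each column is centred by its own scalar mean (the classic
#'   Pearson correlation between sample vectors, `stats::cor` of the columns).
#'
#' Both conventions give a symmetric unit-diagonal PSD matrix with entries in
#' \[-1, 1\]; they differ numerically and the common-mean form is the one the
#' kernel constructions are defined on.
#'
#' @param x p x n numeric matrix, samples as columns (p >= 2, n >= 2).
#' @param mode centring convention, `"common-mean"` or `"pearson"`.
#' @return an n x n matrix of class `"corr_matrix"` with attribute
#'   `"mode"` recording the convention; unit diagonal.
#' @examples
#' x <- cbind(c(1, 2, 3), c(2, 4, 6))
#' correlation_matrix(x)            # exact anticorrelation off-diagonal
#' @export
correlation_matrix <- function(x, mode = c("common-mean", "pearson")) {
  mode <- match.arg(mode)
  .check_sample_matrix(x)
  xc <- if (mode == "common-mean") x - rowMeans(x) else sweep(x, 2L, colMeans(x), "-")
  d <- sqrt(colSums(xc^2))
  zero <- which(d == 0)
  if (length(zero)) {
    what <- if (mode == "common-mean") "equals the mean sample" else "is constant"
    stop("sample ", zero[1], " ", what, "; correlation undefined")
  }
  cc <- crossprod(xc) / tcrossprod(d)
  cc <- (cc + t(cc)) / 2         # guard against accumulated asymmetry
  diag(cc) <- 1
  cc[cc > 1] <- 1                # clamp fp overshoot at the boundary
  cc[cc < -1] <- -1
  structure(cc, class = c("corr_matrix", "matrix", "array"), mode = mode)
}

#' Unit-norm centred embedding of the samples
#'
#' Returns the p x n matrix `T` whose column i is
#' \eqn{(X_i - \bar X)/\|X_i - \bar X\|}: the common-mean-centred sample
#' scaled to unit Euclidean norm. By construction
#' `crossprod(T)` equals `correlation_matrix(x, "common-mean")`, which is the
#' explicit feature map certifying that the correlation matrix — and hence the
#' parsimonious correlation kernel — is positive semidefinite.
#'
#' @inheritParams correlation_matrix
#' @return p x n numeric matrix with unit-norm columns.
#' @export
unit_centered_embedding <- function(x) {
  .check_sample_matrix(x)
  xc <- x - rowMeans(x)
  d <- sqrt(colSums(xc^2))
  zero <- which(d == 0)
  if (length(zero)) {
    stop("sample ", zero[1], " equals the mean sample; no direction to embed")
  }
  sweep(xc, 2L, d, "/")
}

# Accept either a corr_matrix or a plain symmetric unit-diagonal matrix and
# return validated plain values; all kernel constructors funnel through here.
.corr_values <- function(cc, tol = 1e-8) {
  if (!is.matrix(cc) || !is.numeric(cc)) stop("correlation input must be a numeric matrix")
  if (nrow(cc) != ncol(cc)) stop("correlation matrix must be square")
  if (max(abs(cc - t(cc))) > tol) stop("correlation matrix is not symmetric")
  if (max(abs(diag(cc) - 1)) > tol) stop("correlation matrix must have unit diagonal")
  if (max(abs(cc)) > 1 + tol) stop("correlation entries must lie in [-1, 1]")
  v <- (unclass(cc) + t(unclass(cc))) / 2
  attributes(v) <- list(dim = dim(v))
  v
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("Sample correlation matrix (%d x %d, %s centring)\n",
              nrow(x), ncol(x), attr(x, "mode")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6L) cat("... (", nrow(x), " samples)\n", sep = "")
  invisible(x)
}
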