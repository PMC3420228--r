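# Eigendecomposition, the spectrum-repair transform family for indefinite
# similarity matrices, and PSD certification.

#' Eigendecomposition of a symmetric matrix
#'
#' Symmetrizes the input as (m + t(m))/2, solves with the symmetric
#' eigensolver and returns eigenvalues sorted in descending order with the
#' matching orthonormal eigenvectors as columns.
#'
#' @param m square numeric matrix, symmetric within `tol`.
#' @param tol maximum allowed asymmetry, default 1e-8.
#' @return an object of class `"kernel_spectrum"`: a list with `values`
#'   (descending eigenvalues) and `vectors` (orthonormal columns, column i
#'   paired with `values[i]`).
#' @seealso [transform_spectrum()], [reconstruct()]
#' @export
eigendecompose <- function(m, tol = 1e-8) {
  .check_symmetric(m, tol)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  structure(list(values = e$values, vectors = e$vectors),
            class = "kernel_spectrum")
}

#' Repair an indefinite spectrum
#'
#' Applies one of the four standard eigenvalue transforms used to turn an
#' indefinite similarity matrix into a positive semidefinite kernel:
#'
#' * `clip` (denoise): negative eigenvalues are set to zero, nonnegative ones
#'   kept — the transform behind the DCB kernel. Strictly negative values
#'   only; small positive eigenvalues are never touched.
#' * `flip`: eigenvalues are replaced by their absolute values.
#' * `diffusion`: eigenvalues are exponentiated, \eqn{\tilde p_i = e^{t p_i}}
#'   with diffusion time `param` = t > 0 (default 1).
#' * `shift`: a constant `param` = \eqn{\eta \ge \max(0, -p_n)} is added to
#'   every eigenvalue; the default is exactly \eqn{-p_n} when the smallest
#'   eigenvalue is negative, else 0 (identity on PSD spectra).
#'
#' Eigenvectors are untouched, so the repaired matrix from [reconstruct()]
#' shares the source's eigenbasis.
#'
#' @param s a `"kernel_spectrum"` from [eigendecompose()].
#' @param method `"clip"`, `"flip"`, `"diffusion"` or `"shift"`.
#' @param param diffusion time t (> 0) or shift eta; ignored by clip/flip.
#' @return a `"kernel_spectrum"` with transformed (still descending)
#'   eigenvalues.
#' @export
transform_spectrum <- function(s, method = c("clip", "flip", "diffusion", "shift"),
                               param = NULL) {
  method <- match.arg(method)
  if (!inherits(s, "kernel_spectrum")) stop("s must come from eigendecompose()")
  p <- s$values
  pt <- switch(method,
    clip = pmax(p, 0),
    flip = abs(p),
    diffusion = {
      t <- if (is.null(param)) 1 else param
      if (t <= 0) stop("diffusion time must be > 0, got ", t)
      exp(t * p)
    },
    shift = {
      pn <- p[length(p)]
      eta <- if (is.null(param)) max(0, -pn) else param
      if (eta < -pn) {
        stop("shift eta = ", eta, " is below -min(eigenvalue) = ", -pn,
             "; result would remain indefinite")
      }
      p + eta
    }
  )
  ord <- order(pt, decreasing = TRUE)
  structure(list(values = pt[ord], vectors = s$vectors[, ord, drop = FALSE]),
            class = "kernel_spectrum")
}

#' Reassemble a matrix from its spectrum
#'
#' Returns `U diag(p) t(U)` for a `"kernel_spectrum"`; the output is
#' symmetrized so it is exactly symmetric.
#'
#' @param s a `"kernel_spectrum"`.
#' @return symmetric numeric matrix.
#' @export
reconstruct <- function(s) {
  if (!inherits(s, "kernel_spectrum")) stop("s must come from eigendecompose()")
  m <- s$vectors %*% (s$values * t(s$vectors))
  (m + t(m)) / 2
}

#' Smallest and largest eigenvalues; PSD test
#'
#' `min_eigenvalue()` and `dominant_eigenvalue()` return the extreme
#' eigenvalues of a symmetric matrix; `is_psd()` reports whether the smallest
#' eigenvalue is at least `-tol`. The dominant eigenvalue of a kernel matrix
#' summarizes how much similarity mass its leading component carries, and is
#' the quantity used to compare the PC and DCB kernels on a dataset.
#'
#' @param m square numeric matrix, symmetric within 1e-8.
#' @param tol nonnegative slack for `is_psd`, default 1e-8.
#' @return a single eigenvalue (`min_eigenvalue`, `dominant_eigenvalue`) or a
#'   logical (`is_psd`).
#' @export
min_eigenvalue <- function(m) {
  .check_symmetric(m)
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname min_eigenvalue
#' @export
dominant_eigenvalue <- function(m) {
  .check_symmetric(m)
  max(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname min_eigenvalue
#' @export
is_psd <- function(m, tol = 1e-8) {
  min_eigenvalue(m) >= -tol
}

.check_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("input must be square, got ", nrow(m), " x ", ncol(m))
  if (max(abs(m - t(m))) > tol) {
    stop("input is asymmetric beyond tolerance ", tol)
  }
  invisible(m)
}

#' @export
print.kernel_spectrum <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("Spectrum of a %d x %d symmetric matrix\n", n, n))
  k <- min(6L, n)
  cat("eigenvalues:", paste(sprintf("%.4f", x$values[seq_len(k)]), collapse = " "),
      if (n > k) "..." else "", "\n")
  neg <- sum(x$values < 0)
  cat(sprintf("negative eigenvalues: %d (min %.4g)\n", neg, min(x$values)))
  invisible(x)
}
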