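# Classed model interface: fit a correlation-kernel SVM once on a training
# matrix and predict new samples through the inductive out-of-sample
# extension of the (possibly repaired) kernel.

#' Fit a correlation-kernel SVM
#'
#' Trains a soft-margin C-SVM on one of the correlation-derived kernels (PC,
#' UC, CB or DCB) built from the training samples, and stores everything
#' needed to embed new samples into the same kernel geometry: the training
#' mean sample, the centred column norms, and — for DCB — the clipped
#' eigenbasis through which out-of-sample similarity columns are projected.
#'
#' @param x p x n numeric training matrix, samples as columns.
#' @param y length-n labels over \{+1, -1\} (or any two-valued coding; the
#'   larger value maps to +1), both classes present.
#' @param kernel `"dcb"` (default), `"pc"`, `"uc"` or `"cb"`. CB is accepted
#'   for completeness but is generally indefinite; a warning is raised when
#'   its training matrix is.
#' @param gamma UC decay rate (ignored by the other kernels).
#' @param cost soft-margin cost C > 0.
#' @param transform spectrum repair for DCB (default `"clip"`).
#' @param corr_mode centring convention, see [correlation_matrix()].
#' @return an object of class `"corrsvm"` with `print`, `summary`, `predict`
#'   and `fitted` methods.
#' @examples
#' \donttest{
#' d <- generate_two_class(synthetic_spec(n_pos = 15, n_neg = 15, p = 200,
#'                                        n_informative = 15, effect_size = 2,
#'                                        seed = 7))
#' fit <- corrsvm(d$x, d$labels, kernel = "dcb")
#' fit
#' mean(fitted(fit) == d$labels)
#' }
#' @export
corrsvm <- function(x, y, kernel = c("dcb", "pc", "uc", "cb"),
                    gamma = 1, cost = 1, transform = "clip",
                    corr_mode = c("common-mean", "pearson")) {
  kernel <- match.arg(kernel)
  corr_mode <- match.arg(corr_mode)
  .check_sample_matrix(x)
  if (length(y) != ncol(x)) stop("y length must equal ncol(x)")
  y <- .map_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (cost <= 0) stop("cost must be positive")

  center <- if (corr_mode == "common-mean") rowMeans(x) else NULL
  xc <- if (is.null(center)) sweep(x, 2L, colMeans(x), "-") else x - center
  norms <- sqrt(colSums(xc^2))
  if (any(norms == 0)) stop("a training sample has no direction after centring")
  cc <- correlation_matrix(x, mode = corr_mode)

  spectrum <- NULL
  keep <- NULL
  kmat <- switch(kernel,
    pc = pc_kernel(cc),
    uc = uc_kernel(cc, gamma),
    cb = cb_kernel(cc),
    dcb = dcb_kernel(cc, transform))
  if (kernel == "dcb") {
    spectrum <- eigendecompose(unclass_kernel(cb_kernel(cc)))
    keep <- spectrum$values >= 0
  }
  if (kernel == "cb" && !attr(kmat, "psd_certified")) {
    warning("CB training kernel is indefinite (min eigenvalue ",
            signif(min_eigenvalue(unclass_kernel(kmat)), 3),
            "); consider kernel = \"dcb\"")
  }

  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(unclass_kernel(kmat)),
                       factor(y, levels = c(-1, 1)),
                       type = "C-svc", C = cost, kernel = "matrix")
  obj <- structure(list(kernel = kernel, gamma = gamma, cost = cost,
                        transform = if (kernel == "dcb") transform else NULL,
                        corr_mode = corr_mode,
                        x = x, y = y, center = center, norms = norms,
                        train_kernel = kmat, spectrum = spectrum, keep = keep,
                        svm = fit, n = ncol(x), p = nrow(x)),
                   class = "corrsvm")
  obj$fitted <- predict(obj, x)
  obj
}

# Cross-kernel block (m new samples x n training samples) under the fitted
# kernel geometry.
.cross_kernel <- function(object, newdata) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (nrow(newdata) != object$p) {
    stop("newdata must have ", object$p, " feature rows, got ", nrow(newdata))
  }
  xc_tr <- if (is.null(object$center)) {
    sweep(object$x, 2L, colMeans(object$x), "-")
  } else object$x - object$center
  xc_new <- if (is.null(object$center)) {
    sweep(newdata, 2L, colMeans(newdata), "-")
  } else newdata - object$center
  dn <- sqrt(colSums(xc_new^2))
  if (any(dn == 0)) stop("a new sample has no direction after centring")
  cc <- crossprod(xc_new, xc_tr) / tcrossprod(dn, object$norms)
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  switch(object$kernel,
         pc = cc,
         uc = exp(-object$gamma * (1 - cc)),
         cb = 1 - exp(-cc),
         dcb = {
           k <- 1 - exp(-cc)
           if (identical(object$transform, "clip")) {
             u <- object$spectrum$vectors[, object$keep, drop = FALSE]
             k %*% (u %*% t(u))
           } else k
         })
}

#' Predict class labels for new samples
#'
#' Embeds the columns of `newdata` into the fitted kernel geometry (inductive
#' out-of-sample extension) and evaluates the trained SVM.
#'
#' @param object a `"corrsvm"` fit.
#' @param newdata p x m matrix of new samples as columns; defaults to the
#'   training matrix.
#' @param type `"class"` for \{+1, -1\} labels, `"decision"` for the signed
#'   SVM decision values.
#' @param ... unused.
#' @return numeric vector of length m.
#' @export
predict.corrsvm <- function(object, newdata = NULL,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  kc <- .cross_kernel(object, newdata)
  sv <- kernlab::SVindex(object$svm)
  km <- kernlab::as.kernelMatrix(kc[, sv, drop = FALSE])
  if (type == "decision") {
    as.numeric(kernlab::predict(object$svm, km, type = "decision"))
  } else {
    as.numeric(as.character(kernlab::predict(object$svm, km)))
  }
}

#' @export
fitted.corrsvm <- function(object, ...) object$fitted

#' @export
residuals.corrsvm <- function(object, ...) object$y - object$fitted

#' @export
print.corrsvm <- function(x, ...) {
  cat(sprintf("Correlation-kernel SVM (%s kernel%s)\n",
              toupper(x$kernel),
              if (x$kernel == "uc") sprintf(", gamma = %g", x$gamma)
              else if (x$kernel == "dcb") sprintf(", %s repair", x$transform)
              else ""))
  cat(sprintf("  %d samples x %d features, cost C = %g, %s centring\n",
              x$n, x$p, x$cost, x$corr_mode))
  cat(sprintf("  support vectors: %d | training accuracy: %.4f\n",
              length(kernlab::SVindex(x$svm)), mean(x$fitted == x$y)))
  invisible(x)
}

#' @export
summary.corrsvm <- function(object, ...) {
  k <- unclass_kernel(object$train_kernel)
  s <- eigen((k + t(k)) / 2, symmetric = TRUE, only.values = TRUE)$values
  out <- list(fit = object,
              dominant_eigenvalue = max(s),
              min_eigenvalue = min(s),
              n_negative_eigenvalues = sum(s < 0),
              psd_certified = attr(object$train_kernel, "psd_certified"),
              class_counts = table(object$y),
              training_accuracy = mean(object$fitted == object$y))
  class(out) <- "summary.corrsvm"
  out
}

#' @export
print.summary.corrsvm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  class counts: +1: %d, -1: %d\n",
              x$class_counts[["1"]], x$class_counts[["-1"]]))
  cat(sprintf("  kernel spectrum: dominant %.4f, min %.4g, %d negative; PSD: %s\n",
              x$dominant_eigenvalue, x$min_eigenvalue,
              x$n_negative_eigenvalues, x$psd_certified))
  invisible(x)
}
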