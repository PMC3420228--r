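# Precomputed-kernel SVM classification, KNN and decision-tree baselines,
# and the repeated stratified k-fold cross-validation harness.

#' Describe a classification method for the benchmark harness
#'
#' Bundles a method name with exactly the parameters that method uses:
#' `gamma` for UC, `k` for KNN, `svm_cost` and `kernel_mode` for the kernel
#' methods, `transform` for DCB. Irrelevant parameters are dropped so two
#' specs compare equal iff they describe the same experiment.
#'
#' @param name `"DT"`, `"KNN"`, `"UC"`, `"PC"` or `"DCB"`.
#' @param gamma UC decay rate (default 1).
#' @param k number of neighbours for KNN (default 5).
#' @param svm_cost soft-margin cost C for the kernel methods (default 1).
#' @param transform spectrum repair for DCB (default `"clip"`).
#' @param kernel_mode `"transductive"` (kernel built once on all samples,
#'   folds slice it — the convention matching n x n kernel benchmarking) or
#'   `"inductive"` (centring, correlation and denoising refit from training
#'   columns only; test columns projected in).
#' @param corr_mode centring convention passed to [correlation_matrix()].
#' @return a `"method_spec"` list.
#' @export
method_spec <- function(name = c("DT", "KNN", "UC", "PC", "DCB"),
                        gamma = 1, k = 5, svm_cost = 1, transform = "clip",
                        kernel_mode = c("transductive", "inductive"),
                        corr_mode = c("common-mean", "pearson")) {
  name <- match.arg(name)
  kernel_mode <- match.arg(kernel_mode)
  corr_mode <- match.arg(corr_mode)
  spec <- list(name = name)
  if (name == "KNN") {
    if (k < 1) stop("k must be a positive integer")
    spec$k <- as.integer(k)
  }
  if (name %in% c("UC", "PC", "DCB")) {
    if (svm_cost <= 0) stop("svm_cost must be positive")
    spec$svm_cost <- svm_cost
    spec$kernel_mode <- kernel_mode
    spec$corr_mode <- corr_mode
  }
  if (name == "UC") {
    if (gamma <= 0) stop("gamma must be positive")
    spec$gamma <- gamma
  }
  if (name == "DCB") spec$transform <- transform
  structure(spec, class = "method_spec")
}

#' @export
format.method_spec <- function(x, ...) {
  switch(x$name,
         UC = sprintf("UC(gamma=%g)", x$gamma),
         KNN = sprintf("KNN(k=%d)", x$k),
         DCB = if (identical(x$transform, "clip")) "DCB" else
           sprintf("DCB(%s)", x$transform),
         x$name)
}

#' @export
print.method_spec <- function(x, ...) {
  cat("method:", format(x))
  if (!is.null(x$kernel_mode)) cat(" |", x$kernel_mode, "kernel, cost", x$svm_cost)
  cat("\n")
  invisible(x)
}

#' Train a precomputed-kernel SVM on a fold and predict the held-out samples
#'
#' Fits a soft-margin C-SVM on the `train_idx` x `train_idx` submatrix of a
#' full n x n kernel and predicts labels for `test_idx` from the
#' `test_idx` x `train_idx` block. The solver is kernlab's SMO; results are
#' deterministic for fixed inputs. If the training submatrix is indefinite
#' beyond -1e-6 a warning is issued and the solve proceeds (SMO tolerates
#' slight indefiniteness).
#'
#' @param kernel_full n x n kernel matrix covering all samples
#'   (a `"corr_kernel"` or plain symmetric matrix).
#' @param labels length-n vector over \{+1, -1\}.
#' @param train_idx,test_idx disjoint nonempty index vectors into 1..n;
#'   training indices must contain both classes.
#' @param cost soft-margin cost C > 0.
#' @return numeric vector of predicted \{+1, -1\} labels, one per `test_idx`.
#' @export
svm_fit_predict <- function(kernel_full, labels, train_idx, test_idx, cost = 1) {
  k <- unclass_kernel(kernel_full)
  n <- nrow(k)
  if (length(labels) != n) stop("labels length must match kernel dimension")
  if (!length(train_idx) || !length(test_idx)) stop("empty train or test fold")
  if (length(intersect(train_idx, test_idx))) stop("train and test folds overlap")
  if (length(unique(labels[train_idx])) < 2L) {
    stop("training fold contains a single class; stratify the folds")
  }
  ktr <- k[train_idx, train_idx, drop = FALSE]
  me <- min_eigenvalue(ktr)
  if (me < -1e-6) {
    warning(sprintf("training kernel submatrix indefinite (min eigenvalue %.3g); proceeding", me))
  }
  .svm_train_predict(ktr, labels[train_idx],
                     k[test_idx, train_idx, drop = FALSE], cost)
}

# Fit on a train kernel, predict from a test x train cross-kernel block.
.svm_train_predict <- function(k_train, y_train, k_cross, cost) {
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(k_train),
                       factor(y_train, levels = c(-1, 1)),
                       type = "C-svc", C = cost, kernel = "matrix")
  sv <- kernlab::SVindex(fit)
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(k_cross[, sv, drop = FALSE]))
  as.numeric(as.character(pred))
}

#' Build train/cross kernel blocks for one CV fold
#'
#' Arranges the kernel blocks [svm_fit_predict()] needs under either fold
#' convention. In `"transductive"` mode the correlation matrix, the kernel and
#' (for DCB) the denoising are computed once on all n samples and the fold
#' merely slices the result — bit-identical to building the full kernel and
#' subsetting. In `"inductive"` mode the mean sample and column norms come
#' from the training columns only; test columns are centred with the training
#' mean, and for DCB the repaired training kernel is
#' \eqn{\tilde K = U \tilde P U^\top} while cross-kernel rows are projected
#' through \eqn{U D U^\top} with \eqn{D_{ii} = 1} iff eigenvalue i was
#' retained — the out-of-sample extension of the clipped eigenbasis.
#'
#' @param x p x n sample matrix.
#' @param spec a kernel-method `"method_spec"` (UC, PC or DCB).
#' @param train_idx,test_idx disjoint index vectors into 1..n.
#' @return list with `train` (|train| x |train| kernel) and `cross`
#'   (|test| x |train| block).
#' @export
build_method_kernel <- function(x, spec, train_idx, test_idx) {
  if (!inherits(spec, "method_spec") || !spec$name %in% c("UC", "PC", "DCB")) {
    stop("spec must be a kernel method (UC, PC or DCB)")
  }
  if (spec$kernel_mode == "transductive") {
    k <- unclass_kernel(.full_kernel(x, spec))
    return(list(train = k[train_idx, train_idx, drop = FALSE],
                cross = k[test_idx, train_idx, drop = FALSE]))
  }
  .inductive_kernel(x, spec, train_idx, test_idx)
}

# Full-data kernel for a method spec (transductive path).
.full_kernel <- function(x, spec) {
  cc <- correlation_matrix(x, mode = spec$corr_mode)
  switch(spec$name,
         UC = uc_kernel(cc, spec$gamma),
         PC = pc_kernel(cc),
         DCB = dcb_kernel(cc, spec$transform))
}

# Inductive path: all statistics from training columns; test columns are
# projected into the trained (possibly repaired) kernel geometry.
.inductive_kernel <- function(x, spec, train_idx, test_idx) {
  xtr <- x[, train_idx, drop = FALSE]
  xte <- x[, test_idx, drop = FALSE]
  if (spec$corr_mode == "common-mean") {
    ctr <- xtr - rowMeans(xtr)
    cte <- xte - rowMeans(xtr)
  } else {
    ctr <- sweep(xtr, 2L, colMeans(xtr), "-")
    cte <- sweep(xte, 2L, colMeans(xte), "-")
  }
  dtr <- sqrt(colSums(ctr^2))
  dte <- sqrt(colSums(cte^2))
  if (any(dtr == 0) || any(dte == 0)) {
    stop("a sample has no direction after centring; correlation undefined")
  }
  c_tr <- crossprod(ctr) / tcrossprod(dtr)
  c_tr <- (c_tr + t(c_tr)) / 2; diag(c_tr) <- 1
  c_tr[c_tr > 1] <- 1; c_tr[c_tr < -1] <- -1
  c_cross <- crossprod(cte, ctr) / tcrossprod(dte, dtr)  # |test| x |train|
  c_cross[c_cross > 1] <- 1; c_cross[c_cross < -1] <- -1

  if (spec$name == "UC") {
    return(list(train = exp(-spec$gamma * (1 - c_tr)),
                cross = exp(-spec$gamma * (1 - c_cross))))
  }
  if (spec$name == "PC") {
    return(list(train = c_tr, cross = c_cross))
  }
  # DCB: repair the training CB kernel, project the CB cross block onto the
  # retained eigenspace.
  cb_tr <- 1 - exp(-c_tr)
  cb_cross <- 1 - exp(-c_cross)
  s <- eigendecompose(cb_tr)
  st <- transform_spectrum(s, spec$transform)
  if (identical(spec$transform, "clip")) {
    keep <- s$values >= 0
    if (!any(keep)) stop("inductive DCB: no retained components (all eigenvalues negative)")
    proj <- s$vectors[, keep, drop = FALSE] %*% t(s$vectors[, keep, drop = FALSE])
    cross <- cb_cross %*% proj
  } else {
    cross <- cb_cross   # flip/diffusion/shift keep the full eigenbasis
  }
  list(train = reconstruct(st), cross = cross)
}

#' K-nearest-neighbour prediction
#'
#' Euclidean distance on the feature columns; majority vote among the `k`
#' nearest training samples. A tied vote is broken by decrementing `k` until
#' the majority is strict (`k = 1` never ties on distinct distances); equal
#' distances are broken in favour of the lower training-sample index.
#'
#' @param x p x n sample matrix.
#' @param labels length-n vector over \{+1, -1\}.
#' @param train_idx,test_idx index vectors into 1..n.
#' @param k positive integer, at most `length(train_idx)`.
#' @return numeric vector of predicted labels for `test_idx`.
#' @export
knn_predict <- function(x, labels, train_idx, test_idx, k = 5) {
  if (k < 1) stop("k must be a positive integer")
  if (k > length(train_idx)) stop("k exceeds the number of training samples")
  xtr <- x[, train_idx, drop = FALSE]
  ytr <- labels[train_idx]
  vapply(test_idx, function(j) {
    d <- sqrt(colSums((xtr - x[, j])^2))
    ord <- order(d, train_idx)        # distance, then lower sample index
    for (kk in seq(k, 1L)) {
      s <- sum(ytr[ord[seq_len(kk)]])
      if (s != 0) return(sign(s))
    }
    ytr[ord[1L]]                      # unreachable for +/-1 labels; safety
  }, numeric(1))
}

#' Decision-tree (CART) prediction
#'
#' Fits an unpruned CART classifier with the Gini impurity (rpart with
#' `cp = 0`, `minsplit = 2`, no cross-validation pruning) on the training
#' columns and predicts the held-out ones. Deterministic for fixed inputs;
#' with no usable split the tree predicts the training majority class.
#'
#' @inheritParams knn_predict
#' @return numeric vector of predicted labels for `test_idx`.
#' @export
decision_tree_predict <- function(x, labels, train_idx, test_idx) {
  if (length(unique(labels[train_idx])) < 2L) {
    stop("training fold contains a single class")
  }
  df <- as.data.frame(t(x[, train_idx, drop = FALSE]))
  df$.y <- factor(labels[train_idx], levels = c(-1, 1))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                     cp = 0, xval = 0,
                                                     maxcompete = 0,
                                                     maxsurrogate = 0))
  nd <- as.data.frame(t(x[, test_idx, drop = FALSE]))
  as.numeric(as.character(predict(fit, newdata = nd, type = "class")))
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin, so every fold keeps both classes when each class has >= folds
# members. Uses the current RNG state.
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

# Predictions of one method for one fold (indices into columns of x).
.fold_predict <- function(x, labels, spec, train_idx, test_idx, full_kernel) {
  switch(spec$name,
    DT = decision_tree_predict(x, labels, train_idx, test_idx),
    KNN = knn_predict(x, labels, train_idx, test_idx, spec$k),
    {
      if (!is.null(full_kernel)) {
        svm_fit_predict(full_kernel, labels, train_idx, test_idx, spec$svm_cost)
      } else {
        blocks <- build_method_kernel(x, spec, train_idx, test_idx)
        me <- min_eigenvalue(blocks$train)
        if (me < -1e-6) {
          warning(sprintf("training kernel indefinite (min eigenvalue %.3g)", me))
        }
        .svm_train_predict(blocks$train, labels[train_idx], blocks$cross, spec$svm_cost)
      }
    })
}

#' Repeated stratified k-fold cross-validation of one method
#'
#' Runs `runs` independent repetitions of stratified `folds`-fold
#' cross-validation. Repetition r draws its fold assignment from seed
#' `seed + r`; every sample is tested exactly once per repetition, the per-run
#' accuracy is the pooled fraction of correct predictions (correct / n), and
#' the reported accuracy is the mean over repetitions. For kernel methods in
#' transductive mode the full n x n kernel (including any denoising) is built
#' once and folds slice it.
#'
#' @param x p x n sample matrix.
#' @param labels length-n vector over \{+1, -1\}; each class needs at least
#'   `folds` members.
#' @param spec a `"method_spec"`.
#' @param runs number of CV repetitions (default 10).
#' @param folds number of folds (default 5).
#' @param seed integer seed; run r uses `seed + r`.
#' @return a `"cv_report"`: method spec, `per_run_accuracy` (length `runs`),
#'   `mean_accuracy`, `runs`, `folds`, `seed`.
#' @examples
#' \donttest{
#' d <- generate_two_class(synthetic_spec(n_pos = 15, n_neg = 15, p = 100,
#'                                        n_informative = 10, effect_size = 2,
#'                                        seed = 1))
#' cross_validate(d$x, d$labels, method_spec("PC"), runs = 2, seed = 1)
#' }
#' @export
cross_validate <- function(x, labels, spec, runs = 10, folds = 5, seed = 0) {
  .check_sample_matrix(x)
  if (length(labels) != ncol(x)) stop("labels length must equal ncol(x)")
  if (!all(labels %in% c(-1, 1))) stop("labels must lie in {+1, -1}")
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (min(tab) < folds) {
    stop("smallest class has ", min(tab), " members, fewer than folds = ",
         folds, "; reduce the number of folds")
  }
  n <- ncol(x)
  full_kernel <- NULL
  if (spec$name %in% c("UC", "PC", "DCB") && spec$kernel_mode == "transductive") {
    full_kernel <- .full_kernel(x, spec)
  }
  per_run <- numeric(runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    fold <- .stratified_folds(labels, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      pred <- .fold_predict(x, labels, spec, tr, te, full_kernel)
      correct <- correct + sum(pred == labels[te])
    }
    per_run[r] <- correct / n
  }
  structure(list(method = spec, runs = runs, folds = folds,
                 per_run_accuracy = per_run,
                 mean_accuracy = mean(per_run), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold stratified CV | %s\n", x$runs, x$folds,
              format(x$method)))
  cat(sprintf("mean accuracy: %.4f (per-run range %.4f - %.4f)\n",
              x$mean_accuracy, min(x$per_run_accuracy), max(x$per_run_accuracy)))
  invisible(x)
}

#' @describeIn cross_validate plot per-run accuracies of a CV report.
#' @param y ignored (generic signature).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_report <- function(x, y, ...) {
  plot(seq_len(x$runs), x$per_run_accuracy, type = "b", pch = 19,
       xlab = "run", ylab = "accuracy", ylim = c(0, 1),
       main = format(x$method), ...)
  invisible(x)
}

#' Benchmark several methods on one dataset
#'
#' Cross-validates every method spec with the same data, seed and fold scheme
#' and returns their mean accuracies side by side, together with the full
#' per-run series for plotting run-accuracy curves.
#'
#' @inheritParams cross_validate
#' @param specs list of `"method_spec"` objects.
#' @return a `"cv_comparison"`: data frame of mean accuracies (one row, one
#'   column per method) with attributes `reports` (the `"cv_report"` list) and
#'   `per_run` (runs x methods matrix).
#' @export
comparison_table <- function(x, labels, specs, runs = 10, folds = 5, seed = 0) {
  if (!length(specs)) stop("specs must be a nonempty list of method_spec")
  reports <- lapply(specs, function(s) cross_validate(x, labels, s, runs, folds, seed))
  nm <- vapply(specs, format, "")
  acc <- vapply(reports, function(r) r$mean_accuracy, numeric(1))
  per_run <- vapply(reports, function(r) r$per_run_accuracy, numeric(runs))
  if (is.null(dim(per_run))) per_run <- matrix(per_run, nrow = runs)
  colnames(per_run) <- nm
  out <- as.data.frame(as.list(stats::setNames(acc, nm)), check.names = FALSE)
  structure(out, class = c("cv_comparison", "data.frame"),
            reports = reports, per_run = per_run,
            runs = runs, folds = folds, seed = seed)
}

#' The nine-method benchmark grid
#'
#' Convenience constructor for the standard comparison: decision tree, UC at
#' gamma in \{0.1, 1, 10\}, PC, DCB, and KNN at k in \{1, 5, 10\}.
#'
#' @param svm_cost soft-margin cost for the kernel methods.
#' @param kernel_mode,corr_mode passed to [method_spec()].
#' @return list of `"method_spec"` objects in table order.
#' @export
benchmark_grid <- function(svm_cost = 1, kernel_mode = "transductive",
                           corr_mode = "common-mean") {
  c(list(method_spec("DT")),
    lapply(c(0.1, 1, 10), function(g)
      method_spec("UC", gamma = g, svm_cost = svm_cost,
                  kernel_mode = kernel_mode, corr_mode = corr_mode)),
    list(method_spec("PC", svm_cost = svm_cost, kernel_mode = kernel_mode,
                     corr_mode = corr_mode),
         method_spec("DCB", svm_cost = svm_cost, kernel_mode = kernel_mode,
                     corr_mode = corr_mode)),
    lapply(c(1L, 5L, 10L), function(k) method_spec("KNN", k = k)))
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf("Mean accuracy, %d x %d-fold stratified CV (seed %d)\n",
              attr(x, "runs"), attr(x, "folds"), attr(x, "seed")))
  print(round(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}

#' @describeIn comparison_table run-accuracy curves, one line per method.
#' @param y ignored (generic signature).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cv_comparison <- function(x, y, ...) {
  pr <- attr(x, "per_run")
  matplot(seq_len(nrow(pr)), pr, type = "b", pch = seq_len(ncol(pr)),
          lty = 1, xlab = "run", ylab = "accuracy", ylim = c(0, 1), ...)
  legend("bottomright", legend = colnames(pr), pch = seq_len(ncol(pr)),
         col = seq_len(ncol(pr)), cex = 0.8)
  invisible(x)
}
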