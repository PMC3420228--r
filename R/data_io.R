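# Reading/writing the libsvm sparse sample format and the two-stage
# standardization applied to expression matrices before kernel construction.

#' Read a libsvm-format file into a feature-by-sample matrix
#'
#' Parses the sparse libsvm format (`label idx:val idx:val ...`, one sample per
#' line, 1-based strictly increasing feature indices) into a dense p x n matrix
#' with samples as columns, plus a label vector in \{+1, -1\}.
#'
#' Absent feature indices are zeros, following the libsvm convention. Raw
#' labels may be coded \{+1,-1\}, \{1,0\} or \{1,2\}; any two-valued numeric
#' coding is accepted and the larger raw value maps to +1 (a message reports
#' the mapping when it is not the identity).
#'
#' @param path path to a libsvm-format text file.
#' @param expected_features optional positive integer; if given, the returned
#'   matrix has exactly this many rows (an index beyond it is an error).
#'   Otherwise the largest index seen determines p.
#' @return a list with components `x` (p x n numeric matrix, column j = sample
#'   j) and `labels` (length-n numeric vector over \{+1, -1\}).
#' @seealso [write_libsvm()], [zscore_samples()], [zscore_features()]
#' @examples
#' f <- tempfile()
#' writeLines(c("+1 1:0.5 3:-0.2", "-1 2:1.0"), f)
#' d <- read_libsvm(f, expected_features = 3)
#' d$x
#' d$labels
#' @export
read_libsvm <- function(path, expected_features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty libsvm file: ", path)
  n <- length(lines)

  raw_labels <- numeric(n)
  idx_list <- vector("list", n)
  val_list <- vector("list", n)
  max_idx <- 0L
  for (j in seq_len(n)) {
    tok <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
    lab <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(lab)) {
      stop("line ", j, ": malformed label '", tok[1], "'")
    }
    raw_labels[j] <- lab
    if (length(tok) > 1L) {
      parts <- strsplit(tok[-1], ":", fixed = TRUE)
      bad <- which(lengths(parts) != 2L)
      if (length(bad)) {
        stop("line ", j, ": malformed feature token '", tok[-1][bad[1]], "'")
      }
      idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
      if (anyNA(idx) || anyNA(val)) {
        stop("line ", j, ": non-numeric feature index or value")
      }
      if (any(idx < 1L)) stop("line ", j, ": feature indices must be >= 1")
      if (any(diff(idx) <= 0L)) {
        stop("line ", j, ": feature indices must be strictly increasing")
      }
      idx_list[[j]] <- idx
      val_list[[j]] <- val
      max_idx <- max(max_idx, idx[length(idx)])
    }
  }

  p <- if (is.null(expected_features)) max_idx else as.integer(expected_features)
  if (p < 1L) stop("no feature indices found and expected_features not given")
  if (max_idx > p) {
    stop("feature index ", max_idx, " exceeds expected_features = ", p)
  }

  x <- matrix(0, nrow = p, ncol = n)
  for (j in seq_len(n)) {
    if (length(idx_list[[j]])) x[idx_list[[j]], j] <- val_list[[j]]
  }
  list(x = x, labels = .map_labels(raw_labels))
}

# Map a two-valued raw label coding onto {+1, -1}: larger raw value -> +1.
.map_labels <- function(raw) {
  u <- sort(unique(raw), decreasing = TRUE)
  if (length(u) > 2L) {
    stop("more than two distinct labels found: ", paste(u, collapse = ", "),
         " (binary classification only)")
  }
  if (all(u %in% c(-1, 1))) return(raw)
  if (length(u) == 1L) {
    stop("single label value ", u, " cannot be mapped onto {+1, -1}")
  }
  message("mapping labels: ", u[1], " -> +1, ", u[2], " -> -1")
  ifelse(raw == u[1], 1, -1)
}

#' Write a feature-by-sample matrix in libsvm sparse format
#'
#' Inverse of [read_libsvm()]: zeros are omitted (libsvm convention), values
#' are written with full `%.17g` precision so a read-back reproduces the dense
#' matrix exactly.
#'
#' @param x p x n numeric matrix, samples as columns.
#' @param labels length-n vector over \{+1, -1\}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(x, labels, path) {
  .check_sample_matrix(x)
  if (length(labels) != ncol(x)) stop("labels length must equal ncol(x)")
  lines <- vapply(seq_len(ncol(x)), function(j) {
    nz <- which(x[, j] != 0)
    feat <- if (length(nz)) {
      paste(sprintf("%d:%.17g", nz, x[nz, j]), collapse = " ")
    } else ""
    trimws(paste(sprintf("%+d", as.integer(labels[j])), feat))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Instance-wise standardization (each sample column to mean 0, sd 1)
#'
#' First stage of the two-stage preprocessing applied to expression matrices:
#' every sample column is centred and scaled to unit standard deviation. The
#' population convention (divisor p) is the default, so that a standardized
#' column literally has second moment 1; set `divisor = "sample"` for the
#' p - 1 convention.
#'
#' @param x p x n numeric matrix, samples as columns.
#' @param divisor `"population"` (divide by p, default) or `"sample"` (p - 1).
#' @return matrix of the same shape with standardized columns.
#' @seealso [zscore_features()] for the second stage.
#' @export
zscore_samples <- function(x, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  .check_sample_matrix(x)
  denom <- if (divisor == "population") nrow(x) else nrow(x) - 1L
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- sqrt(colSums(xc^2) / denom)
  zero <- which(s == 0)
  if (length(zero)) {
    stop("sample ", zero[1], " has zero variance; cannot standardize")
  }
  sweep(xc, 2L, s, "/")
}

#' Feature-wise standardization (each feature row to mean 0, sd 1)
#'
#' Second stage of the two-stage preprocessing: every feature (gene) row is
#' centred and scaled across samples. Row moments hold exactly afterwards;
#' column moments set by [zscore_samples()] are no longer guaranteed.
#'
#' @inheritParams zscore_samples
#' @return matrix of the same shape with standardized rows.
#' @export
zscore_features <- function(x, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  .check_sample_matrix(x)
  denom <- if (divisor == "population") ncol(x) else ncol(x) - 1L
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / denom)
  zero <- which(s == 0)
  if (length(zero)) {
    stop("feature ", zero[1], " has zero variance; cannot standardize")
  }
  xc / s
}

# Shared validation for the p x n sample-matrix contract.
.check_sample_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("sample matrix must be a numeric matrix (features x samples)")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("sample matrix needs at least 2 features and 2 samples, got ",
         nrow(x), " x ", ncol(x))
  }
  if (!all(is.finite(x))) stop("sample matrix contains NaN/Inf entries")
  invisible(x)
}
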