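# Shared fixtures and independent oracles, all built in code.

# Random p x n sample matrix (continuous, so degenerate columns have
# probability zero).
rand_sample_matrix <- function(p, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * n), p, n)
}

# Brute-force correlation oracle: a literal double loop over the defining
# quotient, independent of the vectorized implementation.
corr_oracle <- function(x, mode = "common-mean") {
  n <- ncol(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ci <- if (mode == "common-mean") rowMeans(x) else rep(mean(x[, i]), nrow(x))
      cj <- if (mode == "common-mean") rowMeans(x) else rep(mean(x[, j]), nrow(x))
      a <- x[, i] - ci
      b <- x[, j] - cj
      out[i, j] <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
    }
  }
  out
}

# The strongly anticorrelated two-sample witness: corr = [[1,-1],[-1,1]],
# whose CB kernel is indefinite with closed-form eigenvalues.
witness_corr <- function() {
  m <- cbind(c(1, -1), c(-1, 1))
  structure(m, class = c("corr_matrix", "matrix", "array"), mode = "common-mean")
}

# Write a small libsvm file and return its path.
write_libsvm_lines <- function(lines) {
  f <- tempfile(fileext = ".libsvm")
  writeLines(lines, f)
  f
}
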