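# Closed-form expectations below: exp(-1) = 0.36787944, exp(-2) = 0.13533528,
# 1 - exp(-1) = 0.63212056, 1 - exp(1) = -1.71828183.

test_that("UC kernel matches its closed form entrywise", {
  cc <- cbind(c(1, 0, -1), c(0, 1, 0), c(-1, 0, 1))  # zero- and anti-correlated pairs
  k <- uc_kernel(cc, gamma = 1)
  expect_equal(diag(unclass_kernel(k)), rep(1, 3))
  expect_equal(k[1, 2], exp(-1))
  expect_equal(k[1, 3], exp(-2))
  expect_equal(attr(k, "kind"), "UC")
  expect_error(uc_kernel(cc, gamma = 0), "positive")
  expect_error(uc_kernel(cc, gamma = -1), "positive")
})

test_that("UC equals the Hadamard-exponential factorization exp(-g) * exp(g*corr)", {
  for (s in 1:10) {
    x <- rand_sample_matrix(12, 8, seed = 300 + s)
    cc <- correlation_matrix(x)
    for (g in c(0.1, 1, 10)) {
      k <- unclass_kernel(uc_kernel(cc, g))
      expect_equal(k, exp(-g) * exp(g * unclass_kernel(cc)), tolerance = 1e-12)
    }
  }
})

test_that("PC kernel is the correlation matrix itself, certified PSD", {
  x <- rand_sample_matrix(9, 6, seed = 21)
  cc <- correlation_matrix(x)
  k <- pc_kernel(cc)
  expect_identical(unclass_kernel(k), unclass_kernel(cc))
  expect_true(attr(k, "psd_certified"))
  # 2x2 anticorrelated: eigenvalues {2, 0}, still PSD
  kw <- pc_kernel(witness_corr())
  ev <- eigen(unclass_kernel(kw), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(2, 0), tolerance = 1e-12)
  # numerically indefinite input is an upstream fault, not repaired silently
  bad <- cbind(c(1, 0.9, 0.1), c(0.9, 1, 0.9), c(0.1, 0.9, 1))
  expect_error(pc_kernel(bad), "indefinite")
})

test_that("CB kernel closed form, constant diagonal, and witness indefiniteness", {
  k <- cb_kernel(witness_corr())
  expect_equal(diag(unclass_kernel(k)), rep(1 - exp(-1), 2))
  expect_equal(k[1, 2], 1 - exp(1))
  ev <- eigen(unclass_kernel(k), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(2.350402, -1.086161), tolerance = 1e-6)
  expect_false(attr(k, "psd_certified"))
  # c_ij = 0 maps to 0
  x <- rand_sample_matrix(30, 5, seed = 4)
  cc <- unclass_kernel(correlation_matrix(x))
  expect_equal(unclass_kernel(cb_kernel(cc)), 1 - exp(-cc), tolerance = 1e-15)
})

test_that("K1CB has unit diagonal and satisfies the scaling identity", {
  for (s in 1:10) {
    x <- rand_sample_matrix(10, 6, seed = 400 + s)
    cc <- correlation_matrix(x)
    k1 <- unclass_kernel(k1cb_kernel(cc))
    cb <- unclass_kernel(cb_kernel(cc))
    expect_equal(diag(k1), rep(1, 6))
    expect_equal((1 - exp(-1)) * k1, cb, tolerance = 1e-12)
  }
})

test_that("DCB clip reproduces the hand-computed 2x2 rank-1 reconstruction", {
  dcb <- dcb_kernel(witness_corr())
  expect_equal(unclass_kernel(dcb),
               cbind(c(1.175201, -1.175201), c(-1.175201, 1.175201)),
               tolerance = 1e-6)
  expect_true(attr(dcb, "psd_certified"))
  expect_equal(attr(dcb, "transform"), "clip")
  expect_error(dcb_kernel(witness_corr(), method = "nope"))
})

test_that("DCB is the identity on an already-PSD CB kernel", {
  cc <- cbind(c(1, 0.5), c(0.5, 1))
  cb <- cb_kernel(cc)
  expect_true(attr(cb, "psd_certified"))
  expect_equal(unclass_kernel(dcb_kernel(cc)), unclass_kernel(cb), tolerance = 1e-10)
})

test_that("clipped mass accounting: ||DCB - CB||_F^2 = sum of squared negative eigenvalues", {
  for (s in 1:5) {
    cc <- generate_indefinite_case(6, seed = 500 + s)
    cb <- unclass_kernel(cb_kernel(cc))
    dcb <- unclass_kernel(dcb_kernel(cc))
    ev <- eigen(cb, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum((dcb - cb)^2), sum(ev[ev < 0]^2), tolerance = 1e-8)
    expect_gte(min_eigenvalue(dcb), -1e-10)
  }
})

test_that("UC/CB entries increase in correlation; UC decreases in gamma below the diagonal", {
  cgrid <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(exp(-1 * (1 - cgrid))) > 0))
  expect_true(all(diff(1 - exp(-cgrid)) > 0))
  x <- rand_sample_matrix(15, 5, seed = 6)
  cc <- correlation_matrix(x)
  k1 <- unclass_kernel(uc_kernel(cc, 1))
  k2 <- unclass_kernel(uc_kernel(cc, 2))
  off <- upper.tri(k1)
  expect_true(all(k2[off] < k1[off]))
  # gamma -> 0 limit: all-ones matrix
  k0 <- unclass_kernel(uc_kernel(cc, 1e-12))
  expect_equal(k0, matrix(1, 5, 5), tolerance = 1e-10)
})
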