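test_that("svm_fit_predict separates a block-structured kernel and flips with labels", {
  n <- 20
  y <- c(rep(1, 10), rep(-1, 10))
  k <- matrix(0, n, n)
  k[1:10, 1:10] <- 1
  k[11:20, 11:20] <- 1
  tr <- c(1:7, 11:17); te <- setdiff(1:n, tr)
  expect_equal(svm_fit_predict(k, y, tr, te, cost = 10), y[te])
  # training-set predictions on separable data with large cost are perfect
  expect_equal(svm_fit_predict(k, y, tr, setdiff(1:n, tr), cost = 100), y[te])
  # flipped labels flip the predictions
  expect_equal(svm_fit_predict(k, -y, tr, te, cost = 10), -y[te])
})

test_that("svm_fit_predict validates folds and warns on indefinite training kernels", {
  k <- diag(4); y <- c(1, 1, -1, -1)
  expect_error(svm_fit_predict(k, y, 1:3, 3:4), "overlap")
  expect_error(svm_fit_predict(k, y, integer(0), 1:2), "empty")
  expect_error(svm_fit_predict(k, y, 1:2, 3:4), "single class")
  cb <- unclass_kernel(cb_kernel(generate_indefinite_case(8, seed = 1)))
  yy <- rep(c(1, -1), 4)
  expect_warning(svm_fit_predict(cb, yy, 1:6, 7:8), "indefinite")
})

test_that("transductive build_method_kernel slices the full kernel bit-identically", {
  d <- generate_two_class(synthetic_spec(n_pos = 8, n_neg = 8, p = 60,
                                         n_informative = 6, effect_size = 1.5,
                                         block_correlation = 0, seed = 2))
  tr <- c(1:6, 9:14); te <- setdiff(1:16, tr)
  for (nm in c("UC", "PC", "DCB")) {
    spec <- method_spec(nm, kernel_mode = "transductive")
    blocks <- build_method_kernel(d$x, spec, tr, te)
    full <- switch(nm,
                   UC = uc_kernel(correlation_matrix(d$x), 1),
                   PC = pc_kernel(correlation_matrix(d$x)),
                   DCB = dcb_kernel(correlation_matrix(d$x)))
    full <- unclass_kernel(full)
    expect_identical(blocks$train, full[tr, tr], info = nm)
    expect_identical(blocks$cross, full[te, tr], info = nm)
  }
  expect_error(build_method_kernel(d$x, method_spec("KNN"), tr, te), "kernel method")
})

test_that("inductive PC cross-kernel agrees with train entries for duplicated columns", {
  x <- rand_sample_matrix(40, 10, seed = 33)
  x[, 9] <- x[, 3]   # test column 9 duplicates train column 3
  x[, 10] <- x[, 5]
  spec <- method_spec("PC", kernel_mode = "inductive")
  blocks <- build_method_kernel(x, spec, 1:8, 9:10)
  expect_equal(blocks$cross[1, ], blocks$train[3, ], tolerance = 1e-10)
  expect_equal(blocks$cross[2, ], blocks$train[5, ], tolerance = 1e-10)
})

test_that("inductive DCB equals inductive PC-style CB when CB is already PSD", {
  # two training samples: the 2x2 CB kernel built on near-identical columns is PSD
  set.seed(44)
  base <- rnorm(30)
  x <- cbind(base + rnorm(30, sd = 0.1), base + rnorm(30, sd = 0.1),
             base + rnorm(30, sd = 0.1), rnorm(30))
  tr <- 1:3; te <- 4
  cbsp <- method_spec("DCB", kernel_mode = "inductive")
  blocks <- build_method_kernel(x, cbsp, tr, te)
  # CB on the training trio: verify PSD, then DCB must coincide with raw CB
  ctr <- x[, tr] - rowMeans(x[, tr])
  d <- sqrt(colSums(ctr^2))
  cbtr <- 1 - exp(-(crossprod(ctr) / tcrossprod(d)))
  if (min_eigenvalue(cbtr) >= -1e-10) {
    expect_equal(blocks$train, (cbtr + t(cbtr)) / 2, tolerance = 1e-8)
  }
  expect_gte(min_eigenvalue(blocks$train), -1e-10)
})

test_that("knn_predict follows the distance/vote/tie rules exactly", {
  # train columns at known distances from a test column at the origin
  x <- cbind(c(0, 1), c(0, 2), c(0, -3), c(0, 0))
  y <- c(1, 1, -1, NA)
  expect_equal(knn_predict(x, y, 1:3, 4, k = 3), 1)      # majority (+1,+1,-1)
  expect_equal(knn_predict(x, y, 1:3, 4, k = 1), 1)      # nearest neighbour
  # k = 2 tie (+1 at distance 1, -1 at distance 2) -> decrement to k = 1
  x2 <- cbind(c(0, 1), c(0, -2), c(0, 0))
  expect_equal(knn_predict(x2, c(1, -1, NA), 1:2, 3, k = 2), 1)
  # equal distances broken by the lower training-sample index
  x3 <- cbind(c(0, 1), c(0, -1), c(0, 0))
  expect_equal(knn_predict(x3, c(-1, 1, NA), 1:2, 3, k = 1), -1)
  # zero distance returns the coinciding point's label
  x4 <- cbind(c(1, 1), c(5, 5), c(1, 1))
  expect_equal(knn_predict(x4, c(-1, 1, NA), 1:2, 3, k = 1), -1)
  expect_error(knn_predict(x, y, 1:3, 4, k = 0), "positive")
  expect_error(knn_predict(x, y, 1:3, 4, k = 5), "exceeds")
})

test_that("decision_tree_predict splits a single separating feature and is deterministic", {
  set.seed(12)
  x <- rbind(c(rep(0, 8), rep(10, 8)) + rnorm(16, sd = 0.1),
             rnorm(16), rnorm(16))
  y <- c(rep(-1, 8), rep(1, 8))
  tr <- c(1:6, 9:14); te <- setdiff(1:16, tr)
  p1 <- decision_tree_predict(x, y, tr, te)
  expect_equal(p1, y[te])
  expect_identical(decision_tree_predict(x, y, tr, te), p1)
  # constant features: majority-class prediction
  xc <- matrix(1, 3, 10) + 0   # constant; rpart cannot split
  yc <- c(rep(1, 6), rep(-1, 4))
  expect_equal(decision_tree_predict(xc, yc, 1:10, 1:10), rep(1, 10))
  expect_error(decision_tree_predict(x, rep(1, 16), tr, te), "single class")
})

test_that("cross_validate partitions every sample once per run and is seed-reproducible", {
  d <- generate_two_class(synthetic_spec(n_pos = 10, n_neg = 10, p = 80,
                                         n_informative = 8, effect_size = 2,
                                         block_correlation = 0, seed = 3))
  r1 <- cross_validate(d$x, d$labels, method_spec("PC"), runs = 3, folds = 5, seed = 9)
  r2 <- cross_validate(d$x, d$labels, method_spec("PC"), runs = 3, folds = 5, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$mean_accuracy, mean(r1$per_run_accuracy), tolerance = 1e-12)
  expect_true(all(r1$per_run_accuracy >= 0 & r1$per_run_accuracy <= 1))
  # a different seed reshuffles folds
  r3 <- cross_validate(d$x, d$labels, method_spec("PC"), runs = 3, folds = 5, seed = 10)
  expect_false(identical(r1$per_run_accuracy, r3$per_run_accuracy))
  # class smaller than folds is refused with advice
  expect_error(cross_validate(d$x[, 1:12], c(rep(1, 10), -1, -1),
                              method_spec("PC"), folds = 5),
               "fewer than folds|reduce")
})

test_that("stratified fold assignment keeps both classes in every training fold", {
  # imbalanced data (11 vs 27, the leukemia shape) must never yield a
  # single-class training fold under stratification
  d <- generate_two_class(synthetic_spec(n_pos = 11, n_neg = 27, p = 50,
                                         n_informative = 5, effect_size = 1,
                                         block_correlation = 0, seed = 5))
  r <- cross_validate(d$x, d$labels, method_spec("PC"), runs = 5, folds = 5, seed = 0)
  expect_true(all(is.finite(r$per_run_accuracy)))
})

test_that("transductive and inductive modes agree on strong-signal data", {
  d <- generate_two_class(synthetic_spec(n_pos = 12, n_neg = 12, p = 150,
                                         n_informative = 12, effect_size = 2,
                                         block_correlation = 0, seed = 6))
  for (nm in c("PC", "DCB")) {
    a <- cross_validate(d$x, d$labels, method_spec(nm, kernel_mode = "transductive"),
                        runs = 3, seed = 2)$mean_accuracy
    b <- cross_validate(d$x, d$labels, method_spec(nm, kernel_mode = "inductive"),
                        runs = 3, seed = 2)$mean_accuracy
    expect_lt(abs(a - b), 0.1)
  }
})

test_that("permuted labels drive accuracy to the majority-class fraction", {
  d <- generate_two_class(synthetic_spec(n_pos = 20, n_neg = 20, p = 100,
                                         n_informative = 10, effect_size = 2,
                                         block_correlation = 0, seed = 7))
  # average over permutations: any single permutation can align by chance
  # with the latent clusters on a small sample
  set.seed(99)
  acc <- vapply(1:3, function(i) {
    yperm <- sample(d$labels)
    cross_validate(d$x, yperm, method_spec("DCB"), runs = 4,
                   seed = i)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.12)
})

test_that("comparison_table reproduces the benchmark layout deterministically", {
  d <- generate_two_class(synthetic_spec(n_pos = 8, n_neg = 8, p = 60,
                                         n_informative = 6, effect_size = 2,
                                         block_correlation = 0, seed = 8))
  specs <- list(method_spec("PC"), method_spec("PC"))
  tab <- comparison_table(d$x, d$labels, specs, runs = 2, seed = 3)
  expect_equal(dim(as.data.frame(tab)), c(1L, 2L))
  expect_equal(tab[[1]], tab[[2]])       # identical specs, identical columns
  expect_true(all(unlist(tab) >= 0 & unlist(tab) <= 1))

  grid <- benchmark_grid()
  expect_equal(vapply(grid, format, ""),
               c("DT", "UC(gamma=0.1)", "UC(gamma=1)", "UC(gamma=10)",
                 "PC", "DCB", "KNN(k=1)", "KNN(k=5)", "KNN(k=10)"))
  tab2 <- comparison_table(d$x, d$labels, grid, runs = 2, seed = 3)
  expect_equal(ncol(as.data.frame(tab2)), 9L)
  expect_equal(dim(attr(tab2, "per_run")), c(2L, 9L))
})
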