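test_that("rbf kernel follows the 2-sigma denominator exactly", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.7), 1)
  # ||x - y||^2 = 2 sigma ln 2  ->  K = 1/2
  sigma <- 1.3
  x <- c(0, 0); y <- c(sqrt(2 * sigma * log(2)), 0)
  expect_equal(rbf_kernel(x, y, sigma), 0.5, tolerance = 1e-12)
  withr::local_seed(30)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4); s <- runif(1, 0.1, 5)
    expect_equal(rbf_kernel(a, b, s), rbf_kernel(b, a, s))
    expect_equal(rbf_kernel(a, b, s),
                 exp(-sum((a - b)^2) / (2 * s)), tolerance = 1e-14)
  }
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
  expect_error(rbf_kernel(c(1), c(1), 0), "sigma")
})

test_that("kernel Gram matrices are symmetric positive semidefinite", {
  withr::local_seed(31)
  X <- matrix(rnorm(40), 10, 4)
  G <- rbf_kernel(X, X, 2)
  expect_equal(G, t(G), tolerance = 1e-12)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("a separable pair is classified with opposite decision signs", {
  fm <- feature_matrix(rbind(c(-1, 0), c(1, 0)), c(1L, 2L))
  m <- train_svm(fm, 1, 1)
  pr <- predict_svm(m, fm)
  expect_equal(pr$labels, c(1L, 2L))
  expect_gt(pr$decision[1], 0)
  expect_lt(pr$decision[2], 0)
  expect_error(train_svm(feature_matrix(rbind(c(0, 0), c(1, 1)),
                                        c(1L, 1L)), 1, 1), "single class")
})

test_that("XOR is solved and the dual solution satisfies the KKT system", {
  fm <- xor_features()
  C <- 10; sigma <- 0.5
  m <- train_svm(fm, C, sigma)
  pr <- predict_svm(m, fm)
  expect_equal(pr$labels, fm$labels)
  # dual equality constraint
  expect_lt(abs(sum(m$dual_coefs)), 1e-6)
  # box constraint: |alpha_i y_i| <= C
  expect_true(all(abs(m$dual_coefs) <= C + 1e-8))
  # KKT: free support vectors (alpha < C) sit exactly on the margin
  f_sv <- predict_svm(m, m$support_vectors)$decision
  y_sv <- sign(m$dual_coefs)
  free <- abs(m$dual_coefs) < C - 1e-6
  expect_lt(max(abs(y_sv[free] * f_sv[free] - 1)), 1e-6)
})

test_that("decision values decay to the bias far from support vectors", {
  withr::local_seed(32)
  fm <- feature_matrix(rbind(matrix(rnorm(20, -2), 10, 2),
                             matrix(rnorm(20, 2), 10, 2)),
                       rep(1:2, each = 10))
  m <- train_svm(fm, 1, 1)
  far <- matrix(c(500, 500), 1, 2)
  expect_equal(predict_svm(m, far)$decision, m$bias, tolerance = 1e-6)
  expect_error(predict_svm(m, matrix(0, 1, 3)), "width")
})

test_that("label flip negates the decision function of a refit", {
  withr::local_seed(33)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  fm1 <- feature_matrix(X, rep(1:2, each = 10))
  fm2 <- feature_matrix(X, rep(2:1, each = 10))
  d1 <- predict_svm(train_svm(fm1, 1, 1), X)$decision
  d2 <- predict_svm(train_svm(fm2, 1, 1), X)$decision
  expect_equal(d1, -d2, tolerance = 1e-8)
})

test_that("grid search covers 110 points and finds a separating model", {
  withr::local_seed(34)
  fm <- feature_matrix(rbind(matrix(rnorm(40, -3), 20, 2),
                             matrix(rnorm(40, 3), 20, 2)),
                       rep(1:2, each = 20))
  gs <- grid_search(fm, folds = 5, seed = 7)
  expect_equal(nrow(gs$grid), 110L)
  expect_equal(sort(unique(gs$grid$C)), 2^seq(-5, 15, 2))
  expect_equal(sort(unique(gs$grid$sigma)), 2^seq(-15, 3, 2))
  expect_gte(max(gs$mean_accuracy), 0.95)
  # reproducibility
  gs2 <- grid_search(fm, folds = 5, seed = 7)
  expect_identical(gs$fold_accuracies, gs2$fold_accuracies)
  expect_identical(c(gs$best_C, gs$best_sigma), c(gs2$best_C, gs2$best_sigma))
  expect_error(grid_search(fm, folds = 30), "folds")
})

test_that("row shuffling barely moves the grid-search CV estimate", {
  withr::local_seed(35)
  fm <- feature_matrix(rbind(matrix(rnorm(60, -2), 30, 2),
                             matrix(rnorm(60, 2), 30, 2)),
                       rep(1:2, each = 30))
  gs1 <- grid_search(fm, folds = 5, seed = 3,
                     C_exponents = c(-1L, 1L), sigma_exponents = c(-1L, 1L))
  perm <- sample(nrow(fm$values))
  fm_sh <- feature_matrix(fm$values[perm, ], fm$labels[perm])
  gs2 <- grid_search(fm_sh, folds = 5, seed = 3,
                     C_exponents = c(-1L, 1L), sigma_exponents = c(-1L, 1L))
  expect_lt(abs(max(gs1$mean_accuracy) - max(gs2$mean_accuracy)), 0.02)
})

test_that("raising C never increases margin violations on separable data", {
  withr::local_seed(36)
  X <- rbind(matrix(rnorm(30, -3), 15, 2), matrix(rnorm(30, 3), 15, 2))
  fm <- feature_matrix(X, rep(1:2, each = 15))
  viol <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    m <- train_svm(fm, C, 2)
    pr <- predict_svm(m, fm)
    y <- ifelse(fm$labels == 1, 1, -1)
    sum(y * pr$decision < 1 - 1e-4)   # slack beyond solver precision
  }, 0)
  expect_true(all(diff(viol) <= 0))
})
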