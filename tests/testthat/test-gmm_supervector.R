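test_that("components_for_rate maps rates to counts", {
  expect_equal(components_for_rate(0.30, 270), 81L)
  expect_equal(components_for_rate(1.0, 200), 200L)
  expect_equal(components_for_rate(0.001, 100), 1L)
  expect_error(components_for_rate(0, 10), "rate")
  expect_error(components_for_rate(-0.1, 10), "rate")
})

test_that("one E-step reproduces brute-force posterior densities", {
  X <- rbind(c(0, 0), c(1, 1), c(4, -1))
  weights <- c(0.3, 0.7)
  means <- rbind(c(0, 0), c(3, 0))
  vars <- rbind(c(1, 2), c(0.5, 1))
  es <- gmm_estep(X, weights, means, vars)
  # oracle: product of univariate normal densities, normalized by hand
  for (i in 1:3) {
    dens <- vapply(1:2, function(j)
      weights[j] * prod(dnorm(X[i, ], means[j, ], sqrt(vars[j, ]))), 0)
    expect_equal(unname(es$resp[i, ]), dens / sum(dens), tolerance = 1e-10)
  }
  ll_oracle <- sum(log(vapply(1:3, function(i)
    sum(vapply(1:2, function(j)
      weights[j] * prod(dnorm(X[i, ], means[j, ], sqrt(vars[j, ]))), 0)), 0)))
  expect_equal(es$log_lik, ll_oracle, tolerance = 1e-10)
})

test_that("single-component EM hits the closed-form fixed point", {
  withr::local_seed(20)
  X <- matrix(rnorm(30), 10, 3)
  g <- fit_class_gmm(X, 1, seed = 1)
  expect_equal(drop(g$means), colMeans(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(g$vars),
               apply(X, 2, function(c) mean((c - mean(c))^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$weights, 1)
})

test_that("EM recovers two well-separated clusters", {
  withr::local_seed(21)
  X <- rbind(matrix(rnorm(200, -10), 100, 2),
             matrix(rnorm(200, 10), 100, 2))
  g <- fit_class_gmm(X, 2, seed = 42)
  ord <- order(g$means[, 1])
  expect_lt(max(abs(g$means[ord[1], ] - c(-10, -10))), 0.2)
  expect_lt(max(abs(g$means[ord[2], ] - c(10, 10))), 0.2)
  expect_lt(max(abs(g$weights - 0.5)), 0.05)
})

test_that("EM invariants hold on every fitted fixture", {
  withr::local_seed(22)
  for (m in c(1, 3, 5)) {
    X <- matrix(rnorm(200), 50, 4)
    g <- fit_class_gmm(X, m, seed = m)
    expect_equal(sum(g$weights), 1, tolerance = 1e-10)
    expect_true(all(g$weights >= 0 & g$weights <= 1))
    expect_true(all(diff(g$log_likelihood_trace) > -1e-8))
    expect_true(all(g$vars > 0))
    # stationarity: mixture mean equals the sample mean
    expect_equal(drop(g$weights %*% g$means), colMeans(X),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(fit_class_gmm(matrix(rnorm(10), 5, 2), 6, seed = 1),
               "exceeds")
  expect_error(fit_class_gmm(matrix(0, 0, 2), 1, seed = 1), "empty")
})

test_that("EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  withr::local_seed(25)
  X <- rbind(matrix(rnorm(120, -3), 60, 2), matrix(rnorm(120, 3), 60, 2))
  g <- fit_class_gmm(X, 2, seed = 9)
  mc <- suppressMessages(
    mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE))
  mc_means <- t(mc$parameters$mean)
  ord_g <- order(g$means[, 1]); ord_m <- order(mc_means[, 1])
  expect_lt(max(abs(g$means[ord_g, ] - mc_means[ord_m, ])), 0.05)
  expect_lt(max(abs(sort(g$weights) - sort(mc$parameters$pro))), 0.02)
})

test_that("supervector stacking keeps class blocks in order", {
  withr::local_seed(23)
  g1 <- fit_class_gmm(matrix(rnorm(50), 10, 5), 3, seed = 1,
                      class_label = 1L)
  g2 <- fit_class_gmm(matrix(rnorm(50, 2), 10, 5), 2, seed = 2,
                      class_label = 2L)
  M <- build_supervectors(g1, g2)
  expect_equal(dim(M$values), c(5L, 5L))
  expect_equal(M$labels, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(unname(M$values[1:3, ]), unname(g1$means))
  swapped <- build_supervectors(g2, g1)
  expect_equal(swapped$labels, c(2L, 2L, 1L, 1L, 1L))
  g3 <- fit_class_gmm(matrix(rnorm(20), 10, 2), 2, seed = 3)
  expect_error(build_supervectors(g1, g3), "mismatch")
})

test_that("rate-1 components reproduce the input rows up to ordering", {
  withr::local_seed(24)
  X <- matrix(rnorm(16), 8, 2)
  g <- fit_class_gmm(X, 8, seed = 1)
  d <- as.matrix(dist(rbind(g$means, X)))[1:8, 9:16]
  matched <- apply(d, 2, min)
  expect_lt(max(matched), 1e-3)
})

test_that("supervector training beats random subsampling under outliers", {
  accs <- t(vapply(1:20, function(seed) {
    fx <- cluster_fixture(seed)
    n <- sum(fx$train$labels == 1)
    sv <- reduce_to_supervectors(fx$train, 0.05, seed = seed)
    acc_sv <- mean(predict_svm(train_svm(sv, 1, 1), fx$test)$labels ==
                     fx$test_labels)
    idx <- withr::with_seed(seed + 1000, unlist(lapply(1:2, function(cl)
      sample(which(fx$train$labels == cl),
             components_for_rate(0.05, n)))))
    rs <- feature_matrix(fx$train$values[idx, , drop = FALSE],
                         fx$train$labels[idx])
    acc_rs <- mean(predict_svm(train_svm(rs, 1, 1), fx$test)$labels ==
                     fx$test_labels)
    c(acc_sv, acc_rs)
  }, c(0, 0)))
  expect_gte(mean(accs[, 1]), mean(accs[, 2]))
})
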