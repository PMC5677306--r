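test_that("cohen_kappa matches hand computations and conventions", {
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  # balanced binary truth, accuracy 0.75, errors balanced -> 2*acc - 1
  truth <- rep(1:2, each = 20)
  pred <- truth
  pred[c(1:5, 21:25)] <- 3 - pred[c(1:5, 21:25)]
  expect_equal(cohen_kappa(pred, truth), 0.5)
  # confusion rows (40, 10) / (10, 40): p_o = 0.8, p_e = 0.5 -> 0.6
  truth2 <- rep(1:2, each = 50)
  pred2 <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  expect_equal(cohen_kappa(pred2, truth2), 0.6)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 0)   # p_e = 1 convention
  expect_error(cohen_kappa(1:3, 1:4), "length")
})

test_that("mutual information follows the SNR criterion", {
  withr::local_seed(40)
  truth <- rep(1:2, each = 100)
  same <- rep(c(0.3, -0.1), 100)
  expect_equal(mutual_information(c(same[1:100], same[1:100]),
                                  truth), 0)
  # construct decision values with exact class moments: gap 2, var 1
  z <- as.numeric(scale(rnorm(100)))
  d <- c(1 + z, -1 + z)
  expect_equal(mutual_information(d, truth), 0.5)
  expect_equal(mutual_information(5 * d, truth),
               mutual_information(d, truth))        # scale invariance
  # zero variance with a gap -> infinity sentinel
  expect_equal(mutual_information(rep(c(1, -1), each = 50),
                                  rep(1:2, each = 50)), Inf)
})

test_that("kappa and MI are invariant to class relabeling", {
  withr::local_seed(41)
  truth <- rep(1:2, each = 30)
  pred <- ifelse(runif(60) < 0.8, truth, 3 - truth)
  d <- rnorm(60) + ifelse(truth == 1, 1, -1)
  expect_equal(cohen_kappa(pred, truth), cohen_kappa(3 - pred, 3 - truth))
  expect_equal(mutual_information(d, truth), mutual_information(-d, 3 - truth))
})

test_that("cross-validation is exhaustive and exact on a separable toy", {
  withr::local_seed(42)
  fm <- feature_matrix(rbind(matrix(rnorm(6, -5), 3, 2),
                             matrix(rnorm(6, 5), 3, 2)),
                       rep(1:2, each = 3))
  rep1 <- repeated_cv(fm, pipeline_config(pca_threshold = 1.0),
                      repeats = 1, folds = 3, seed = 1)
  expect_equal(rep1$accuracy, 1.0)
  expect_equal(rep1$kappa, 1.0)
  expect_equal(sum(rep1$confusion), 6)
})

test_that("CV plumbing never lets test rows into the fitted models", {
  fm <- effect_features()
  fold_id <- stratified_folds(fm$labels, 10, seed = 5)
  te <- fold_id == 1
  cfg <- pipeline_config(rate = 0.3)
  f1 <- fit_fold(miwave:::subset_features(fm, !te), cfg, seed = 9)
  fm_perturbed <- fm
  fm_perturbed$values[te, ] <- fm_perturbed$values[te, ] + 1000
  f2 <- fit_fold(miwave:::subset_features(fm_perturbed, !te), cfg, seed = 9)
  expect_identical(f1$pca$W, f2$pca$W)
  expect_identical(f1$svm$support_vectors, f2$svm$support_vectors)
  expect_identical(f1$svm$dual_coefs, f2$svm$dual_coefs)
})

test_that("repeated CV is exactly reproducible under a master seed", {
  fm <- effect_features()
  r1 <- repeated_cv(fm, pipeline_config(), repeats = 2, folds = 5, seed = 3)
  r2 <- repeated_cv(fm, pipeline_config(), repeats = 2, folds = 5, seed = 3)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_error(repeated_cv(miwave:::subset_features(fm, 1:12),
                           pipeline_config(), folds = 10, seed = 1),
               "folds")
})

test_that("reduction sweep accounts for supervector training sizes", {
  fm <- effect_features()
  tab <- reduction_sweep(fm, pipeline_config(), rates = c(0.1, 1.0),
                         repeats = 1, folds = 5, seed = 2)
  expect_equal(nrow(tab), 2)
  # at rate r the SVM sees components_for_rate per class, summed
  n_tr <- sum(stratified_folds(fm$labels, 5, 1) != 1)  # per-fold train size
  per_class <- components_for_rate(0.1, 80)
  expect_equal(tab$mean_train_size[1], 2 * per_class)
  expect_equal(tab$mean_train_size[2], 160)            # all training rows
  # degenerate sweep equals repeated_cv
  tab1 <- reduction_sweep(fm, pipeline_config(), rates = 1.0,
                          repeats = 1, folds = 5, seed = 2)
  r <- repeated_cv(fm, pipeline_config(), repeats = 1, folds = 5, seed = 2)
  expect_equal(tab1$mean_accuracy, r$accuracy)
  expect_error(reduction_sweep(fm, pipeline_config(), rates = c(0, 0.5)),
               "rates")
})
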