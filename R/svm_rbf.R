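#' Radial basis kernel with width parameter sigma
#'
#' \code{K(x, y) = exp(-||x - y||^2 / (2 sigma))}: note sigma enters the
#' denominator linearly, not squared.  When delegating to libsvm (which
#' is parameterized as \code{exp(-gamma ||x - y||^2)}), the mapping is
#' \code{gamma = 1 / (2 sigma)}.
#'
#' @param x,y numeric vectors of equal length, or matrices with one
#'   observation per row (then the full cross-kernel matrix is returned).
#' @param sigma kernel width parameter, > 0.
#' @return similarity in (0, 1] (scalar) or the kernel matrix.
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.matrix(x) || is.matrix(y)) {
    x <- as.matrix(x); y <- as.matrix(y)
    if (ncol(x) != ncol(y)) stop("dimension mismatch")
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    return(exp(-pmax(d2, 0) / (2 * sigma)))
  }
  if (length(x) != length(y)) stop("dimension mismatch")
  exp(-sum((x - y)^2) / (2 * sigma))
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Solves the dual box-constrained quadratic program (via libsvm through
#' \pkg{e1071}, with \code{gamma = 1 / (2 sigma)} so the kernel equals
#' \code{\link{rbf_kernel}} exactly) and stores the support vectors, the
#' dual coefficients \code{alpha_i y_i}, and the bias.  Class 1 is the
#' positive class: decision values are positive on the class-1 side.
#'
#' @param fm a \code{feature_matrix} with both classes present.
#' @param C penalty parameter, > 0.
#' @param sigma kernel width parameter, > 0.
#' @return an \code{svm_model}: \code{support_vectors},
#'   \code{dual_coefs}, \code{bias}, \code{C}, \code{sigma},
#'   \code{n_features}.
#' @export
train_svm <- function(fm, C, sigma) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (C <= 0) stop("C must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(unique(fm$labels)) < 2)
    stop("training data contains a single class; need both")
  y <- factor(fm$labels, levels = c(1L, 2L))
  fit <- e1071::svm(x = fm$values, y = y, type = "C-classification",
                    kernel = "radial", gamma = 1 / (2 * sigma), cost = C,
                    scale = FALSE, tolerance = 1e-6)
  # libsvm: decision = sum(coefs * K(SV, x)) - rho, positive for the class
  # it met first in the data; flip signs if that class is 2 so the stored
  # expansion is always positive on the class-1 side
  flip <- if (levels(y)[fit$labels[1]] == "2") -1 else 1
  structure(list(support_vectors = unname(as.matrix(fit$SV)),
                 dual_coefs = flip * as.numeric(fit$coefs),
                 bias = flip * -fit$rho,
                 C = C, sigma = sigma,
                 n_features = ncol(fm$values)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d support vectors in %d dims; C=%g, sigma=%g\n",
              nrow(x$support_vectors), x$n_features, x$C, x$sigma))
  invisible(x)
}

#' Predict classes and decision values from a fitted SVM
#'
#' Evaluates \code{f(x) = sum_i alpha_i y_i K(s_i, x) + b} by the kernel
#' expansion over the stored support vectors; labels are 1 where
#' \code{f(x) >= 0} and 2 otherwise (ties to class 1).
#'
#' @param model an \code{svm_model}.
#' @param X a \code{feature_matrix} or numeric matrix with the training
#'   feature width.
#' @return list: \code{labels} (integer 1/2) and \code{decision}
#'   (numeric f(x)).
#' @export
predict_svm <- function(model, X) {
  stopifnot(inherits(model, "svm_model"))
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature width ", ncol(X), " does not match the training width ",
         model$n_features)
  Km <- rbf_kernel(X, model$support_vectors, model$sigma)
  f <- drop(Km %*% model$dual_coefs) + model$bias
  list(labels = ifelse(f >= 0, 1L, 2L), decision = f)
}

#' Seeded stratified fold assignment
#'
#' @param labels class codes.
#' @param folds fold count.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..folds, with each class
#'   spread as evenly as possible across folds.
#' @export
stratified_folds <- function(labels, folds, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    out[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Cross-validated grid search over C and sigma
#'
#' Exhaustive search over \code{C = 2^(-5), 2^(-3), ..., 2^15} and
#' \code{sigma = 2^(-15), 2^(-13), ..., 2^3} (exponent step 2; 11 x 10 =
#' 110 grid points) with seeded stratified k-fold cross-validation.
#' Ties in mean fold accuracy are broken toward the smallest C, then the
#' largest sigma (the simpler, smoother model).
#'
#' @param fm a \code{feature_matrix}; each class must have at least
#'   \code{folds} members.
#' @param folds fold count, default 10.
#' @param seed integer seed for the fold assignment.
#' @param C_exponents,sigma_exponents base-2 exponent grids.
#' @return a \code{grid_search_result}: \code{best_C}, \code{best_sigma},
#'   \code{fold_accuracies} (grid points x folds), \code{mean_accuracy}
#'   per grid point, \code{grid} (C, sigma per point), \code{folds}.
#' @export
grid_search <- function(fm, folds = 10L, seed = 1L,
                        C_exponents = seq(-5L, 15L, by = 2L),
                        sigma_exponents = seq(-15L, 3L, by = 2L)) {
  stopifnot(inherits(fm, "feature_matrix"))
  cnt <- tabulate(fm$labels, 2L)
  if (any(cnt < folds))
    stop("class with ", min(cnt[cnt > 0]), " members cannot fill ", folds,
         " folds; use fewer folds")
  grid <- expand.grid(C = 2^C_exponents, sigma = 2^sigma_exponents,
                      KEEP.OUT.ATTRS = FALSE)
  fold_id <- stratified_folds(fm$labels, folds, seed)
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fm_tr <- feature_matrix(fm$values[tr, , drop = FALSE], fm$labels[tr],
                            fm$feature_names)
    X_te <- fm$values[!tr, , drop = FALSE]
    y_te <- fm$labels[!tr]
    for (g in seq_len(nrow(grid))) {
      mdl <- train_svm(fm_tr, grid$C[g], grid$sigma[g])
      acc[g, k] <- mean(predict_svm(mdl, X_te)$labels == y_te)
    }
  }
  mean_acc <- rowMeans(acc)
  best <- order(-mean_acc, grid$C, -grid$sigma)[1]
  structure(list(best_C = grid$C[best], best_sigma = grid$sigma[best],
                 fold_accuracies = acc, mean_accuracy = mean_acc,
                 grid = grid, folds = as.integer(folds)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %d points x %d folds; best C=%g, sigma=%g (CV acc %.3f)\n",
    nrow(x$grid), x$folds, x$best_C, x$best_sigma, max(x$mean_accuracy)))
  invisible(x)
}
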