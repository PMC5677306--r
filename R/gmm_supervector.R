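#' Mixture component count for a training-set reduction rate
#'
#' Maps a per-class reduction rate onto a Gaussian component count:
#' \code{max(1, round(rate * n_class))}, capped at \code{n_class}.  At
#' rate 0.30 and 270 class trials this gives 81 components, i.e. the
#' class's share of a training set reduced to 30\% of its size.
#'
#' @param rate fraction in (0, 1].
#' @param n_class number of training trials in the class (>= 1).
#' @return integer component count.
#' @export
components_for_rate <- function(rate, n_class) {
  if (!(rate > 0 && rate <= 1)) stop("rate must lie in (0, 1]")
  if (n_class < 1) stop("n_class must be >= 1")
  min(max(1L, as.integer(round(rate * n_class))), as.integer(n_class))
}

# log N(x | mu, diag(v)) for all rows of X against all components:
# returns n x m matrix of log densities.
gmm_log_dens <- function(X, means, vars) {
  n <- nrow(X); m <- nrow(means); K <- ncol(X)
  out <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    v <- vars[j, ]
    d <- sweep(X, 2, means[j, ])
    out[, j] <- -0.5 * (K * log(2 * pi) + sum(log(v)) +
                          rowSums(sweep(d^2, 2, v, "/")))
  }
  out
}

#' E-step responsibilities of a diagonal-covariance Gaussian mixture
#'
#' Evaluates, for every data row, the posterior probability of each
#' mixture component: the weighted Gaussian density normalized over
#' components.  Exposed so a single step can be verified directly.
#'
#' @param X numeric matrix, n x K.
#' @param weights mixture weights, length m, summing to 1.
#' @param means m x K component means.
#' @param vars m x K diagonal covariances.
#' @return list: \code{resp} (n x m responsibilities, rows sum to 1) and
#'   \code{log_lik} (total data log-likelihood).
#' @export
gmm_estep <- function(X, weights, means, vars) {
  lg <- sweep(gmm_log_dens(X, means, vars), 2, log(weights), "+")
  mx <- apply(lg, 1, max)
  w <- exp(lg - mx)
  sw <- rowSums(w)
  list(resp = w / sw, log_lik = sum(log(sw) + mx))
}

#' Fit a per-class diagonal-covariance Gaussian mixture by EM
#'
#' Maximum-likelihood fit of an m-component mixture with diagonal
#' covariances.  Initialization is seeded k-means; \code{n_restarts}
#' independent starts are run and the fit with the best final
#' log-likelihood kept.  Variances are floored at
#' \code{var_floor_frac} times the per-feature data variance after every
#' M-step, which also makes the degenerate one-component-per-point fit
#' well defined.
#'
#' @param X numeric matrix (or \code{feature_matrix}) of one class's rows.
#' @param m component count, \code{1 <= m <= nrow(X)}.
#' @param seed integer seed controlling initialization.
#' @param class_label class code stored with the model.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap per restart.
#' @param n_restarts independent k-means starts.
#' @param var_floor_frac variance floor as a fraction of the per-feature
#'   data variance.
#' @return a \code{class_gmm}: \code{weights}, \code{means} (m x K),
#'   \code{vars} (m x K), \code{m}, \code{class_label},
#'   \code{log_likelihood_trace}, \code{converged}.
#' @export
fit_class_gmm <- function(X, m, seed = 1L, class_label = NA_integer_,
                          tol = 1e-6, max_iter = 300L, n_restarts = 10L,
                          var_floor_frac = 1e-6) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  if (n == 0L) stop("empty input")
  if (m > n) stop("component count ", m, " exceeds row count ", n)
  data_var <- apply(X, 2, function(col) mean((col - mean(col))^2))
  floor_v <- pmax(var_floor_frac * data_var, 1e-12)
  best <- NULL
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (r in seq_len(n_restarts)) {
    centers <- if (m == n) X else
      tryCatch(stats::kmeans(X, centers = m, nstart = 1,
                             iter.max = 50)$centers,
               error = function(e) X[sample(n, m), , drop = FALSE])
    means <- matrix(as.numeric(centers), m, K)
    vars <- matrix(rep(pmax(data_var, floor_v), each = m), m, K)
    weights <- rep(1 / m, m)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- gmm_estep(X, weights, means, vars)
      trace <- c(trace, es$log_lik)
      nk <- colSums(es$resp)
      weights <- nk / n
      for (j in seq_len(m)) {
        rj <- es$resp[, j]
        if (nk[j] < 1e-10) next                # dead component: freeze
        means[j, ] <- colSums(X * rj) / nk[j]
        d2 <- sweep(X, 2, means[j, ])^2
        vars[j, ] <- pmax(colSums(d2 * rj) / nk[j], floor_v)
      }
      if (it > 1 &&
          abs(trace[it] - trace[it - 1]) <=
            tol * (abs(trace[it - 1]) + 1e-10)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || trace[length(trace)] > best$ll) {
      best <- list(weights = weights, means = means, vars = vars,
                   trace = trace, converged = converged,
                   ll = trace[length(trace)])
    }
    if (m == n) break                          # init is deterministic
  }
  structure(list(weights = best$weights, means = best$means,
                 vars = best$vars, m = as.integer(m),
                 class_label = as.integer(class_label),
                 log_likelihood_trace = best$trace,
                 converged = best$converged),
            class = "class_gmm")
}

#' @export
print.class_gmm <- function(x, ...) {
  cat(sprintf(
    "<class_gmm> class %s: %d components in %d dims; logLik %.4f (%s)\n",
    x$class_label, x$m, ncol(x$means),
    x$log_likelihood_trace[length(x$log_likelihood_trace)],
    if (x$converged) "converged" else "max-iteration stop"))
  invisible(x)
}

#' Stack two class mixtures into a supervector training set
#'
#' Keeps only the component mean vectors — the "supervectors" — of each
#' class's mixture, stacked class 1 first, and labels each row with its
#' class.  Weights and variances are deliberately discarded: the reduced
#' training set consists of representative points only.
#'
#' @param g1,g2 \code{class_gmm} objects for classes 1 and 2, fitted on
#'   the same feature dimensionality.
#' @return a \code{feature_matrix} of \code{m1 + m2} rows.
#' @export
build_supervectors <- function(g1, g2) {
  stopifnot(inherits(g1, "class_gmm"), inherits(g2, "class_gmm"))
  if (ncol(g1$means) != ncol(g2$means))
    stop("feature dimensionality mismatch: ", ncol(g1$means), " vs ",
         ncol(g2$means))
  lab1 <- if (is.na(g1$class_label)) 1L else g1$class_label
  lab2 <- if (is.na(g2$class_label)) 2L else g2$class_label
  feature_matrix(rbind(g1$means, g2$means),
                 c(rep(lab1, g1$m), rep(lab2, g2$m)),
                 sprintf("pc%d", seq_len(ncol(g1$means))))
}

#' Reduce a labeled training set to GMM supervectors
#'
#' Convenience wrapper: splits a \code{feature_matrix} by class, fits one
#' mixture per class with \code{\link{components_for_rate}} components,
#' and stacks the mean vectors.  At \code{rate >= 1} the input is
#' returned unchanged (no reduction).
#'
#' @param fm a \code{feature_matrix} with both classes present.
#' @param rate per-class reduction rate in (0, 1].
#' @param seed integer seed for the EM initializations.
#' @param ... passed to \code{\link{fit_class_gmm}}.
#' @return a \code{feature_matrix} of supervectors (or \code{fm} itself
#'   at rate 1).
#' @export
reduce_to_supervectors <- function(fm, rate, seed = 1L, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (rate >= 1) return(fm)
  gs <- lapply(1:2, function(cl) {
    rows <- fm$labels == cl
    if (!any(rows)) stop("class ", cl, " absent from the training set")
    fit_class_gmm(fm$values[rows, , drop = FALSE],
                  components_for_rate(rate, sum(rows)),
                  seed = seed + cl, class_label = cl, ...)
  })
  build_supervectors(gs[[1]], gs[[2]])
}

# save/restore .Random.seed so seeded fits do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
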