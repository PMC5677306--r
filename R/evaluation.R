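#' Cohen's kappa for two label vectors
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with
#' \code{p_o} the observed agreement and \code{p_e} the expected
#' agreement from the marginal label frequencies.  When \code{p_e = 1}
#' (both vectors constant and equal) kappa is defined as 0.
#'
#' @param pred,truth equal-length label vectors.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (length(pred) == 0) stop("need at least one element")
  lv <- sort(unique(c(pred, truth)))
  p <- factor(pred, levels = lv); t <- factor(truth, levels = lv)
  tab <- table(p, t) / length(pred)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

#' Mutual information (in bits) of classifier outputs
#'
#' The BCI-competition performance criterion applied to the per-trial
#' decision values: \code{MI = 0.5 * log2(1 + SNR)} with
#' \code{SNR = ((mu1 - mu2) / 2)^2 / ((var1 + var2) / 2)}, where
#' \code{mu_c, var_c} are the class-conditional mean and unbiased
#' variance of the decision values.  Zero within-class variance with a
#' nonzero mean gap returns \code{Inf} (perfectly separated outputs).
#'
#' @param decision_values numeric per-trial classifier outputs.
#' @param truth class labels (both classes must be present).
#' @return mutual information in bits.
#' @export
mutual_information <- function(decision_values, truth) {
  if (length(decision_values) != length(truth))
    stop("decision values and truth must have equal length")
  cls <- sort(unique(truth))
  if (length(cls) != 2) stop("both classes must be present")
  d1 <- decision_values[truth == cls[1]]
  d2 <- decision_values[truth == cls[2]]
  gap <- mean(d1) - mean(d2)
  v <- (stats::var(d1) + stats::var(d2)) / 2
  if (!is.finite(v) || v <= 0) {
    if (abs(gap) > 0) return(Inf)
    return(0)
  }
  snr <- (gap / 2)^2 / v
  0.5 * log2(1 + snr)
}

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline: preprocessing
#' (band edges in Hz, cue-relative crop window in s, channel subset),
#' the feature configurations, the PCA retained-variance threshold, the
#' supervector reduction rate (1 = no reduction), and the classifier
#' settings.  When \code{use_grid_search} is FALSE, the SVM is trained
#' at the fixed \code{C} and \code{sigma} (\code{sigma = NULL} means the
#' dimension heuristic \code{sigma = K / 2}, i.e. libsvm's default
#' \code{gamma = 1/K} under the \code{gamma = 1/(2 sigma)} mapping).
#'
#' @param band_lo,band_hi band-pass edges, Hz.
#' @param crop_start,crop_end cue-relative crop window, s.
#' @param channels channel subset (NULL = keep all).
#' @param cwt a \code{cwt_config}.
#' @param dwt a \code{dwt_config}, or NULL to pick by sampling rate.
#' @param pca_threshold PCA retained-variance fraction.
#' @param rate supervector reduction rate in (0, 1].
#' @param use_grid_search run the C/sigma grid search inside each
#'   training fold.
#' @param C,sigma fixed SVM hyperparameters when the grid search is off.
#' @param grid_folds inner fold count for the grid search.
#' @param C_exponents,sigma_exponents base-2 exponent grids.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(band_lo = 0.5, band_hi = 30,
                            crop_start = 0.5, crop_end = 6,
                            channels = NULL,
                            cwt = cwt_config(), dwt = NULL,
                            pca_threshold = 0.98,
                            rate = 1.0,
                            use_grid_search = FALSE,
                            C = 1, sigma = NULL,
                            grid_folds = 10L,
                            C_exponents = seq(-5L, 15L, by = 2L),
                            sigma_exponents = seq(-15L, 3L, by = 2L)) {
  if (!(band_lo > 0 && band_lo < band_hi)) stop("require 0 < band_lo < band_hi")
  if (!(crop_start < crop_end)) stop("require crop_start < crop_end")
  if (!(rate > 0 && rate <= 1)) stop("rate must lie in (0, 1]")
  if (!(pca_threshold > 0 && pca_threshold <= 1))
    stop("pca_threshold must lie in (0, 1]")
  if (C <= 0) stop("C must be > 0")
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 crop_start = crop_start, crop_end = crop_end,
                 channels = channels, cwt = cwt, dwt = dwt,
                 pca_threshold = pca_threshold, rate = rate,
                 use_grid_search = use_grid_search, C = C, sigma = sigma,
                 grid_folds = as.integer(grid_folds),
                 C_exponents = C_exponents,
                 sigma_exponents = sigma_exponents),
            class = "pipeline_config")
}

#' Preprocess a trial set per a pipeline configuration
#'
#' Channel selection, zero-phase band-pass, cue-relative crop.
#'
#' @param ts an \code{eeg_trial_set}.
#' @param cfg a \code{pipeline_config}.
#' @return the preprocessed \code{eeg_trial_set}.
#' @export
preprocess_trials <- function(ts, cfg = pipeline_config()) {
  if (!is.null(cfg$channels)) ts <- select_channels(ts, cfg$channels)
  ts <- bandpass(ts, cfg$band_lo, cfg$band_hi)
  crop(ts, cfg$crop_start, cfg$crop_end)
}

#' Extract the combined wavelet feature matrix
#'
#' CWT log band-power block followed by the DWT sub-band statistic
#' block: 48 + 48 = 96 features for two-channel trials under default
#' configurations.
#'
#' @param ts a preprocessed \code{eeg_trial_set}.
#' @param cfg a \code{pipeline_config}.
#' @return a \code{feature_matrix}.
#' @export
extract_combined_features <- function(ts, cfg = pipeline_config()) {
  dwt_cfg <- if (is.null(cfg$dwt)) dwt_config_for_fs(ts$fs) else cfg$dwt
  concat_features(cwt_features(ts, cfg$cwt), dwt_features(ts, dwt_cfg))
}

# deterministic fan-out of a master seed into stage seeds
stage_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 10007 + counter) %% 2147483647)
}

#' Fit one training fold of the pipeline
#'
#' PCA fit, optional supervector reduction, optional grid search, and
#' SVM training — all strictly on the supplied training rows.
#'
#' @param fm_train a \code{feature_matrix} of training rows.
#' @param cfg a \code{pipeline_config}.
#' @param seed integer seed for the reduction and fold assignment.
#' @return list: \code{pca}, \code{svm}, \code{C}, \code{sigma},
#'   \code{n_train_rows} (rows seen by the SVM).
#' @export
fit_fold <- function(fm_train, cfg, seed = 1L) {
  pca <- fit_pca(fm_train, cfg$pca_threshold)
  S <- apply_pca(fm_train, pca)
  if (cfg$rate < 1)
    S <- reduce_to_supervectors(S, cfg$rate, seed = stage_seed(seed, 1L))
  if (cfg$use_grid_search) {
    gs <- grid_search(S, folds = min(cfg$grid_folds, min(tabulate(S$labels, 2L))),
                      seed = stage_seed(seed, 2L),
                      C_exponents = cfg$C_exponents,
                      sigma_exponents = cfg$sigma_exponents)
    C <- gs$best_C; sigma <- gs$best_sigma
  } else {
    C <- cfg$C
    sigma <- if (is.null(cfg$sigma)) ncol(S$values) / 2 else cfg$sigma
  }
  list(pca = pca, svm = train_svm(S, C, sigma), C = C, sigma = sigma,
       n_train_rows = nrow(S$values))
}

#' Predict a test fold from a fitted fold
#'
#' @param fold the result of \code{\link{fit_fold}}.
#' @param fm_test a \code{feature_matrix} of test rows (original feature
#'   width; the fold's PCA is applied first).
#' @return list: \code{labels}, \code{decision}.
#' @export
predict_fold <- function(fold, fm_test) {
  predict_svm(fold$svm, apply_pca(fm_test, fold$pca))
}

subset_features <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$labels[rows],
                 fm$feature_names)
}

#' Repeated stratified cross-validated evaluation
#'
#' Runs \code{repeats} independent stratified \code{folds}-fold
#' cross-validations of the full pipeline.  All data-dependent fitting
#' (PCA, mixture reduction, grid search, SVM) happens inside each
#' training fold; the held-out fold is only transformed and scored.
#' Feature extraction itself is per-trial and therefore computed once up
#' front.
#'
#' @param ts an \code{eeg_trial_set} (raw; preprocessing is applied), or
#'   a \code{feature_matrix} of already-extracted features.
#' @param cfg a \code{pipeline_config}.
#' @param repeats number of repetitions, default 10.
#' @param folds fold count, default 10.
#' @param seed master seed.
#' @return an \code{eval_report}: \code{accuracy}, \code{accuracy_sd}
#'   (mean/sd over repeats x folds), \code{kappa}, \code{mi_bits},
#'   \code{confusion} (2 x 2, truth in rows, summed over everything),
#'   \code{per_repeat} data frame, \code{fold_accuracies},
#'   \code{mean_train_size}.
#' @export
repeated_cv <- function(ts, cfg = pipeline_config(), repeats = 10L,
                        folds = 10L, seed = 1L) {
  fm <- if (inherits(ts, "feature_matrix")) ts
        else extract_combined_features(preprocess_trials(ts, cfg), cfg)
  cnt <- tabulate(fm$labels, 2L)
  if (any(cnt < folds))
    stop("smallest class has ", min(cnt), " trials; cannot make ", folds,
         " folds")
  n <- nrow(fm$values)
  fold_acc <- matrix(NA_real_, repeats, folds)
  train_sizes <- matrix(NA_real_, repeats, folds)
  per_repeat <- data.frame(repeat_id = seq_len(repeats), accuracy = NA_real_,
                           kappa = NA_real_, mi_bits = NA_real_)
  confusion <- matrix(0, 2, 2,
                      dimnames = list(truth = 1:2, predicted = 1:2))
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(fm$labels, folds,
                                seed = stage_seed(seed, 100L + r))
    pred_all <- integer(n); dec_all <- numeric(n)
    for (k in seq_len(folds)) {
      te <- fold_id == k
      fold <- fit_fold(subset_features(fm, !te), cfg,
                       seed = stage_seed(seed, 1000L * r + k))
      pr <- predict_fold(fold, subset_features(fm, te))
      pred_all[te] <- pr$labels
      dec_all[te] <- pr$decision
      fold_acc[r, k] <- mean(pr$labels == fm$labels[te])
      train_sizes[r, k] <- fold$n_train_rows
    }
    per_repeat$accuracy[r] <- mean(pred_all == fm$labels)
    per_repeat$kappa[r] <- cohen_kappa(pred_all, fm$labels)
    per_repeat$mi_bits[r] <- mutual_information(dec_all, fm$labels)
    for (i in 1:2) for (j in 1:2)
      confusion[i, j] <- confusion[i, j] +
        sum(fm$labels == i & pred_all == j)
  }
  structure(list(accuracy = mean(fold_acc), accuracy_sd = stats::sd(fold_acc),
                 kappa = mean(per_repeat$kappa),
                 mi_bits = mean(per_repeat$mi_bits),
                 confusion = confusion, per_repeat = per_repeat,
                 fold_accuracies = fold_acc,
                 mean_train_size = mean(train_sizes),
                 repeats = repeats, folds = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %dx%d-fold CV: accuracy %.3f +- %.3f, kappa %.3f, MI %.3f bit\n",
    x$repeats, x$folds, x$accuracy, x$accuracy_sd, x$kappa, x$mi_bits))
  cat("  confusion (truth x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Accuracy over a sweep of supervector reduction rates
#'
#' Repeats the cross-validated evaluation at each reduction rate.  The
#' rate-1.0 row is the no-reduction baseline: every training row goes
#' straight to the SVM.
#'
#' @param ts an \code{eeg_trial_set} or pre-extracted
#'   \code{feature_matrix}.
#' @param cfg a \code{pipeline_config}; its \code{rate} is overridden.
#' @param rates reduction rates in (0, 1].
#' @param repeats CV repetitions per rate.
#' @param folds fold count.
#' @param seed master seed (shared across rates, so fold splits match).
#' @return data frame with columns \code{rate}, \code{mean_accuracy},
#'   \code{sd_accuracy}, \code{mean_train_size}; the per-rate
#'   \code{eval_report}s are attached as the \code{"reports"} attribute.
#' @export
reduction_sweep <- function(ts, cfg = pipeline_config(), rates = c(0.3, 1.0),
                            repeats = 10L, folds = 10L, seed = 1L) {
  if (any(rates <= 0 | rates > 1)) stop("rates must lie in (0, 1]")
  fm <- if (inherits(ts, "feature_matrix")) ts
        else extract_combined_features(preprocess_trials(ts, cfg), cfg)
  reports <- lapply(rates, function(r) {
    cfg$rate <- r
    repeated_cv(fm, cfg, repeats = repeats, folds = folds, seed = seed)
  })
  out <- data.frame(
    rate = rates,
    mean_accuracy = vapply(reports, function(x) x$accuracy, 0),
    sd_accuracy = vapply(reports, function(x) x$accuracy_sd, 0),
    mean_train_size = vapply(reports, function(x) x$mean_train_size, 0))
  attr(out, "reports") <- reports
  out
}
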