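# Fixtures are generated in code; nothing is read from disk.

# small deterministic trial set: pure sinusoids + a little white noise
toy_trials <- function(n_per_class = 4, fs = 128, duration = 5.5,
                       freqs = c(10, 20), seed = 99) {
  withr::with_seed(seed, {
    L <- round(duration * fs)
    tt <- (seq_len(L) - 1) / fs
    ntr <- 2 * n_per_class
    dat <- array(0, c(ntr, 2, L))
    for (i in seq_len(ntr))
      for (c in 1:2)
        dat[i, c, ] <- rowSums(sapply(freqs, function(f)
          sin(2 * pi * f * tt + runif(1, 0, 2 * pi)))) +
          0.1 * rnorm(L)
    eeg_trial_set(dat, fs, rep(1:2, n_per_class), c("C3", "C4"), t0 = 0.5)
  })
}

# two Gaussian clusters with a fraction of gross outliers in the training
# rows; clean test rows.  Mirrors the noisy-training-data setting the
# supervector reduction is meant to be robust to.
cluster_fixture <- function(seed, n_train = 100, n_test = 200, sep = 2,
                            outlier_frac = 0.05) {
  withr::with_seed(seed, {
    mk <- function(mu, n) cbind(rnorm(n, mu), rnorm(n))
    tr <- rbind(mk(-sep, n_train), mk(sep, n_train))
    lab <- rep(1:2, each = n_train)
    n_out <- round(outlier_frac * 2 * n_train)
    out <- sample(2 * n_train, n_out)
    tr[out, ] <- matrix(runif(2 * n_out, -20, 20), ncol = 2)
    te <- rbind(mk(-sep, n_test), mk(sep, n_test))
    list(train = feature_matrix(tr, lab),
         test = te, test_labels = rep(1:2, each = n_test))
  })
}

# the four-point XOR configuration, not linearly separable
xor_features <- function() {
  feature_matrix(rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
                 c(1L, 1L, 2L, 2L))
}

# shared pipeline fixtures for the slower evaluation tests (built once)
effect_trials <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_trials(synth_config(n_per_class = 100,
                                           erd_factor = 0.3,
                                           noise_sigma = 1, seed = 11))
    val
  }
})

effect_features <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- pipeline_config()
      val <<- extract_combined_features(
        preprocess_trials(effect_trials(), cfg), cfg)
    }
    val
  }
})
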