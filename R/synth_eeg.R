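#' Configuration for the synthetic motor-imagery trial generator
#'
#' Generates two-class trial sets that emulate the event-related
#' desynchronization (ERD) signature of hand motor imagery: mu (~10 Hz)
#' and beta (~20 Hz) oscillations over 1/f background noise, with the
#' oscillation amplitudes on the contralateral channel attenuated by the
#' factor \code{erd_factor}.  Left-hand imagery (class 1) attenuates C4,
#' right-hand imagery (class 2) attenuates C3.  \code{erd_factor = 1}
#' makes the class distributions identical (null data);
#' \code{erd_factor = 0} silences the contralateral rhythms entirely.
#' ERD is modeled as sustained attenuation over the whole trial — the
#' pipeline averages power over the crop, so a time-locked envelope
#' would not change any feature it extracts.
#'
#' @param n_per_class trials per class.
#' @param fs sampling rate, Hz.
#' @param duration trial length, s.
#' @param channels channel names (contralateral convention assumes
#'   C3/C4 are present).
#' @param mu_freq,beta_freq rhythm frequencies, Hz.
#' @param mu_amp,beta_amp oscillation amplitudes, microvolts.
#' @param erd_factor contralateral amplitude attenuation in [0, 1].
#' @param noise_sigma 1/f background noise scale (standard deviation),
#'   microvolts.
#' @param t0 time of the first sample relative to cue onset, s.
#' @param seed integer seed; the generated set is fully determined by it.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_per_class = 100L, fs = 128, duration = 5.5,
                         channels = c("C3", "C4"),
                         mu_freq = 10, beta_freq = 20,
                         mu_amp = 6, beta_amp = 3,
                         erd_factor = 0.5, noise_sigma = 2,
                         t0 = 0.5, seed = 1L) {
  if (!(erd_factor >= 0 && erd_factor <= 1))
    stop("erd_factor must lie in [0, 1]")
  if (fs <= 2 * beta_freq)
    stop("fs must exceed twice the beta frequency")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(n_per_class = as.integer(n_per_class), fs = fs,
                 duration = duration, channels = channels,
                 mu_freq = mu_freq, beta_freq = beta_freq,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 erd_factor = erd_factor, noise_sigma = noise_sigma,
                 t0 = t0, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f ("pink") noise of length n: white Gaussian spectrum shaped by
# 1/sqrt(f), unit variance
pink_noise <- function(n) {
  nf <- floor(n / 2)
  odd <- n %% 2 == 1
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) /
    sqrt(seq_len(nf))
  if (!odd) z[nf] <- complex(real = Re(z[nf]), imaginary = 0)  # Nyquist real
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  idx <- 2:(nf + if (odd) 1L else 0L)
  spec[n + 2 - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a two-class motor-imagery trial set
#'
#' See \code{\link{synth_config}} for the generative model.  Trials
#' alternate class 1, class 2, ... so labels are balanced and
#' interleaved; each trial draws independent rhythm phases and noise.
#'
#' @param cfg a \code{synth_config}.
#' @return an \code{eeg_trial_set} of \code{2 * n_per_class} trials.
#' @export
simulate_trials <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  L <- round(cfg$duration * cfg$fs)
  nc <- length(cfg$channels)
  ntr <- 2L * cfg$n_per_class
  tt <- (seq_len(L) - 1) / cfg$fs
  labels <- rep(c(1L, 2L), cfg$n_per_class)
  dat <- array(NA_real_, c(ntr, nc, L))
  contra <- function(lab) if (lab == 1L) "C4" else "C3"
  for (i in seq_len(ntr)) {
    att_ch <- contra(labels[i])
    for (c in seq_len(nc)) {
      g <- if (cfg$channels[c] == att_ch) cfg$erd_factor else 1
      ph_mu <- stats::runif(1, 0, 2 * pi)
      ph_beta <- stats::runif(1, 0, 2 * pi)
      dat[i, c, ] <- cfg$noise_sigma * pink_noise(L) +
        g * cfg$mu_amp * sin(2 * pi * cfg$mu_freq * tt + ph_mu) +
        g * cfg$beta_amp * sin(2 * pi * cfg$beta_freq * tt + ph_beta)
    }
  }
  eeg_trial_set(dat, cfg$fs, labels, cfg$channels, cfg$t0)
}

#' Write a trial set to disk as a test fixture
#'
#' @param ts an \code{eeg_trial_set}.
#' @param path output file path.
#' @param format \code{"columnar"} (bit-exact round trip) or
#'   \code{"edf"} (16-bit quantized; labels in a sidecar file).
#' @return \code{path}, invisibly.
#' @export
write_fixture <- function(ts, path, format = c("columnar", "edf")) {
  format <- match.arg(format)
  switch(format,
         columnar = write_trials_columnar(ts, path),
         edf = write_trials_edf(ts, path))
}
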