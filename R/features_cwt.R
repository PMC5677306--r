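#' Configuration for Morlet CWT log band-power features
#'
#' Power is extracted in 1 Hz bins across 6--30 Hz by default (24 bins),
#' one complex Morlet scale per bin at the bin's center frequency
#' (6.5, 7.5, ..., 29.5 Hz).  \code{wavelet_param} is the dimensionless
#' Morlet center frequency omega0; the default is chosen so the wavelet's
#' half-power bandwidth at 10 Hz is 2 Hz
#' (omega0 = 2 sqrt(ln 2) * 10 / 2 = 8.3255), a resolution that separates
#' neighbouring 1 Hz bins without smearing mu-band power into the beta
#' band.  \code{log_floor} is a strictly positive offset added under the
#' log; it is interpreted relative to the mean trial power (and used as an
#' absolute floor for an all-zero trial), preventing -Inf on silent
#' channels.
#'
#' @param f_lo,f_hi band limits in Hz.
#' @param bin_width bin width in Hz; \code{(f_hi - f_lo) / bin_width}
#'   must be a positive integer.
#' @param wavelet_param Morlet time-frequency parameter omega0.
#' @param log_floor relative power floor for the log transform.
#' @return a \code{cwt_config} list.
#' @export
cwt_config <- function(f_lo = 6, f_hi = 30, bin_width = 1,
                       wavelet_param = 2 * sqrt(log(2)) * 10 / 2,
                       log_floor = 1e-12) {
  if (!(f_lo < f_hi)) stop("require f_lo < f_hi")
  nb <- (f_hi - f_lo) / bin_width
  if (abs(nb - round(nb)) > 1e-9 || nb < 1)
    stop("(f_hi - f_lo) / bin_width must be a positive integer")
  if (log_floor <= 0) stop("log_floor must be > 0")
  structure(list(f_lo = f_lo, f_hi = f_hi, bin_width = bin_width,
                 wavelet_param = wavelet_param, log_floor = log_floor,
                 n_bins = as.integer(round(nb))),
            class = "cwt_config")
}

#' Bin center frequencies of a CWT configuration
#' @param cfg a \code{cwt_config}.
#' @return numeric vector of center frequencies in Hz.
#' @export
cwt_center_freqs <- function(cfg) {
  cfg$f_lo + cfg$bin_width * (seq_len(cfg$n_bins) - 0.5)
}

#' Complex Morlet continuous wavelet transform
#'
#' Computes the CWT of a real signal at the scales corresponding to the
#' requested center frequencies, using the analytic Morlet mother wavelet
#' psi(t) = pi^(-1/4) exp(i omega0 t) exp(-t^2 / 2) with the 1/sqrt(a)
#' scale normalization.  Coefficients are computed by FFT convolution
#' with zero padding beyond the signal ends; \code{Mod(coef)^2} is the
#' time-resolved power at each scale.
#'
#' @param x real numeric vector, length >= 2.
#' @param center_freqs frequencies in Hz at which to place scales; each
#'   must be below \code{fs / 2}.
#' @param fs sampling rate in Hz.
#' @param omega0 Morlet time-frequency parameter.
#' @return complex matrix, \code{length(center_freqs)} x \code{length(x)};
#'   row i holds the coefficients for \code{center_freqs[i]}.
#' @export
morlet_cwt <- function(x, center_freqs, fs,
                       omega0 = 2 * sqrt(log(2)) * 10 / 2) {
  L <- length(x)
  if (L < 2) stop("signal must have length >= 2")
  if (any(center_freqs >= fs / 2))
    stop("center frequency at or above the Nyquist frequency ", fs / 2, " Hz")
  if (any(center_freqs <= 0)) stop("center frequencies must be positive")
  dt <- 1 / fs
  scales <- omega0 / (2 * pi * center_freqs)          # seconds
  half <- ceiling(6 * max(scales) * fs)               # +-6 sd of envelope
  nfft <- 2^ceiling(log2(L + 2 * half + 1))
  X <- stats::fft(c(x, rep(0, nfft - L)))
  out <- matrix(0i, nrow = length(center_freqs), ncol = L)
  m <- seq(-half, half)
  for (i in seq_along(scales)) {
    a <- scales[i]
    tt <- m * dt / a
    # conj(psi) sampled backwards: correlation of x with the scaled wavelet
    g <- Conj(pi^(-0.25) * exp(1i * omega0 * tt) * exp(-tt^2 / 2)) *
      dt / sqrt(a)
    kern <- rev(g)                                    # convolution kernel
    kpad <- complex(length.out = nfft)
    kpad[seq_along(kern)] <- kern
    conv <- stats::fft(X * stats::fft(kpad), inverse = TRUE) / nfft
    # linear convolution index of sample b is b + half (kernel center)
    out[i, ] <- conv[half + seq_len(L)]
  }
  out
}

#' Morlet log band-power feature matrix
#'
#' For each trial, channel and 1 Hz bin: the natural log of the mean (over
#' the whole trial) squared-magnitude CWT coefficient at the bin's center
#' frequency, plus the power floor.  Feature order is channel-major,
#' ascending frequency within a channel: with 2 channels and the default
#' 24 bins, 48 features per trial.
#'
#' @param ts an \code{eeg_trial_set}, band-limited to cover
#'   \code{[f_lo, f_hi]}.
#' @param cfg a \code{cwt_config}.
#' @return a \code{feature_matrix} (see \code{\link{feature_matrix}}),
#'   N trials x (channels * bins).
#' @export
cwt_features <- function(ts, cfg = cwt_config()) {
  stopifnot(inherits(ts, "eeg_trial_set"), inherits(cfg, "cwt_config"))
  L <- n_samples(ts)
  if (L < ts$fs / cfg$f_lo)
    stop("trial shorter than one period of the lowest analysis frequency")
  freqs <- cwt_center_freqs(cfg)
  nt <- n_trials(ts); nc <- n_channels(ts); nb <- cfg$n_bins
  vals <- matrix(NA_real_, nrow = nt, ncol = nc * nb)
  for (i in seq_len(nt)) {
    mean_pow <- mean(ts$data[i, , ]^2)
    floor_i <- if (mean_pow > 0) cfg$log_floor * mean_pow else cfg$log_floor
    for (c in seq_len(nc)) {
      W <- morlet_cwt(ts$data[i, c, ], freqs, ts$fs, cfg$wavelet_param)
      vals[i, (c - 1) * nb + seq_len(nb)] <-
        log(rowMeans(Mod(W)^2) + floor_i)
    }
  }
  feature_matrix(vals, ts$labels,
                 as.vector(outer(sprintf("%.1fHz", freqs),
                                 ts$channel_names,
                                 function(f, ch) paste0("cwt_", ch, "_", f))))
}
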