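# db4 scaling (low-pass decomposition) filter, sum = sqrt(2).  Standard
# Daubechies 4-vanishing-moment coefficients; the QMF high-pass is derived
# below.
DB4_H <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
           -0.02798376941698385, -0.1870348117188811, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728)

#' Configuration for db4 sub-band statistic features
#'
#' The trial signal is decomposed into \code{n_levels} detail bands plus
#' an approximation by an orthogonal db4 DWT with periodic boundary
#' extension.  Three consecutive detail levels are assigned to the beta,
#' mu and theta rhythms.  With the level rule of
#' \code{\link{dwt_config_for_fs}}: at fs <= 160 Hz, 4 levels with
#' \{D2 = beta, D3 = mu, D4 = theta\}; above 160 Hz, 5 levels with
#' \{D3, D4, D5\} — detail level j nominally covers
#' (fs / 2^(j+1), fs / 2^j] Hz, so these choices put ~8--16 Hz in the mu
#' band for the common 125/128 and 250 Hz EEG rates.
#'
#' @param wavelet wavelet name; only \code{"db4"} is supported.
#' @param n_levels decomposition depth, 4 or 5.
#' @param rhythm_bands integer vector of the three consecutive detail
#'   levels assigned to (beta, mu, theta), finest first.
#' @return a \code{dwt_config} list.
#' @export
dwt_config <- function(wavelet = "db4", n_levels = 4L,
                       rhythm_bands = c(2L, 3L, 4L)) {
  if (wavelet != "db4") stop("only the db4 wavelet is supported")
  n_levels <- as.integer(n_levels)
  if (!n_levels %in% c(4L, 5L)) stop("n_levels must be 4 or 5")
  rhythm_bands <- as.integer(rhythm_bands)
  if (length(rhythm_bands) != 3L ||
      !all(diff(rhythm_bands) == 1L) ||
      min(rhythm_bands) < 1L || max(rhythm_bands) > n_levels)
    stop("rhythm_bands must be three consecutive detail levels within 1..",
         n_levels)
  structure(list(wavelet = wavelet, n_levels = n_levels,
                 rhythm_bands = rhythm_bands),
            class = "dwt_config")
}

#' @rdname dwt_config
#' @param fs sampling rate in Hz.
#' @export
dwt_config_for_fs <- function(fs) {
  if (fs <= 160) dwt_config(n_levels = 4L, rhythm_bands = c(2L, 3L, 4L))
  else dwt_config(n_levels = 5L, rhythm_bands = c(3L, 4L, 5L))
}

# one analysis step with periodization: circular convolution + dyadic
# downsampling; orthogonal, so energy is conserved exactly.
dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }  # edge-pad odd lengths
  h <- DB4_H
  g <- rev(h) * (-1)^(seq_along(h) - 1)                # QMF high-pass
  nk <- length(h)
  idx <- outer(2 * (seq_len(n / 2) - 1), seq_len(nk) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = drop(xm %*% h), detail = drop(xm %*% g))
}

#' Multilevel db4 discrete wavelet decomposition
#'
#' Orthogonal pyramid decomposition with periodic (circular) boundary
#' extension, so the sum of sub-band energies equals the signal energy to
#' machine precision for even dyadic lengths.
#'
#' @param x real numeric vector.
#' @param cfg a \code{dwt_config}.
#' @return named list \code{D1, ..., Dn, An} of coefficient vectors,
#'   finest detail first.
#' @export
dwt_decompose <- function(x, cfg = dwt_config()) {
  stopifnot(inherits(cfg, "dwt_config"))
  min_len <- length(DB4_H) * 2^(cfg$n_levels - 1)
  if (length(x) < min_len)
    stop("signal too short for ", cfg$n_levels,
         "-level decomposition; minimum length is ", min_len)
  out <- vector("list", cfg$n_levels + 1L)
  names(out) <- c(paste0("D", seq_len(cfg$n_levels)),
                  paste0("A", cfg$n_levels))
  cur <- as.numeric(x)
  for (j in seq_len(cfg$n_levels)) {
    st <- dwt_step(cur)
    out[[paste0("D", j)]] <- st$detail
    cur <- st$approx
  }
  out[[paste0("A", cfg$n_levels)]] <- cur
  out
}

#' The eight sub-band statistics of a coefficient array
#'
#' In order: (1) mean absolute value, (2) average power, (3) sample
#' standard deviation (n-1 divisor), (4) ratio of this band's mean
#' absolute value to the adjacent (next-coarser) band's, (5) energy,
#' (6) Shannon entropy in bits of the normalized coefficient energies
#' (0 log 0 := 0), (7) skewness m3 / m2^(3/2), and (8) non-excess
#' kurtosis m4 / m2^2, with m_r the r-th central sample moment.  An
#' all-zero array yields entropy, skewness and kurtosis of 0 and a
#' ratio with a safeguarded (+1e-12) denominator; no error is raised.
#'
#' @param coeffs numeric coefficient vector of one sub-band.
#' @param neighbor_coeffs coefficient vector of the adjacent
#'   (next-coarser) sub-band, used only for the ratio statistic.
#' @return named numeric vector of length 8.
#' @export
subband_stats <- function(coeffs, neighbor_coeffs) {
  if (length(coeffs) == 0L || length(neighbor_coeffs) == 0L)
    stop("coefficient arrays must be non-empty")
  n <- length(coeffs)
  mav <- mean(abs(coeffs))
  pow <- mean(coeffs^2)
  sdv <- if (n > 1) stats::sd(coeffs) else 0
  ratio <- mav / (mean(abs(neighbor_coeffs)) + 1e-12)
  energy <- sum(coeffs^2)
  if (energy > 0) {
    p <- coeffs^2 / energy
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  } else entropy <- 0
  m2 <- mean((coeffs - mean(coeffs))^2)
  if (m2 > 0) {
    m3 <- mean((coeffs - mean(coeffs))^3)
    m4 <- mean((coeffs - mean(coeffs))^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else { skew <- 0; kurt <- 0 }
  c(mav = mav, avg_power = pow, sd = sdv, mav_ratio = ratio,
    energy = energy, entropy = entropy, skewness = skew, kurtosis = kurt)
}

#' db4 sub-band statistic feature matrix
#'
#' Per trial and channel, the eight statistics of
#' \code{\link{subband_stats}} for each of the three rhythm detail bands.
#' Order: channel-major, then band (beta, mu, theta — finest detail
#' first), then statistic.  With 2 channels: 2 x 3 x 8 = 48 features.
#' For each band the ratio statistic uses the next-coarser detail band;
#' for the coarsest rhythm band (theta) the neighbor is the approximation
#' band.
#'
#' @param ts an \code{eeg_trial_set}.
#' @param cfg a \code{dwt_config}; default chosen from \code{ts$fs} via
#'   \code{\link{dwt_config_for_fs}}.
#' @return a \code{feature_matrix}, N x (channels * 24).
#' @export
dwt_features <- function(ts, cfg = NULL) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  if (is.null(cfg)) cfg <- dwt_config_for_fs(ts$fs)
  stopifnot(inherits(cfg, "dwt_config"))
  band_names <- c("beta", "mu", "theta")
  nt <- n_trials(ts); nc <- n_channels(ts)
  stat_names <- names(subband_stats(c(1, 2), c(1)))
  vals <- matrix(NA_real_, nrow = nt, ncol = nc * 24L)
  fn <- character(nc * 24L)
  for (i in seq_len(nt)) {
    k <- 1L
    for (c in seq_len(nc)) {
      dec <- dwt_decompose(ts$data[i, c, ], cfg)
      for (b in seq_len(3L)) {
        lev <- cfg$rhythm_bands[b]
        this <- dec[[paste0("D", lev)]]
        neigh <- if (lev < cfg$n_levels) dec[[paste0("D", lev + 1L)]]
                 else dec[[paste0("A", cfg$n_levels)]]
        vals[i, k:(k + 7L)] <- subband_stats(this, neigh)
        if (i == 1L)
          fn[k:(k + 7L)] <- paste0("dwt_", ts$channel_names[c], "_",
                                   band_names[b], "_", stat_names)
        k <- k + 8L
      }
    }
  }
  feature_matrix(vals, ts$labels, fn)
}
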