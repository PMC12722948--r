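# Classical functional-connectivity baselines: time-domain covariance and
# correlation, Welch spectral estimates, phase locking, and the zero-lag
# robust metrics (imaginary coherency, wPLI).

#' Time-average covariance of two signals
#'
#' `Cov(x, y) = (1/T) sum_t (x(t) - mu_x) conj(y(t) - mu_y)` — divisor `T`,
#' matching the covariance estimator used for QL states.
#'
#' @param x,y numeric or complex vectors of equal length `>= 2`.
#' @return Covariance (complex if the inputs are complex).
#' @export
fc_covariance <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  x <- x - mean(x); y <- y - mean(y)
  out <- mean(x * Conj(y))
  if (is.numeric(x) && is.numeric(y)) Re(out) else out
}

#' Pearson correlation coefficient
#'
#' `r_xy = Cov(x, y) / (sigma_x sigma_y)`, in `[-1, 1]` for real signals.
#'
#' @param x,y real vectors of equal length `>= 2`.
#' @return Correlation coefficient.
#' @export
fc_pearson <- function(x, y) {
  sx <- sqrt(Re(fc_covariance(x, x)))
  sy <- sqrt(Re(fc_covariance(y, y)))
  if (sx == 0 || sy == 0) stop("Pearson correlation undefined for a zero-variance signal")
  Re(fc_covariance(x, y)) / (sx * sy)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Segment a signal into windowed, demeaned, FFT'd pieces (Welch pieces).
welch_segments <- function(x, seg_len, overlap) {
  n <- length(x)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- hann_window(seg_len)
  segs <- lapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1)]
    stats::fft((seg - mean(seg)) * w)
  })
  list(fft = segs, n_segments = length(starts), window = w)
}

#' Welch auto-/cross-spectral densities
#'
#' Hann-windowed, mean-removed, 50%-overlapping segment averages of
#' `X(f) conj(Y(f))`, returned one-sided with density scaling
#' `2 / (fs * sum(w^2))`.  Auto-spectra are real and non-negative and
#' `S_xy = conj(S_yx)` by construction.
#'
#' @param x,y signals of equal length (use `y = x` for an auto-spectrum).
#' @param fs sampling frequency in Hz.
#' @param seg_len segment length in samples (default: `length(x) / 8`
#'   rounded, at least 16).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return A `ql_spectrum`: fields `frequencies` (Hz), `Sxx`, `Syy`, `Sxy`
#'   (complex), `n_segments`, `seg_len`, `per_segment` (matrix of
#'   per-segment cross terms, used by wPLI).
#' @export
welch_csd <- function(x, y, fs, seg_len = NULL, overlap = 0.5) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (is.null(seg_len)) seg_len <- max(16L, floor(length(x) / 8))
  seg_len <- as.integer(seg_len)
  if (seg_len < 4) stop("segment length too short")
  if (length(x) < seg_len) stop("input shorter than one segment")
  sx <- welch_segments(x, seg_len, overlap)
  sy <- welch_segments(y, seg_len, overlap)
  if (sx$n_segments < 2) {
    stop("input too short: fewer than 2 Welch segments (shorten seg_len)")
  }
  nf <- floor(seg_len / 2) + 1
  scale <- 2 / (fs * sum(sx$window^2))
  cross <- t(vapply(seq_len(sx$n_segments), function(k) {
    (sx$fft[[k]] * Conj(sy$fft[[k]]))[seq_len(nf)] * scale
  }, complex(nf)))
  auto_x <- t(vapply(sx$fft, function(f) Mod(f[seq_len(nf)])^2 * scale,
                     numeric(nf)))
  auto_y <- t(vapply(sy$fft, function(f) Mod(f[seq_len(nf)])^2 * scale,
                     numeric(nf)))
  structure(list(
    frequencies = (seq_len(nf) - 1) * fs / seg_len,
    Sxx = colMeans(auto_x), Syy = colMeans(auto_y),
    Sxy = colMeans(cross),
    per_segment = cross,
    n_segments = sx$n_segments, seg_len = seg_len, overlap = overlap, fs = fs
  ), class = "ql_spectrum")
}

#' @export
print.ql_spectrum <- function(x, ...) {
  cat(sprintf("<ql_spectrum> %d frequencies (0..%.4g Hz), %d segments of %d samples\n",
              length(x$frequencies), max(x$frequencies), x$n_segments, x$seg_len))
  invisible(x)
}

#' Magnitude-squared coherence
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, in `[0, 1]` at every
#' frequency (Cauchy-Schwarz over the segment average).  Needs at least two
#' Welch segments; with a single segment the estimate degenerates to 1.
#'
#' @inheritParams welch_csd
#' @return List with `frequencies`, `coherence`, and the underlying
#'   `spectrum`.
#' @export
coherence <- function(x, y, fs, seg_len = NULL, overlap = 0.5) {
  sp <- welch_csd(x, y, fs, seg_len, overlap)
  denom <- sp$Sxx * sp$Syy
  coh <- ifelse(denom > 0, Mod(sp$Sxy)^2 / denom, 0)
  list(frequencies = sp$frequencies, coherence = pmin(pmax(coh, 0), 1),
       spectrum = sp)
}

# Analytic signal via the FFT: zero out negative frequencies, double the
# positive ones.  Real narrowband input assumed for meaningful phases.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value
#'
#' `PLV = |(1/T) sum_t exp(i (phi_x(t) - phi_y(t)))|` with instantaneous
#' phases from the Hilbert analytic signal.  Edge samples (a fraction
#' `trim` on each side) are discarded before averaging to avoid transform
#' edge artifacts.  Real narrowband signals are the intended input.
#'
#' @param x,y real signals of equal length.
#' @param trim fraction trimmed from each end after the analytic-signal
#'   construction (default 0.1).
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(x, y, trim = 0.1) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("instantaneous phase undefined for a constant signal")
  }
  phix <- Arg(analytic_signal(x - mean(x)))
  phiy <- Arg(analytic_signal(y - mean(y)))
  n <- length(x)
  keep <- seq(floor(n * trim) + 1, n - floor(n * trim))
  Mod(mean(exp(1i * (phix[keep] - phiy[keep]))))
}

#' Zero-lag-robust connectivity metrics
#'
#' Imaginary coherency `Im(S_xy) / sqrt(S_xx S_yy)` and the weighted
#' phase-lag index `wPLI = |mean_k Im S_xy^(k)| / mean_k |Im S_xy^(k)|`
#' over Welch segments `k`.  Both vanish for zero-lag-identical signals
#' (volume-conduction surrogates) and are large only for consistently
#' lagged coupling.
#'
#' @inheritParams welch_csd
#' @return List with `frequencies`, `imaginary_coherency`, `wpli`, and the
#'   underlying `spectrum`.
#' @export
robust_metrics <- function(x, y, fs, seg_len = NULL, overlap = 0.5) {
  sp <- welch_csd(x, y, fs, seg_len, overlap)
  denom <- sqrt(sp$Sxx * sp$Syy)
  icoh <- ifelse(denom > 0, Im(sp$Sxy) / denom, 0)
  imcross <- Im(sp$per_segment)
  num <- abs(colMeans(imcross))
  den <- colMeans(abs(imcross))
  wpli <- ifelse(den > 0, num / den, 0)
  list(frequencies = sp$frequencies,
       imaginary_coherency = pmin(pmax(icoh, -1), 1),
       wpli = pmin(pmax(wpli, 0), 1),
       spectrum = sp)
}

#' Pairwise functional-connectivity matrix
#'
#' Applies one metric to every channel pair of a multichannel recording.
#' Spectral metrics (coherence, imaginary coherency, wPLI) are averaged
#' over `band` (a frequency interval in Hz; the full axis by default).
#' The diagonal is fixed at the metric's self-value and the matrix is
#' symmetric (absolute values are used for signed spectral metrics).
#'
#' @param signals real matrix with channels in rows and samples in columns
#'   (the CSV layout), or a [signal_ensemble()] in time-series mode.
#' @param metric one of `"covariance"`, `"pearson"`, `"plv"`,
#'   `"coherence"`, `"imaginary_coherency"`, `"wpli"`.
#' @param fs sampling frequency (spectral metrics only).
#' @param band optional `c(flo, fhi)` averaging band in Hz.
#' @param ... passed to the metric (e.g. `seg_len`, `trim`).
#' @return Symmetric `N x N` numeric matrix.
#' @export
fc_matrix <- function(signals, metric = c("covariance", "pearson", "plv",
                                          "coherence", "imaginary_coherency",
                                          "wpli"),
                      fs = NULL, band = NULL, ...) {
  metric <- match.arg(metric)
  if (inherits(signals, "ql_ensemble")) signals <- t(Re(signals$data))
  signals <- as.matrix(signals)
  N <- nrow(signals)
  band_mean <- function(f, v) {
    if (!is.null(band)) v <- v[f >= band[1] & f <= band[2]]
    mean(v)
  }
  pairval <- function(x, y) {
    switch(metric,
      covariance = Re(fc_covariance(x, y)),
      pearson = fc_pearson(x, y),
      plv = plv(x, y, ...),
      coherence = {
        co <- coherence(x, y, fs = fs, ...)
        band_mean(co$frequencies, co$coherence)
      },
      imaginary_coherency = {
        rm <- robust_metrics(x, y, fs = fs, ...)
        band_mean(rm$frequencies, abs(rm$imaginary_coherency))
      },
      wpli = {
        rm <- robust_metrics(x, y, fs = fs, ...)
        band_mean(rm$frequencies, rm$wpli)
      })
  }
  if (metric %in% c("coherence", "imaginary_coherency", "wpli") &&
      is.null(fs)) {
    stop("spectral metrics need the sampling frequency fs")
  }
  out <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j < i) { out[i, j] <- out[j, i]; next }
      if (i == j) {
        out[i, i] <- switch(metric,
          covariance = Re(fc_covariance(signals[i, ], signals[i, ])),
          pearson = 1, plv = 1, coherence = 1,
          imaginary_coherency = 0, wpli = 0)
      } else {
        out[i, j] <- pairval(signals[i, ], signals[j, ])
      }
    }
  }
  out
}

#' Trial-shuffled surrogate of an ensemble or signal pair
#'
#' Breaks the pairing between two signals (or between the channels of an
#' ensemble) by circularly shifting / permuting one of them, preserving
#' marginal statistics while destroying cross dependence — the matched
#' surrogate control for PLV/coherence null levels.
#'
#' @param y vector to decouple.
#' @param seed RNG seed.
#' @return Permuted copy of `y`.
#' @export
shuffle_surrogate <- function(y, seed) {
  set.seed(seed)
  y[sample.int(length(y))]
}
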