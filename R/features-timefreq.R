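#' Time-frequency analysis specification
#'
#' Parameters of the Smoothed Pseudo Wigner-Ville Distribution (SPWVD) and
#' the spectral band layout. The SPWVD is a Cohen's-class distribution with
#' separable smoothing: a Gaussian-tapered time-smoothing window of length
#' `round(time_param * N)` samples and a Gaussian lag (frequency-smoothing)
#' window of length `round(freq_param * N)`, where `N` is the analysed signal
#' length and `kernel_shape` is the attenuation of the Gaussian taper at the
#' window ends. Bands are contiguous 40 Hz bands over 0-160 Hz for
#' bipolar EGMs and 20 Hz bands over 0-80 Hz for unipolar EGMs.
#'
#' @param time_param,freq_param,kernel_shape smoothing parameters (defaults
#'   0.03, 0.15, 0.25).
#' @param bands 4 x 2 matrix of band edges in Hz (columns `lo`, `hi`);
#'   defaults to the channel layout via [channel_bands()].
#' @return A `tf_spec` object.
#' @export
tf_spec <- function(time_param = 0.03, freq_param = 0.15, kernel_shape = 0.25,
                    bands = NULL) {
  structure(list(time_param = time_param, freq_param = freq_param,
                 kernel_shape = kernel_shape, bands = bands),
            class = "tf_spec")
}

# Ideal (FFT) band-limited resampling to n_new samples.
resample_fft <- function(x, n_new) {
  n <- length(x)
  if (n_new >= n) return(x)
  X <- fft(x)
  k <- (n_new - 1L) %/% 2L
  Y <- complex(n_new)
  Y[1:(k + 1L)] <- X[1:(k + 1L)]
  if (k > 0L) Y[(n_new - k + 1L):n_new] <- X[(n - k + 1L):n]
  Re(fft(Y, inverse = TRUE)) / n
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Gaussian taper whose value at the window ends equals `shape` (so the
# nominal window length is the effective support, not a hard truncation of a
# much narrower bell).
gauss_win <- function(n, shape) {
  if (n <= 1L) return(rep(1, n))
  m <- (n - 1) / 2
  t <- seq(-m, m)
  sigma <- m / sqrt(-2 * log(shape))
  exp(-0.5 * (t / sigma)^2)
}

#' Smoothed Pseudo Wigner-Ville Distribution of a trace
#'
#' Computes the SPWVD of the analytic signal (one-sided, suppressing
#' cross-terms between positive and negative frequencies). The signal is
#' first band-limited and resampled so the frequency axis comfortably covers
#' the channel's band maximum (160 Hz bipolar, 80 Hz unipolar). Small
#' negative values of the distribution are clipped and the matrix is
#' renormalized so its integral equals the signal energy.
#'
#' @param trace an [egm_trace()] with at least 64 samples.
#' @param spec a [tf_spec()].
#' @param band_max_hz top of the frequency range of interest; defaults by
#'   channel (160 bipolar / 80 unipolar).
#' @return A frequency x time matrix (class `vts_tfr`) with attributes
#'   `freqs_hz`, `times_ms`, `df_hz`, `dt_s` and `energy_ratio` (the raw
#'   integral over the signal energy before renormalization).
#' @export
spwvd <- function(trace, spec = tf_spec(),
                  band_max_hz = if (trace$kind == "bipolar") 160 else 80) {
  x <- trace$samples
  if (length(x) < 64L) abort("spwvd needs at least 64 samples")
  fs <- trace$fs
  fs_target <- max(5 * band_max_hz, 400)
  n_new <- if (fs > fs_target) {
    max(64L, as.integer(floor(length(x) * fs_target / fs)))
  } else length(x)
  xr <- resample_fft(x, n_new)
  fs_d <- fs * n_new / length(x)
  N <- length(xr)
  z <- analytic_signal(xr)

  Lg <- max(1L, round(spec$time_param * N)); if (Lg %% 2L == 0L) Lg <- Lg + 1L
  Lh <- max(3L, round(spec$freq_param * N)); if (Lh %% 2L == 0L) Lh <- Lh + 1L
  g <- gauss_win(Lg, spec$kernel_shape); g <- g / sum(g)
  h <- gauss_win(Lh, spec$kernel_shape)
  Mg <- (Lg - 1L) %/% 2L; Mh <- (Lh - 1L) %/% 2L

  pad <- Mg + Mh + 1L
  zp <- c(complex(pad), z, complex(pad))
  idx <- pad + seq_len(N)
  Nf <- max(128L, 2^ceiling(log2(N)))
  ker <- matrix(0 + 0i, Nf, N)
  ls <- seq.int(-Mg, Mg)
  for (m in 0:Mh) {
    acc <- complex(N)
    for (j in seq_along(ls)) {
      l <- ls[j]
      acc <- acc + g[j] * zp[idx + l + m] * Conj(zp[idx + l - m])
    }
    ker[m + 1L, ] <- h[m + Mh + 1L] * acc
    if (m > 0L) ker[Nf - m + 1L, ] <- h[Mh + 1L - m] * Conj(acc)
  }
  tfr <- Re(stats::mvfft(ker))

  df <- fs_d / 2 / Nf
  dt <- 1 / fs_d
  energy <- sum(xr^2) / fs_d
  raw <- sum(tfr) * dt * df / fs_d   # canonical scaling of the discrete SPWVD
  tfr[tfr < 0] <- 0
  total <- sum(tfr) * dt * df
  if (total > 0) tfr <- tfr * energy / total
  structure(tfr,
            freqs_hz = (seq_len(Nf) - 1) * df,
            times_ms = (seq_len(N) - 1) / fs_d * 1000,
            df_hz = df, dt_s = dt,
            energy_ratio = if (energy > 0) raw / energy else NA_real_,
            class = c("vts_tfr", "matrix", "array"))
}

#' Windowed total and fractional band energies of an SPWVD
#'
#' @param tf a matrix from [spwvd()].
#' @param window_ms numeric length-2: window start and end (ms, end
#'   exclusive) on the trace's time axis.
#' @param bands 4 x 2 band-edge matrix (Hz), e.g. [channel_bands()].
#' @return A list with `total` (energy within the window over the full band
#'   range, mV^2 s) and `fractions` (length-4, summing to 1; all `NA` when
#'   the window energy is zero).
#' @export
band_energies <- function(tf, window_ms, bands) {
  tms <- attr(tf, "times_ms"); fz <- attr(tf, "freqs_hz")
  df <- attr(tf, "df_hz"); dt <- attr(tf, "dt_s")
  cols <- which(tms >= window_ms[1] & tms < window_ms[2])
  if (!length(cols)) abort("window outside the time span of the matrix")
  fmax <- max(bands)
  rows_all <- which(fz < fmax)
  sub <- tf[rows_all, cols, drop = FALSE]
  total <- sum(sub) * dt * df
  if (total <= 0) {
    return(list(total = 0, fractions = rep(NA_real_, nrow(bands))))
  }
  fr <- vapply(seq_len(nrow(bands)), function(i) {
    hi_closed <- i == nrow(bands)
    rows <- which(fz >= bands[i, 1] & (fz < bands[i, 2] | (hi_closed & fz == bands[i, 2])))
    sum(tf[rows, cols]) * dt * df / total
  }, numeric(1))
  list(total = total, fractions = fr / sum(fr))
}

# Hann-tapered periodogram of a window, clipped to band_max_hz.
window_psd <- function(trace, window, band_max_hz) {
  x <- trace$samples[window]
  n <- length(x)
  if (n < 32L) abort("spectral features need a window of >= 32 samples")
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- fft(x * w)
  nf <- n %/% 2L + 1L
  psd <- (Mod(X[1:nf])^2) / (trace$fs * sum(w^2))
  f <- (seq_len(nf) - 1) * trace$fs / n
  keep <- f <= band_max_hz
  list(f = f[keep], psd = psd[keep])
}

#' Central (centre-of-mass) frequency of a window
#'
#' The PSD-amplitude-weighted mean frequency over `[0, band_max_hz]`.
#'
#' @param trace an [egm_trace()].
#' @param window integer sample indices (>= 32 samples).
#' @param band_max_hz upper frequency limit; defaults by channel.
#' @return Frequency in Hz, `NA_real_` for a zero-power window.
#' @export
central_frequency <- function(trace, window,
                              band_max_hz = if (trace$kind == "bipolar") 160 else 80) {
  p <- window_psd(trace, window, band_max_hz)
  tot <- sum(p$psd)
  if (tot <= 0) return(NA_real_)
  sum(p$f * p$psd) / tot
}

#' Number of spectral peaks in a window
#'
#' Local maxima of the Hann-tapered periodogram with prominence at least
#' `prominence_frac` of the maximum PSD value, separated by at least
#' `min_sep_hz` (peaks are accepted greedily in descending height).
#'
#' @inheritParams central_frequency
#' @param prominence_frac prominence threshold (default 0.05 of max PSD).
#' @param min_sep_hz minimum peak separation (default 5 Hz).
#' @return Integer count (0 for a zero-power window).
#' @export
spectral_peaks <- function(trace, window,
                           band_max_hz = if (trace$kind == "bipolar") 160 else 80,
                           prominence_frac = 0.05, min_sep_hz = 5) {
  p <- window_psd(trace, window, band_max_hz)
  y <- p$psd
  if (max(y) <= 0) return(0L)
  n <- length(y)
  ex <- extrema_idx(y)
  cand <- ex$max
  if (!length(cand)) return(0L)
  prom <- vapply(cand, function(i) {
    vl <- y[i]; j <- i
    while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; vl <- min(vl, y[j]) }
    vr <- y[i]; j <- i
    while (j < n && y[j + 1L] <= y[i]) { j <- j + 1L; vr <- min(vr, y[j]) }
    y[i] - max(vl, vr)
  }, numeric(1))
  keep <- cand[prom >= prominence_frac * max(y)]
  if (!length(keep)) return(0L)
  keep <- keep[order(y[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel) || all(abs(p$f[sel] - p$f[i]) >= min_sep_hz)) sel <- c(sel, i)
  }
  length(sel)
}
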