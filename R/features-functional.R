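# Functional-domain features: timings (LAT, RT, ARI), durations, amplitudes,
# deflection counts and change rates, computed per point on filtered traces.

# Central-difference derivative, one-sided at the ends, in signal units per
# millisecond.
deriv_mv_ms <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d * fs / 1000
}

# Indices of local extrema (plateaus take their first sample).
extrema_idx <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  s <- sign(diff(x))
  # carry last non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  turn <- which(diff(s) != 0) + 1L
  list(max = turn[s[turn - 1L] > 0], min = turn[s[turn - 1L] < 0])
}

#' Local activation time from a bipolar trace
#'
#' The activation time is annotated at the latest deflection inside the QRS
#' window whose excursion exceeds 20% of the window's peak-to-peak amplitude.
#' A deflection is a negative-going swing (downstroke) from a local maximum —
#' or the window start for a QS-type onset — to the following local minimum;
#' its time is the midpoint of the swing, the steepest part of a biphasic
#' wave, where the clinical annotation sits.
#'
#' @param trace a bipolar [egm_trace()] (filtered).
#' @param min_frac deflection magnitude threshold as a fraction of the QRS
#'   window peak-to-peak amplitude.
#' @return Activation time in ms from trace start, or `NA_real_` when no
#'   qualifying deflection exists (annotation missing, not an error).
#' @export
detect_lat <- function(trace, min_frac = 0.2) {
  w <- segment(trace)$qrs
  x <- trace$samples[w]
  ptp <- diff(range(x))
  if (!is.finite(ptp) || ptp <= 0) return(NA_real_)
  ex <- extrema_idx(x)
  if (!length(ex$min)) return(NA_real_)
  lat <- NA_real_
  for (m in ex$min) {
    start <- if (any(ex$max < m)) max(ex$max[ex$max < m]) else 1L
    if (x[start] - x[m] > min_frac * ptp) lat <- (start + m) / 2
  }
  if (is.na(lat)) return(NA_real_)
  sample_to_ms(w[1] - 1L + lat, trace$fs)
}

#' Repolarization time from a unipolar trace
#'
#' Annotated at the maximum of the first derivative of the T-wave (the
#' post-QRS window of the unipolar EGM).
#'
#' @param trace a unipolar [egm_trace()] (filtered).
#' @return Repolarization time in ms from trace start, or `NA_real_` if the
#'   window is degenerate.
#' @export
detect_rt <- function(trace) {
  w <- tryCatch(segment(trace)$post, error = function(e) integer(0))
  if (length(w) < 2L) return(NA_real_)
  d <- deriv_mv_ms(trace$samples[w], trace$fs)
  sample_to_ms(w[which.max(d)], trace$fs)
}

#' Activation-recovery interval
#'
#' `ARI = RT - LAT`, a surrogate of local action-potential duration. A
#' negative value is retained but flagged with a warning.
#'
#' @param rt_ms,lat_ms repolarization and activation times (ms).
#' @return ARI in ms (`NA` if either input is missing).
#' @export
compute_ari <- function(rt_ms, lat_ms) {
  out <- rt_ms - lat_ms
  neg <- which(is.finite(out) & out < 0)
  if (length(neg)) warn(sprintf("%d negative ARI value(s) retained", length(neg)))
  out
}

#' Electrogram duration in a window
#'
#' The rectified signal is smoothed with a running median (noise-robust and
#' edge-preserving) and thresholded at a fraction of its window maximum; the
#' duration is the span between the first and last threshold crossing.
#'
#' @param trace an [egm_trace()].
#' @param window integer sample indices (e.g. from [segment()]).
#' @param threshold_frac threshold as a fraction of the smoothed rectified
#'   maximum (default 0.2).
#' @param smooth_ms running-median width in ms (default 10).
#' @return Duration in ms (0 for an all-zero window).
#' @export
egm_duration <- function(trace, window, threshold_frac = 0.2, smooth_ms = 10) {
  x <- abs(trace$samples[window])
  if (!length(x) || max(x) == 0) return(0)
  k <- max(1L, as.integer(round(smooth_ms / 1000 * trace$fs)))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- if (length(x) > k) {
    as.numeric(stats::runmed(x, k, endrule = "median"))
  } else x
  above <- which(sm >= threshold_frac * max(sm))
  if (!length(above)) return(0)
  (max(above) - min(above)) / trace$fs * 1000
}

#' Peak-to-peak amplitude in a window
#'
#' @inheritParams egm_duration
#' @return Amplitude in mV.
#' @export
amplitude <- function(trace, window) {
  x <- trace$samples[window]
  diff(range(x))
}

#' Count negative deflections in a window
#'
#' Counts local minima whose depth relative to the flanking maxima exceeds a
#' fraction of the window's peak-to-peak amplitude. Scale-invariant.
#'
#' @inheritParams egm_duration
#' @param min_frac depth threshold as a fraction of peak-to-peak amplitude.
#' @return Integer count.
#' @export
count_deflections <- function(trace, window, min_frac = 0.2) {
  x <- trace$samples[window]
  ptp <- diff(range(x))
  if (!is.finite(ptp) || ptp <= 0) return(0L)
  ex <- extrema_idx(x)
  if (!length(ex$min)) return(0L)
  n <- length(x)
  count <- 0L
  for (i in ex$min) {
    left_ref <- if (any(ex$max < i)) x[max(ex$max[ex$max < i])] else max(x[1:i])
    right_ref <- if (any(ex$max > i)) x[min(ex$max[ex$max > i])] else max(x[i:n])
    depth <- min(left_ref, right_ref) - x[i]
    if (depth > min_frac * ptp) count <- count + 1L
  }
  count
}

#' Maximum and mean absolute slope in a window
#'
#' First derivative by central differences (one-sided at the ends), scaled to
#' mV/ms.
#'
#' @inheritParams egm_duration
#' @return Named numeric vector `c(max = , mean = )`.
#' @export
slope_stats <- function(trace, window) {
  if (length(window) < 2L) abort("slope_stats needs a window of length >= 2")
  d <- abs(deriv_mv_ms(trace$samples[window], trace$fs))
  c(max = max(d), mean = mean(d))
}
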