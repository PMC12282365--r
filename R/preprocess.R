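#' Band-pass filter specification
#'
#' Defaults follow standard electrogram preprocessing: unipolar EGMs are
#' band-passed 0.5-20 Hz, bipolar EGMs 0.5-40 Hz, with a 4th-order Butterworth
#' applied forward-backward (zero phase) so activation/repolarization timings
#' are not shifted by group delay.
#'
#' @param low_hz,high_hz passband edges (Hz), `0 < low_hz < high_hz`.
#' @param order overall filter order (even; the design uses `order/2` poles
#'   per edge and the magnitude response is squared by the zero-phase pass).
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4L, zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz)) abort("need 0 < low_hz < high_hz")
  if (order < 2L || order %% 2L != 0L) abort("order must be an even integer >= 2")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Default filter specs per channel
#' @param kind `"unipolar"` or `"bipolar"`.
#' @return A [filter_spec()].
#' @export
default_filter_spec <- function(kind = c("unipolar", "bipolar")) {
  kind <- match.arg(kind)
  if (kind == "unipolar") filter_spec(0.5, 20) else filter_spec(0.5, 40)
}

#' Zero-phase band-pass filter a trace
#'
#' Demeans the signal, reflect-pads both ends by one filter length to avoid
#' end transients, runs the Butterworth design forward and backward, and
#' returns a trace of identical length with windows preserved.
#'
#' @param trace an [egm_trace()].
#' @param spec a [filter_spec()]; defaults to the channel's standard band.
#' @return The filtered `egm_trace`.
#' @export
bandpass <- function(trace, spec = default_filter_spec(trace$kind)) {
  fs <- trace$fs
  if (spec$high_hz >= fs / 2) {
    abort(sprintf("filter high edge %.1f Hz not below Nyquist (fs = %.1f Hz)",
                  spec$high_hz, fs))
  }
  x <- trace$samples
  n <- length(x)
  if (n <= 3L * spec$order) abort("trace too short for the requested filter order")
  bf <- signal::butter(spec$order %/% 2L,
                       c(spec$low_hz, spec$high_hz) / (fs / 2), type = "pass")
  x <- x - mean(x)
  pad <- min(n - 1L, max(64L, 10L * spec$order))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filter(bf, xp)
  if (spec$zero_phase) y <- rev(signal::filter(bf, rev(y)))
  trace$samples <- as.numeric(y[(pad + 1L):(pad + n)])
  trace
}

#' Segment a trace into QRS and post-QRS windows
#'
#' The QRS window is `[qrs_on, qrs_end)`; the post window is
#' `[qrs_end, t_end)` for unipolar traces (the T-wave window) and
#' `[qrs_end, length]` for bipolar traces. The two windows are disjoint and
#' contiguous.
#'
#' @param trace an [egm_trace()].
#' @return A list with integer index vectors `qrs` and `post`.
#' @export
segment <- function(trace) {
  n <- length(trace$samples)
  post_end <- if (trace$kind == "unipolar") trace$t_end else n + 1L
  qrs <- seq.int(trace$qrs_on, trace$qrs_end - 1L)
  post <- if (trace$qrs_end <= post_end - 1L) {
    seq.int(trace$qrs_end, post_end - 1L)
  } else integer(0)
  if (!length(qrs) || !length(post)) abort("degenerate (empty) analysis window")
  list(qrs = qrs, post = post)
}
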