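#' Construct an electrogram trace
#'
#' A single channel's sampled signal together with its analysis windows. The
#' QRS window (ventricular activation period, taken from the surface ECG) and
#' the post-QRS window are stored as sample indices; all user-facing timings
#' are in milliseconds and converted with the trace's sampling rate.
#'
#' @param samples numeric vector of amplitudes (mV), length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param kind `"unipolar"` or `"bipolar"`.
#' @param qrs_on,qrs_end QRS window bounds (1-based sample indices,
#'   `qrs_on < qrs_end`).
#' @param t_end end of the T-wave window (unipolar); for bipolar traces it
#'   defaults to the trace length (the post-QRS window runs to the end).
#' @return An object of class `egm_trace`.
#' @export
egm_trace <- function(samples, fs, kind = c("unipolar", "bipolar"),
                      qrs_on, qrs_end, t_end = length(samples)) {
  kind <- match.arg(kind)
  x <- structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs), kind = kind,
         qrs_on = as.integer(qrs_on), qrs_end = as.integer(qrs_end),
         t_end = as.integer(t_end)),
    class = "egm_trace"
  )
  validate_trace(x)
  x
}

validate_trace <- function(x) {
  n <- length(x$samples)
  if (n < 2L) abort("egm_trace needs at least 2 samples")
  if (!is.finite(x$fs) || x$fs <= 0) abort("egm_trace fs must be > 0")
  if (!all(is.finite(x$samples))) abort("egm_trace samples must be finite")
  ok <- 1L <= x$qrs_on && x$qrs_on < x$qrs_end &&
    x$qrs_end <= x$t_end && x$t_end <= n
  if (!ok) {
    abort(sprintf(
      "egm_trace windows violate 1 <= qrs_on < qrs_end <= t_end <= length (%d, %d, %d, %d)",
      x$qrs_on, x$qrs_end, x$t_end, n))
  }
  invisible(x)
}

#' @export
print.egm_trace <- function(x, ...) {
  cat(sprintf("<egm_trace %s: %d samples @ %.1f Hz, QRS [%d,%d), post ends %d>\n",
              x$kind, length(x$samples), x$fs, x$qrs_on, x$qrs_end, x$t_end))
  invisible(x)
}

#' Assemble a study of substrate maps and VT critical sites
#'
#' A study holds every substrate map acquired for a set of subjects plus the
#' ventricular-tachycardia critical sites (entry / isthmus / exit of the
#' diastolic pathway) localized from VT activation maps, in a shared
#' millimetre coordinate frame.
#'
#' @param subjects character vector of subject ids.
#' @param maps tibble with columns `map_id`, `subject_id`, `rhythm`
#'   (`SR|LV|RV|BIV`), `protocol` (`none|SE|S1S2`; `none` for SR maps).
#' @param points tibble with columns `map_id`, `point_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `lat_ms`, `rt_ms`, `ari_ms` and list-columns `uni`, `bip` of
#'   [egm_trace()] objects.
#' @param sites tibble with columns `site_id`, `vt_id`, `phase`
#'   (`early|mid|late`), `x_mm`, `y_mm`, `z_mm`.
#' @return An object of class `vts_study`.
#' @export
new_study <- function(subjects, maps, points, sites) {
  x <- structure(
    list(subjects = as.character(subjects),
         maps = as_tibble(maps), points = as_tibble(points),
         sites = as_tibble(sites)),
    class = "vts_study"
  )
  validate_study(x)
  x
}

rhythm_levels <- c("SR", "LV", "RV", "BIV")
protocol_levels <- c("none", "SE", "S1S2")
phase_levels <- c("early", "mid", "late")

#' Validate a study against its invariants
#'
#' Checks id uniqueness and referential integrity, enum values, the SR/no
#' protocol rule, window invariants of every trace, coordinate finiteness and
#' the ARI identity `ari_ms = rt_ms - lat_ms` where both annotations exist.
#'
#' @param x a `vts_study`.
#' @return `x` invisibly; aborts with the offending map/point id otherwise.
#' @export
validate_study <- function(x) {
  m <- x$maps
  if (anyDuplicated(m$map_id)) abort("duplicate map_id in maps")
  if (!all(m$rhythm %in% rhythm_levels)) abort("invalid rhythm value in maps")
  if (!all(m$protocol %in% protocol_levels)) abort("invalid protocol value in maps")
  bad <- m$map_id[m$rhythm == "SR" & m$protocol != "none"]
  if (length(bad)) abort(paste0("SR map must have protocol 'none': ", bad[1]))
  if (!all(m$subject_id %in% x$subjects)) abort("map subject_id not in subjects")

  p <- x$points
  if (!all(p$map_id %in% m$map_id)) abort("point references unknown map_id")
  key <- paste(p$map_id, p$point_id)
  if (anyDuplicated(key)) abort("duplicate (map_id, point_id)")
  xyz <- as.matrix(p[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(xyz))) abort("non-finite point coordinates")
  for (i in seq_len(nrow(p))) {
    tr_u <- p$uni[[i]]; tr_b <- p$bip[[i]]
    if (!inherits(tr_u, "egm_trace") || !inherits(tr_b, "egm_trace")) {
      abort(sprintf("point %s/%s is missing a signal trace", p$map_id[i], p$point_id[i]))
    }
    validate_trace(tr_u); validate_trace(tr_b)
    if (is.finite(p$lat_ms[i]) && is.finite(p$rt_ms[i]) && is.finite(p$ari_ms[i])) {
      if (abs(p$ari_ms[i] - (p$rt_ms[i] - p$lat_ms[i])) > 1e-6) {
        abort(sprintf("ARI identity violated at point %s/%s", p$map_id[i], p$point_id[i]))
      }
    }
  }

  s <- x$sites
  if (nrow(s)) {
    if (anyDuplicated(s$site_id)) abort("duplicate site_id")
    if (!all(s$phase %in% phase_levels)) abort("invalid site phase")
    if (!all(is.finite(as.matrix(s[, c("x_mm", "y_mm", "z_mm")])))) {
      abort("non-finite site coordinates")
    }
  }
  invisible(x)
}

#' @export
print.vts_study <- function(x, ...) {
  cat(sprintf("<vts_study: %d subjects, %d maps, %d points, %d VT critical sites>\n",
              length(x$subjects), nrow(x$maps), nrow(x$points), nrow(x$sites)))
  invisible(x)
}

#' @method as_tibble vts_study
#' @export
as_tibble.vts_study <- function(x, ...) {
  dplyr::left_join(x$points, x$maps, by = "map_id")
}
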