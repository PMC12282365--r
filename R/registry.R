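#' The 46-feature registry
#'
#' Enumerates every signal feature the extraction pipeline produces, one row
#' per feature, with its channel attribution, analysis window and domain.
#' The inventory spans four domains: functional (timings, durations,
#' amplitudes, deflection counts, change rates), spatial (gradients of
#' activation time, repolarization time and activation-recovery interval over
#' the 3D point cloud), spectral (central frequency and spectral peak count)
#' and time-frequency (windowed total and fractional band energies from a
#' Smoothed Pseudo Wigner-Ville Distribution).
#'
#' Channel accounting: 46 distinct features of which 2 are "general"
#' parameters shared by both channel models — the bipolar activation time
#' `LATB` (the activation map every other timing is referenced to) and its
#' spatial gradient `GradAT`. The bipolar model uses the 20 bipolar features
#' plus the 2 general ones (22 inputs); the unipolar model uses the 24
#' unipolar features plus the same 2 (26 inputs). All repolarization
#' information (`RT`, `ARIB`, `GradRT`, `GradARI`) is carried by the unipolar
#' model only, since repolarization is annotated on the unipolar T-wave.
#'
#' @return A tibble with columns `name`, `channel`
#'   (`"bipolar"|"unipolar"|"general"`), `window` (`"QRS"|"post"|"whole"|"na"`)
#'   and `domain` (`"functional"|"spatial"|"spectral"|"timefreq"`).
#' @examples
#' reg <- build_registry()
#' nrow(reg)                                   # 46
#' sum(reg$channel %in% c("bipolar", "general"))  # 22
#' sum(reg$channel %in% c("unipolar", "general")) # 26
#' @export
build_registry <- function() {
  f <- function(name, channel, window, domain) {
    tibble(name = name, channel = channel, window = window, domain = domain)
  }
  reg <- dplyr::bind_rows(
    # functional domain ------------------------------------------------
    f("LATB",          "general",  "QRS",  "functional"),
    f("RT",            "unipolar", "post", "functional"),
    f("ARIB",          "unipolar", "na",   "functional"),
    f("DB",            "bipolar",  "whole","functional"),
    f("DU",            "unipolar", "QRS",  "functional"),
    f("AB",            "bipolar",  "QRS",  "functional"),
    f("AU",            "unipolar", "QRS",  "functional"),
    f("ABp",           "bipolar",  "post", "functional"),
    f("AUT",           "unipolar", "post", "functional"),
    f("DefB",          "bipolar",  "QRS",  "functional"),
    f("DefU",          "unipolar", "QRS",  "functional"),
    f("max_dBQRS_dt",  "bipolar",  "QRS",  "functional"),
    f("mean_dBQRS_dt", "bipolar",  "QRS",  "functional"),
    f("max_dBp_dt",    "bipolar",  "post", "functional"),
    f("mean_dBp_dt",   "bipolar",  "post", "functional"),
    f("max_dUQRS_dt",  "unipolar", "QRS",  "functional"),
    f("mean_dUQRS_dt", "unipolar", "QRS",  "functional"),
    f("max_dUT_dt",    "unipolar", "post", "functional"),
    f("mean_dUT_dt",   "unipolar", "post", "functional"),
    # spatial domain ----------------------------------------------------
    f("GradAT",        "general",  "na",   "spatial"),
    f("GradRT",        "unipolar", "na",   "spatial"),
    f("GradARI",       "unipolar", "na",   "spatial"),
    # spectral domain ---------------------------------------------------
    f("fB",            "bipolar",  "whole","spectral"),
    f("fU",            "unipolar", "whole","spectral"),
    f("PB",            "bipolar",  "whole","spectral"),
    f("PU",            "unipolar", "whole","spectral"),
    # time-frequency domain: totals then fractional band energies -------
    f("EB_QRS_0_160",  "bipolar",  "QRS",  "timefreq"),
    f("EB_P_0_160",    "bipolar",  "post", "timefreq"),
    f("RU_QRS_0_80",   "unipolar", "QRS",  "timefreq"),
    f("RU_T_0_80",     "unipolar", "post", "timefreq"),
    f("RB_QRS_0_40",   "bipolar",  "QRS",  "timefreq"),
    f("RB_QRS_40_80",  "bipolar",  "QRS",  "timefreq"),
    f("RB_QRS_80_120", "bipolar",  "QRS",  "timefreq"),
    f("RB_QRS_120_160","bipolar",  "QRS",  "timefreq"),
    f("RB_P_0_40",     "bipolar",  "post", "timefreq"),
    f("RB_P_40_80",    "bipolar",  "post", "timefreq"),
    f("RB_P_80_120",   "bipolar",  "post", "timefreq"),
    f("RB_P_120_160",  "bipolar",  "post", "timefreq"),
    f("RU_QRS_0_20",   "unipolar", "QRS",  "timefreq"),
    f("RU_QRS_20_40",  "unipolar", "QRS",  "timefreq"),
    f("RU_QRS_40_60",  "unipolar", "QRS",  "timefreq"),
    f("RU_QRS_60_80",  "unipolar", "QRS",  "timefreq"),
    f("RU_T_0_20",     "unipolar", "post", "timefreq"),
    f("RU_T_20_40",    "unipolar", "post", "timefreq"),
    f("RU_T_40_60",    "unipolar", "post", "timefreq"),
    f("RU_T_60_80",    "unipolar", "post", "timefreq")
  )
  stopifnot(!anyDuplicated(reg$name), nrow(reg) == 46L)
  class(reg) <- c("vts_registry", class(reg))
  reg
}

#' Feature names used by a channel model
#'
#' @param registry a registry from [build_registry()].
#' @param model `"bipolar"`, `"unipolar"` or `"both"`; general parameters are
#'   included in every model.
#' @return Character vector of feature names.
#' @export
registry_features <- function(registry = build_registry(),
                              model = c("both", "bipolar", "unipolar")) {
  model <- match.arg(model)
  keep <- switch(model,
    both     = c("bipolar", "unipolar", "general"),
    bipolar  = c("bipolar", "general"),
    unipolar = c("unipolar", "general")
  )
  registry$name[registry$channel %in% keep]
}

#' Spectral band edges per channel
#'
#' Four contiguous bands: 40-Hz bands over 0-160 Hz for bipolar EGMs, 20-Hz
#' bands over 0-80 Hz for unipolar EGMs.
#'
#' @param kind `"bipolar"` or `"unipolar"`.
#' @return A 4 x 2 matrix with columns `lo` and `hi` (Hz).
#' @export
channel_bands <- function(kind) {
  if (kind == "bipolar") {
    cbind(lo = c(0, 40, 80, 120), hi = c(40, 80, 120, 160))
  } else {
    cbind(lo = c(0, 20, 40, 60), hi = c(20, 40, 60, 80))
  }
}
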