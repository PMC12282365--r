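#' Extract the full 46-feature table from a study
#'
#' For every mapping point: band-pass filters both channels (0.5-20 Hz
#' unipolar, 0.5-40 Hz bipolar), annotates LAT on the filtered bipolar EGM
#' and RT on the filtered unipolar T-wave, computes the functional-domain
#' features on the filtered traces, computes spectral and time-frequency
#' (SPWVD) features on the unfiltered acquisition-band traces (the spectral
#' bands extend well above the morphology filter's passband), and finally the
#' per-map spatial gradients of the annotated AT/RT/ARI fields. Map-type
#' one-hot indicator columns (`is_SR`, `is_LV`, `is_RV`, `is_BIV`) are
#' appended.
#'
#' @param study a `vts_study`.
#' @param registry feature registry (defaults to [build_registry()]).
#' @param tf a [tf_spec()].
#' @param gradient_radius_mm neighbourhood radius for spatial gradients.
#' @return A tibble keyed by (`map_id`, `point_id`) with point coordinates,
#'   the 46 registry features (in registry order) and the 4 indicators.
#' @export
extract_features <- function(study, registry = build_registry(),
                             tf = tf_spec(), gradient_radius_mm = 10) {
  p <- study$points
  rows <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    point_features(p$uni[[i]], p$bip[[i]], tf)
  })
  out <- dplyr::bind_cols(
    p[, c("map_id", "point_id", "x_mm", "y_mm", "z_mm")], rows)

  # spatial gradients on the annotated fields, per map
  out <- out |>
    dplyr::group_by(.data$map_id) |>
    dplyr::group_modify(function(df, key) {
      xyz <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
      df$GradAT <- spatial_gradient(xyz, df$LATB, gradient_radius_mm)
      df$GradRT <- spatial_gradient(xyz, df$RT, gradient_radius_mm)
      df$GradARI <- spatial_gradient(xyz, df$ARIB, gradient_radius_mm)
      df
    }) |>
    dplyr::ungroup()

  out <- dplyr::left_join(out, study$maps[, c("map_id", "rhythm")], by = "map_id")
  for (r in rhythm_levels) out[[paste0("is_", r)]] <- as.integer(out$rhythm == r)
  out$rhythm <- NULL
  missing <- setdiff(registry$name, names(out))
  if (length(missing)) {
    abort(paste0("extraction did not produce registry feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  out[, c("map_id", "point_id", "x_mm", "y_mm", "z_mm", registry$name,
          paste0("is_", rhythm_levels))]
}

# All single-point features for one unipolar/bipolar trace pair.
point_features <- function(uni, bip, tf = tf_spec()) {
  fu <- bandpass(uni)
  fb <- bandpass(bip)
  su <- segment(fu); sb <- segment(fb)

  latb <- detect_lat(fb)
  rt <- detect_rt(fu)
  arib <- rt - latb

  sl_bq <- slope_stats(fb, sb$qrs); sl_bp <- slope_stats(fb, sb$post)
  sl_uq <- slope_stats(fu, su$qrs); sl_ut <- slope_stats(fu, su$post)

  # time-frequency and spectral features from the unfiltered traces
  qrs_ms <- sample_to_ms(c(bip$qrs_on, bip$qrs_end), bip$fs)
  tf_b <- spwvd(bip, tf)
  eb_q <- band_energies(tf_b, qrs_ms, channel_bands("bipolar"))
  eb_p <- band_energies(tf_b,
                        c(qrs_ms[2], max(attr(tf_b, "times_ms")) + 1),
                        channel_bands("bipolar"))
  tf_u <- spwvd(uni, tf)
  t_ms <- sample_to_ms(uni$t_end, uni$fs)
  eu_q <- band_energies(tf_u, qrs_ms, channel_bands("unipolar"))
  eu_t <- band_energies(tf_u, c(qrs_ms[2], t_ms), channel_bands("unipolar"))

  whole_b <- seq.int(bip$qrs_on, length(bip$samples))
  whole_u <- seq.int(uni$qrs_on, uni$t_end)

  tibble(
    LATB = latb, RT = rt, ARIB = arib,
    DB = egm_duration(fb, seq.int(fb$qrs_on, length(fb$samples))),
    DU = egm_duration(fu, su$qrs),
    AB = amplitude(fb, sb$qrs), AU = amplitude(fu, su$qrs),
    ABp = amplitude(fb, sb$post), AUT = amplitude(fu, su$post),
    DefB = count_deflections(fb, sb$qrs), DefU = count_deflections(fu, su$qrs),
    max_dBQRS_dt = sl_bq[["max"]], mean_dBQRS_dt = sl_bq[["mean"]],
    max_dBp_dt = sl_bp[["max"]], mean_dBp_dt = sl_bp[["mean"]],
    max_dUQRS_dt = sl_uq[["max"]], mean_dUQRS_dt = sl_uq[["mean"]],
    max_dUT_dt = sl_ut[["max"]], mean_dUT_dt = sl_ut[["mean"]],
    fB = central_frequency(bip, whole_b), fU = central_frequency(uni, whole_u),
    PB = spectral_peaks(bip, whole_b), PU = spectral_peaks(uni, whole_u),
    EB_QRS_0_160 = eb_q$total, EB_P_0_160 = eb_p$total,
    RU_QRS_0_80 = eu_q$total, RU_T_0_80 = eu_t$total,
    RB_QRS_0_40 = eb_q$fractions[1], RB_QRS_40_80 = eb_q$fractions[2],
    RB_QRS_80_120 = eb_q$fractions[3], RB_QRS_120_160 = eb_q$fractions[4],
    RB_P_0_40 = eb_p$fractions[1], RB_P_40_80 = eb_p$fractions[2],
    RB_P_80_120 = eb_p$fractions[3], RB_P_120_160 = eb_p$fractions[4],
    RU_QRS_0_20 = eu_q$fractions[1], RU_QRS_20_40 = eu_q$fractions[2],
    RU_QRS_40_60 = eu_q$fractions[3], RU_QRS_60_80 = eu_q$fractions[4],
    RU_T_0_20 = eu_t$fractions[1], RU_T_20_40 = eu_t$fractions[2],
    RU_T_40_60 = eu_t$fractions[3], RU_T_60_80 = eu_t$fractions[4]
  )
}

#' Build the modelling feature table (features + labels + groups)
#'
#' Convenience wrapper: deduplicates the study, extracts features, labels
#' points by distance to the VT critical sites and attaches the leakage
#' group ids.
#'
#' @param study a `vts_study`.
#' @param radius_mm labeling radius (default 6).
#' @param ... passed to [extract_features()].
#' @return The feature tibble with `label` (0/1) and `group_id` columns.
#' @export
build_feature_table <- function(study, radius_mm = 6, ...) {
  study <- deduplicate(study)
  feats <- extract_features(study, ...)
  labs <- label_points(study, radius_mm = radius_mm)
  dplyr::left_join(feats, labs[, c("map_id", "point_id", "label", "group_id")],
                   by = c("map_id", "point_id"))
}

#' Export a feature table as CSV
#'
#' Header row matches the registry feature names.
#'
#' @param table a feature tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
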