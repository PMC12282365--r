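#' Enumerate the model-suite configurations
#'
#' The signal-type by map-source cross: both channels on (i) all maps,
#' (ii) SR, (iii) LV, (iv) RV pacing maps; unipolar only on (v) SR, (vi) LV,
#' (vii) RV; bipolar only on (viii) SR, (ix) LV, (x) RV — 10 configurations.
#' BIV maps contribute to "all" but are never modelled alone (too few
#' points).
#'
#' @return Tibble with `config_id`, `channels`, `maps`.
#' @export
suite_configs <- function() {
  tibble(
    config_id = c("both_all", "both_SR", "both_LV", "both_RV",
                  "uni_SR", "uni_LV", "uni_RV",
                  "bip_SR", "bip_LV", "bip_RV"),
    channels = c(rep("both", 4), rep("unipolar", 3), rep("bipolar", 3)),
    maps = c("all", "SR", "LV", "RV", "SR", "LV", "RV", "SR", "LV", "RV")
  )
}

suite_rows <- function(table, maps) {
  if (maps == "all") seq_len(nrow(table))
  else which(table[[paste0("is_", maps)]] == 1L)
}

suite_features <- function(table, channels, maps) {
  feats <- registry_features(model = channels)
  feats <- intersect(feats, names(table))
  if (maps == "all") feats <- c(feats, intersect(paste0("is_", rhythm_levels),
                                                 names(table)))
  feats
}

#' Run the 10-configuration model suite
#'
#' One global grouped 80/20 split of the table, then for each configuration:
#' restrict rows to its map source and features to its channel model (plus
#' map-type indicators for the all-maps model), rank features by RF
#' importance on the training rows, keep the top `select_k`, and run the full
#' repeated-CV evaluation.
#'
#' @param table feature tibble with `label`, `group_id`, `map_id` (features
#'   should be normalized).
#' @param algorithm classifier for every configuration (default `"RF"`).
#' @param undersample_ratio undersampling during CV (default `"none"`, the
#'   protocol's final choice).
#' @param select_k top-importance features kept per configuration
#'   (default 20).
#' @param k,repeats CV geometry.
#' @param seed RNG seed.
#' @param frac training fraction of the global split.
#' @return A tibble with one row per configuration (glance of each
#'   `vts_eval`), with the reports in the `report` list-column; skipped
#'   configurations (no rows / too few positive groups) carry `NA` metrics.
#' @export
run_model_suite <- function(table, algorithm = "RF",
                            undersample_ratio = "none", select_k = 20L,
                            k = 10L, repeats = 10L, seed = 1L, frac = 0.8) {
  cfgs <- suite_configs()
  split <- grouped_split(table, frac = frac, seed = child_seed(seed, "split"))
  purrr::map_dfr(seq_len(nrow(cfgs)), function(i) {
    rows <- suite_rows(table, cfgs$maps[i])
    feats <- suite_features(table, cfgs$channels[i], cfgs$maps[i])
    sub <- table[rows, ]
    sub_split <- list(train = match(intersect(split$train, rows), rows),
                      test = match(intersect(split$test, rows), rows))
    class(sub_split) <- "vts_split"
    n_pos_groups <- length(unique(sub$group_id[sub$label == 1L &
                                    seq_len(nrow(sub)) %in% sub_split$train]))
    if (!nrow(sub) || n_pos_groups < k || !length(sub_split$test)) {
      warn(sprintf("configuration %s skipped (insufficient data)", cfgs$config_id[i]))
      return(tibble(config_id = cfgs$config_id[i], channels = cfgs$channels[i],
                    maps = cfgs$maps[i], auc = NA_real_,
                    report = list(NULL)))
    }
    rank <- rf_importance(sub, feats, rows = sub_split$train,
                          seed = child_seed(seed, paste0("imp", i)))
    keep <- rank$feature[seq_len(min(select_k, nrow(rank)))]
    ev <- train_eval(sub, sub_split,
                     model_config(algorithm, keep, undersample_ratio),
                     k = k, repeats = repeats,
                     seed = child_seed(seed, paste0("ev", i)))
    dplyr::bind_cols(
      tibble(config_id = cfgs$config_id[i], channels = cfgs$channels[i],
             maps = cfgs$maps[i]),
      glance(ev)[, c("cv_auc", "cv_auc_lo", "cv_auc_hi", "auc", "f1", "ppv",
                     "sensitivity", "specificity", "prevalence")],
      tibble(report = list(ev)))
  })
}

#' Distance sensitivity: AUC and prevalence across labeling radii
#'
#' Re-labels the study at each radius, rebuilds the grouped split (same
#' seed), trains the configured model and reports held-out AUC together with
#' the prevalence at that radius.
#'
#' @param study the `vts_study` (for re-labeling).
#' @param features extracted feature tibble (from [extract_features()],
#'   normalized or raw).
#' @param radii_mm radii in mm (default 3:10).
#' @param algorithm,select_k,k,repeats,seed,frac as in [run_model_suite()].
#' @return Tibble `radius_mm`, `prevalence`, `auc` (class
#'   `vts_sensitivity`); radii whose test partition has no positives report
#'   `NA` AUC.
#' @export
distance_sensitivity <- function(study, features, radii_mm = 3:10,
                                 algorithm = "RF", select_k = 20L,
                                 k = 10L, repeats = 3L, seed = 1L, frac = 0.8) {
  feats <- intersect(build_registry()$name, names(features))
  features <- dplyr::select(features, -dplyr::any_of(c("label", "group_id")))
  out <- purrr::map_dfr(radii_mm, function(r) {
    labs <- label_points(study, radius_mm = r)
    tab <- dplyr::left_join(features,
                            labs[, c("map_id", "point_id", "label", "group_id")],
                            by = c("map_id", "point_id"))
    prev <- mean(tab$label)
    n_groups <- length(unique(tab$group_id[tab$label == 1L]))
    if (n_groups < max(2L, k)) {
      return(tibble(radius_mm = r, prevalence = prev, auc = NA_real_))
    }
    split <- grouped_split(tab, frac = frac, seed = child_seed(seed, "split"))
    if (!sum(tab$label[split$test])) {
      return(tibble(radius_mm = r, prevalence = prev, auc = NA_real_))
    }
    rank <- rf_importance(tab, feats, rows = split$train,
                          seed = child_seed(seed, paste0("imp", r)))
    keep <- rank$feature[seq_len(min(select_k, nrow(rank)))]
    ev <- train_eval(tab, split, model_config(algorithm, keep),
                     k = k, repeats = repeats,
                     seed = child_seed(seed, paste0("ev", r)))
    tibble(radius_mm = r, prevalence = prev, auc = ev$test$auc)
  })
  class(out) <- c("vts_sensitivity", class(out))
  out
}

#' Single-feature benchmarks
#'
#' AUC of each raw feature used alone as a classifier (orientation chosen so
#' AUC >= 0.5), the traditional single-parameter substrate-mapping
#' comparators: activation-time gradient, ARI gradient and voltage (bipolar
#' peak-to-peak amplitude).
#'
#' @param table feature tibble with `label`.
#' @param features feature names (default `GradAT`, `GradARI` and `AB`).
#' @param rows rows to evaluate on (default all; pass a test partition for a
#'   held-out benchmark).
#' @return Tibble `feature`, `auc`; constant features report `NA`.
#' @export
single_feature_benchmark <- function(table,
                                     features = c(GradAT = "GradAT",
                                                  GradARI = "GradARI",
                                                  voltage = "AB"),
                                     rows = seq_len(nrow(table))) {
  purrr::map_dfr(seq_along(features), function(i) {
    x <- table[[features[[i]]]][rows]
    y <- table$label[rows]
    ok <- is.finite(x)
    a <- if (length(unique(x[ok])) < 2L) NA_real_ else {
      max(auc_score(y[ok], x[ok]), auc_score(y[ok], -x[ok]))
    }
    tibble(feature = names(features)[i] %||% features[[i]],
           column = features[[i]], auc = a)
  })
}
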