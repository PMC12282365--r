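#' Pipeline run configuration
#'
#' Bundles every stage's settings; a run is fully determined by this object
#' (and the package version). The root seed is fanned out to per-stage child
#' seeds so stages are individually reproducible.
#'
#' @param seed root seed.
#' @param sim a [sim_config()] (its own seed is overridden by `seed`), or
#'   `NULL` when `bundle` is given.
#' @param bundle optional path to a map bundle to analyse instead of
#'   simulating.
#' @param label_radius_mm primary labeling radius (default 6).
#' @param sweep_radii_mm distance-sensitivity radii (default 3:10).
#' @param algorithm suite classifier (default `"RF"`).
#' @param undersample_ratio CV undersampling (default `"none"`).
#' @param select_k top-importance features per configuration (default 20).
#' @param cv_k,cv_repeats CV geometry.
#' @param stages stages to run, subset of
#'   `c("extract","label","associate","train","sensitivity")`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, sim = sim_config(), bundle = NULL,
                       label_radius_mm = 6, sweep_radii_mm = 3:10,
                       algorithm = "RF", undersample_ratio = "none",
                       select_k = 20L, cv_k = 10L, cv_repeats = 10L,
                       stages = c("extract", "label", "associate",
                                  "train", "sensitivity")) {
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, bundle = bundle,
                 label_radius_mm = label_radius_mm,
                 sweep_radii_mm = sweep_radii_mm, algorithm = algorithm,
                 undersample_ratio = undersample_ratio,
                 select_k = as.integer(select_k),
                 cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
                 stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> deduplicate -> extract -> label -> associate ->
#' model suite -> distance sensitivity, with a manifest recording the config
#' hash, seed and per-stage row counts. Stages omitted from `config$stages`
#' are taken from `prior` (a previous run) when available.
#'
#' @param config a [run_config()].
#' @param prior optional previous `vts_run` supplying cached stage outputs.
#' @return A `vts_run` list: `study`, `features` (labeled, normalized),
#'   `association`, `suite`, `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), prior = NULL) {
  stage <- function(name, cached, expr) {
    if (name %in% config$stages) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)))
      })
    } else cached   # stage toggled off: reuse the prior run's output (or NULL)
  }

  study <- if (!is.null(config$bundle)) read_map_bundle(config$bundle)
           else generate_study(config$sim)
  n_before <- nrow(study$points)
  study <- deduplicate(study)

  features <- stage("extract", prior$features, {
    ft <- build_feature_table(study, radius_mm = config$label_radius_mm)
    normalize_features(ft, intersect(build_registry()$name, names(ft)))
  })
  association <- if (is.null(features)) NULL else {
    stage("associate", prior$association, associate(features))
  }
  suite <- if (is.null(features)) NULL else {
    stage("train", prior$suite, run_model_suite(
      features, algorithm = config$algorithm,
      undersample_ratio = config$undersample_ratio,
      select_k = config$select_k, k = config$cv_k, repeats = config$cv_repeats,
      seed = child_seed(config$seed, "suite")))
  }
  sensitivity <- if (is.null(features)) NULL else {
    stage("sensitivity", prior$sensitivity, distance_sensitivity(
      study, features, radii_mm = config$sweep_radii_mm,
      algorithm = config$algorithm, select_k = config$select_k,
      seed = child_seed(config$seed, "sens")))
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stages = config$stages,
    counts = list(
      n_maps = nrow(study$maps),
      n_points_raw = n_before,
      n_points = nrow(study$points),
      n_duplicates_removed = n_before - nrow(study$points),
      n_sites = nrow(study$sites),
      n_features = if (is.null(features)) NA_integer_ else
        sum(build_registry()$name %in% names(features)),
      n_positive = if (is.null(features)) NA_integer_ else sum(features$label),
      prevalence = if (is.null(features)) NA_real_ else mean(features$label)))
  structure(list(study = study, features = features,
                 association = association, suite = suite,
                 sensitivity = sensitivity, manifest = manifest),
            class = "vts_run")
}

#' @export
print.vts_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<vts_run seed %d | %d maps, %d points (%d duplicates removed), %d sites | prevalence %.2f%%>\n",
              m$seed, m$counts$n_maps, m$counts$n_points,
              m$counts$n_duplicates_removed, m$counts$n_sites,
              100 * m$counts$prevalence))
  invisible(x)
}

#' Render a human-readable report of a pipeline run
#'
#' Per-map point/target counts (median and IQR by map type), the association
#' table sorted by p-value, the per-configuration metric table and the
#' AUC-versus-radius table. Missing stages are omitted with a notice.
#'
#' @param run a `vts_run`.
#' @return A `vts_report` list of tibbles; its print method lays the
#'   sections out as tables.
#' @export
render_report <- function(run) {
  notices <- character(0)

  counts <- run$features |>
    dplyr::count(.data$map_id, wt = NULL, name = "points")
  pos <- run$features |>
    dplyr::group_by(.data$map_id) |>
    dplyr::summarise(targets = sum(.data$label), .groups = "drop")
  per_map <- dplyr::left_join(counts, pos, by = "map_id") |>
    dplyr::left_join(run$study$maps, by = "map_id") |>
    dplyr::group_by(.data$rhythm, .data$protocol) |>
    dplyr::summarise(
      n_maps = dplyr::n(),
      points_median = median(.data$points),
      points_iqr_lo = quantile(.data$points, 0.25),
      points_iqr_hi = quantile(.data$points, 0.75),
      targets_median = median(.data$targets),
      .groups = "drop")

  assoc <- if (!is.null(run$association) && nrow(run$association$multi)) {
    dplyr::arrange(run$association$multi, .data$p_value)
  } else {
    notices <- c(notices, "association stage missing or empty: section omitted")
    NULL
  }
  models <- if (!is.null(run$suite)) {
    dplyr::select(run$suite, -dplyr::any_of("report"))
  } else {
    notices <- c(notices, "model suite missing: section omitted")
    NULL
  }
  structure(list(per_map = per_map, association = assoc, models = models,
                 sensitivity = run$sensitivity, manifest = run$manifest,
                 notices = notices),
            class = "vts_report")
}

#' @export
print.vts_report <- function(x, ...) {
  cat("== Substrate-map analysis report ==\n")
  cat(sprintf("seed %d | %d points | prevalence %.2f%%\n\n", x$manifest$seed,
              x$manifest$counts$n_points, 100 * x$manifest$counts$prevalence))
  cat("-- Points per map (median, IQR) --\n"); print(x$per_map)
  if (!is.null(x$association)) {
    cat("\n-- Multivariable associations (sorted by p) --\n")
    print(x$association, n = nrow(x$association))
  }
  if (!is.null(x$models)) {
    cat("\n-- Model suite --\n"); print(x$models, n = nrow(x$models))
  }
  if (!is.null(x$sensitivity) && nrow(x$sensitivity)) {
    cat("\n-- Distance sensitivity --\n")
    print(as_tibble(x$sensitivity), n = 20)
  }
  for (n in x$notices) cat("\nnotice:", n, "\n")
  invisible(x)
}
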