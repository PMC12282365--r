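#' Random-forest permutation importance ranking
#'
#' Fits the protocol's random forest (100 trees, minimum leaf size 1) on the
#' given rows and ranks features by out-of-bag permutation importance (mean
#' decrease in accuracy), most important first.
#'
#' @param table feature tibble with `label`.
#' @param features feature columns to score.
#' @param rows row indices to train on (default all).
#' @param seed RNG seed (the ranking is deterministic under it).
#' @return Tibble `feature`, `score`, sorted descending; `rank` column added.
#' @export
rf_importance <- function(table, features, rows = seq_len(nrow(table)), seed = 1L) {
  x <- as.matrix(table[rows, features])
  x <- impute_median(x, x[0, , drop = FALSE])$train
  y <- factor(table$label[rows], levels = c(0, 1))
  withr::with_seed(seed, {
    fit <- randomForest::randomForest(x = x, y = y, ntree = 100L,
                                      nodesize = 1L, importance = TRUE)
  })
  imp <- randomForest::importance(fit, type = 1L, scale = TRUE)
  out <- tibble(feature = rownames(imp), score = as.numeric(imp[, 1]))
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  out$rank <- seq_len(nrow(out))
  out
}

#' Sequential feature addition along an importance ranking
#'
#' Features are added one at a time from the most to the least important and
#' each prefix is scored by grouped cross-validated AUC; the selected set is
#' the top `select_k` (default 20) regardless of the curve, mirroring the
#' protocol's stability-over-optimality choice.
#'
#' @param table feature tibble.
#' @param ranking tibble from [rf_importance()] (or any `feature` column in
#'   descending priority).
#' @param split a [grouped_split()]; the curve is computed on its training
#'   rows.
#' @param algorithm classifier used for the curve (default `"RF"`).
#' @param k_grid prefix sizes to evaluate (default every size).
#' @param cv_k,cv_repeats cross-validation geometry for the curve (kept
#'   small by default; the curve is a diagnostic, not the final evaluation).
#' @param select_k size of the selected feature set (default 20).
#' @param seed RNG seed.
#' @return List with `curve` (tibble `k`, `auc`) and `selected` (character).
#' @export
sequential_addition <- function(table, ranking, split, algorithm = "RF",
                                k_grid = seq_len(nrow(ranking)),
                                cv_k = 5L, cv_repeats = 2L,
                                select_k = 20L, seed = 1L) {
  feats <- ranking$feature
  folds <- make_folds(table, split$train, k = cv_k, repeats = cv_repeats,
                      seed = child_seed(seed, "sa_folds"))
  rows <- split$train
  y_all <- table$label
  curve <- purrr::map_dfr(k_grid, function(kk) {
    cfg <- model_config(algorithm, features = feats[seq_len(kk)])
    x_all <- as.matrix(table[, cfg$features, drop = FALSE])
    aucs <- vapply(seq_len(cv_repeats), function(r) {
      fold <- folds[[r]]
      scores <- rep(NA_real_, length(rows))
      for (f in seq_len(cv_k)) {
        va <- rows[fold == f]; tr <- rows[fold != f]
        if (length(unique(y_all[tr])) < 2L || !length(va)) next
        scores[match(va, rows)] <- fit_predict(
          cfg, x_all[tr, , drop = FALSE], y_all[tr],
          x_all[va, , drop = FALSE],
          seed = child_seed(seed, sprintf("sa%d_%d_%d", kk, r, f)))
      }
      ok <- is.finite(scores)
      auc_score(y_all[rows[ok]], scores[ok])
    }, numeric(1))
    tibble(k = kk, auc = mean(aucs, na.rm = TRUE))
  })
  list(curve = curve,
       selected = feats[seq_len(min(select_k, length(feats)))])
}

#' PCA baseline projection
#'
#' Projects normalized features onto the smallest number of principal
#' components explaining at least `variance_target` of the training-row
#' variance (loadings from training rows only; the component count is
#' data-driven, never hard-coded).
#'
#' @param table feature tibble (features already normalized).
#' @param features feature columns.
#' @param split a [grouped_split()]; loadings come from its training rows.
#' @param variance_target cumulative explained-variance target (default 0.90).
#' @return List: `table` (projected tibble with `PC1..PCk` plus `label`,
#'   `group_id`, `map_id`), `n_components`, `explained_variance`, `rotation`.
#' @export
pca_baseline <- function(table, features, split, variance_target = 0.90) {
  x <- as.matrix(table[, features])
  x <- impute_median(x[split$train, , drop = FALSE], x)$test
  pc <- prcomp(x[split$train, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(ev >= variance_target)[1]
  proj <- scale(x, center = pc$center, scale = FALSE) %*%
    pc$rotation[, seq_len(ncomp), drop = FALSE]
  out <- as_tibble(as.data.frame(proj))
  out$label <- table$label
  out$group_id <- table$group_id
  out$map_id <- table$map_id
  list(table = out, n_components = ncomp,
       explained_variance = ev[ncomp], rotation = pc$rotation)
}
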