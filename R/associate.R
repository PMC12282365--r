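#' Normalize feature columns (log-transform skewed, then z-score)
#'
#' Features whose training-set skewness exceeds 2 in absolute value are
#' log1p-transformed after shifting to positive support; every continuous
#' feature is then centred and scaled to unit SD. All statistics (skewness,
#' shift, mean, SD) come from the training rows only and are re-applied
#' unchanged to the remaining rows, so no test information leaks into the
#' transform. Zero-variance columns are set to 0 and flagged.
#'
#' @param table feature tibble.
#' @param features character vector of feature columns to transform.
#' @param train logical or integer row selector for the training rows
#'   (default: all rows).
#' @param skew_threshold |skewness| above which a log transform is applied.
#' @return The table with transformed columns; the recipe (per-feature shift,
#'   log flag, mean, sd, constant flag) is attached as attribute
#'   `"norm_recipe"`.
#' @export
normalize_features <- function(table, features, train = NULL,
                               skew_threshold = 2) {
  if (is.null(train)) train <- rep(TRUE, nrow(table))
  if (is.numeric(train)) train <- seq_len(nrow(table)) %in% train
  recipe <- list()
  constant <- character(0)
  for (f in features) {
    x <- table[[f]]
    xt <- x[train]
    use_log <- FALSE; shift <- 0
    if (is.finite(skew_threshold) && abs(skewness(xt)) > skew_threshold) {
      use_log <- TRUE
      shift <- min(xt, na.rm = TRUE)
      x <- log1p(x - shift)
      xt <- x[train]
    }
    m <- mean(xt, na.rm = TRUE)
    s <- sd(xt, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      constant <- c(constant, f)
      table[[f]] <- 0
      recipe[[f]] <- list(log = use_log, shift = shift, mean = m, sd = 1,
                          constant = TRUE)
    } else {
      table[[f]] <- (x - m) / s
      recipe[[f]] <- list(log = use_log, shift = shift, mean = m, sd = s,
                          constant = FALSE)
    }
  }
  if (length(constant)) {
    warn(paste0("zero-variance feature(s) left at 0: ",
                paste(constant, collapse = ", ")))
  }
  attr(table, "norm_recipe") <- recipe
  table
}

#' Pearson and Spearman correlation matrices of the features
#'
#' @param table feature tibble.
#' @param features feature columns to correlate.
#' @return A list of two symmetric matrices, `pearson` and `spearman`, class
#'   `vts_corr`.
#' @export
correlation_heatmap <- function(table, features) {
  x <- as.matrix(table[, features])
  structure(list(pearson = cor(x, method = "pearson",
                               use = "pairwise.complete.obs"),
                 spearman = cor(x, method = "spearman",
                                use = "pairwise.complete.obs")),
            class = "vts_corr")
}

glmer_quiet <- function(formula, data) {
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = data, family = binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, converged = converged)
}

assoc_row <- function(fit, term, model, converged) {
  sm <- summary(fit)$coefficients
  est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  tibble(feature = term, odds_ratio = exp(est),
         ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
         p_value = sm[term, "Pr(>|z|)"], model = model, converged = converged)
}

#' Single-variable mixed-effects logistic regression
#'
#' Fits `label ~ feature + (1 | map_id)` by Laplace-approximated maximum
#' likelihood. With z-scored features the odds ratio is per 1-SD increase.
#' Non-convergence is flagged in the result, never silent.
#'
#' @param table feature tibble with `label` and `map_id`.
#' @param feature feature column name.
#' @return One-row tibble: feature, odds_ratio, ci_low, ci_high, p_value,
#'   model = "single", converged.
#' @export
fit_single_mixed <- function(table, feature) {
  if (length(unique(table$map_id)) < 2L) abort("need >= 2 maps for a mixed fit")
  d <- data.frame(label = table$label, x = table[[feature]],
                  map_id = table$map_id)
  d <- d[complete.cases(d), ]
  r <- glmer_quiet(label ~ x + (1 | map_id), d)
  out <- assoc_row(r$fit, "x", "single", r$converged)
  out$feature <- feature
  out
}

#' Variance-inflation-factor pruning
#'
#' Computes each feature's VIF = 1 / (1 - R^2) from a linear regression on
#' the remaining features and iteratively drops the worst offender until all
#' VIFs are at or below the threshold. With perfect collinearity the
#' duplicated member is dropped first (infinite VIF).
#'
#' @param table feature tibble.
#' @param features candidate feature columns.
#' @param threshold VIF threshold (default 10).
#' @return Character vector of retained features; the drop history (feature,
#'   vif) is attached as attribute `"dropped"`.
#' @export
vif_prune <- function(table, features, threshold = 10) {
  x <- as.data.frame(table[, features])
  x <- x[complete.cases(x), , drop = FALSE]
  keep <- features
  dropped <- tibble(feature = character(0), vif = numeric(0))
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, function(f) {
      r2 <- summary(lm(stats::reformulate(setdiff(keep, f), response = f),
                       data = x))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- max(vifs)
    if (worst <= threshold) break
    ties <- which(vifs == worst)
    drop <- keep[ties[length(ties)]]
    dropped <- dplyr::add_row(dropped, feature = drop, vif = worst)
    keep <- setdiff(keep, drop)
  }
  attr(keep, "dropped") <- dropped
  keep
}

compute_vif <- function(table, features) {
  x <- as.data.frame(table[, features])
  x <- x[complete.cases(x), , drop = FALSE]
  vapply(features, function(f) {
    r2 <- summary(lm(stats::reformulate(setdiff(features, f), response = f),
                     data = x))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Multivariable mixed-effects logistic regression
#'
#' One joint fit of the retained features (plus, optionally, map-type
#' indicator covariates as fixed effects) with a random intercept per map.
#'
#' @param table feature tibble with `label`, `map_id` and (optionally) the
#'   `is_*` indicator columns.
#' @param features retained feature columns.
#' @param map_type_covariates include the map-type indicators (default TRUE
#'   when present and varying; the SR indicator is the reference level).
#' @return Tibble of per-feature association rows (model = "multi"); returns
#'   an empty tibble with a warning when `features` is empty.
#' @export
fit_multivariable <- function(table, features, map_type_covariates = TRUE) {
  if (!length(features)) {
    warn("no features retained for the multivariable model")
    return(tibble(feature = character(0), odds_ratio = numeric(0),
                  ci_low = numeric(0), ci_high = numeric(0),
                  p_value = numeric(0), model = character(0),
                  converged = logical(0)))
  }
  d <- as.data.frame(table[, c("label", "map_id", features)])
  covars <- character(0)
  if (map_type_covariates) {
    ind <- intersect(paste0("is_", c("LV", "RV", "BIV")), names(table))
    ind <- ind[vapply(ind, function(i) stats::var(table[[i]]) > 0, logical(1))]
    if (length(ind)) {
      d <- cbind(d, as.data.frame(table[, ind]))
      covars <- ind
    }
  }
  d <- d[complete.cases(d), ]
  form <- stats::reformulate(c(features, covars, "(1 | map_id)"),
                             response = "label")
  r <- glmer_quiet(form, d)
  dplyr::bind_rows(lapply(features, function(f) assoc_row(r$fit, f, "multi", r$converged)))
}

#' Run the full association analysis
#'
#' Normalizes the features (training rows), fits single-variable mixed
#' models for every feature, keeps those significant after Bonferroni
#' correction (0.05 divided by the number of tested features), prunes
#' collinearity by VIF and fits the joint multivariable mixed model.
#'
#' @param table feature tibble with `label`, `map_id` and indicator columns.
#' @param features features to screen (default: all registry features present).
#' @param train row selector for the training partition (default all rows).
#' @param vif_threshold VIF threshold (default 10).
#' @return A `vts_association` object: list with `single`, `multi` (tibbles,
#'   sorted by p-value), `retained`, `bonferroni_p`, `n_features`.
#' @export
associate <- function(table, features = NULL, train = NULL, vif_threshold = 10) {
  reg <- build_registry()
  features <- features %||% intersect(reg$name, names(table))
  if (is.null(train)) train <- rep(TRUE, nrow(table))
  if (is.numeric(train)) train <- seq_len(nrow(table)) %in% train
  tab <- normalize_features(table, features, train = train)
  recipe <- attr(tab, "norm_recipe")
  usable <- features[!vapply(features, function(f) recipe[[f]]$constant, logical(1))]
  tab <- tab[train, ]

  single <- dplyr::bind_rows(lapply(usable, function(f) fit_single_mixed(tab, f)))
  single <- dplyr::arrange(single, .data$p_value)
  bonf <- 0.05 / length(usable)
  sig <- single$feature[single$p_value < bonf]
  retained <- if (length(sig) >= 2L) vif_prune(tab, sig, vif_threshold) else sig
  multi <- fit_multivariable(tab, as.character(retained))
  multi <- dplyr::arrange(multi, .data$p_value)
  structure(list(single = single, multi = multi,
                 retained = as.character(retained),
                 bonferroni_p = bonf, n_features = length(usable)),
            class = "vts_association")
}

#' @export
print.vts_association <- function(x, ...) {
  cat(sprintf("<vts_association: %d features screened, Bonferroni p < %.2e, %d significant, %d retained after VIF>\n",
              x$n_features, x$bonferroni_p,
              sum(x$single$p_value < x$bonferroni_p), length(x$retained)))
  print(x$multi, n = 10)
  invisible(x)
}

#' @rdname associate
#' @param x a `vts_association`.
#' @param ... unused.
#' @method tidy vts_association
#' @export
tidy.vts_association <- function(x, ...) {
  dplyr::bind_rows(x$single, x$multi)
}

#' @rdname associate
#' @method glance vts_association
#' @export
glance.vts_association <- function(x, ...) {
  tibble(n_features = x$n_features, bonferroni_p = x$bonferroni_p,
         n_significant = sum(x$single$p_value < x$bonferroni_p),
         n_retained = length(x$retained),
         all_converged = all(c(x$single$converged, x$multi$converged)))
}
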