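#' Classifier configuration
#'
#' Hyperparameters are fixed to the protocol's printed values: random forest
#' with 100 trees and minimum leaf size 1; SVM with Gaussian (radial) kernel
#' and box constraint 1 (Platt-calibrated probabilities for ROC); KNN with
#' k = 10 and Euclidean distance; plain logistic regression as the reference.
#'
#' @param algorithm `"RF"`, `"SVM"`, `"KNN"` or `"logistic"`.
#' @param features feature column names the model sees.
#' @param undersample `"none"`, `"1:1"` or `"1:5"` applied to CV training
#'   folds and the final training fit.
#' @return A `model_config` object.
#' @export
model_config <- function(algorithm = c("RF", "SVM", "KNN", "logistic"),
                         features, undersample = "none") {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, features = features,
                 undersample = undersample,
                 hyper = switch(algorithm,
                   RF = list(trees = 100L, min_leaf = 1L),
                   SVM = list(kernel = "radial", cost = 1),
                   KNN = list(k = 10L, metric = "Euclidean"),
                   logistic = list())),
            class = "model_config")
}

# Median imputation: training-column medians applied to both partitions.
impute_median <- function(x_train, x_test) {
  for (j in seq_len(ncol(x_train))) {
    m <- median(x_train[, j], na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    x_train[!is.finite(x_train[, j]), j] <- m
    x_test[!is.finite(x_test[, j]), j] <- m
  }
  list(train = x_train, test = x_test)
}

# Fit a configured classifier and return positive-class scores on x_test.
fit_predict <- function(cfg, x_train, y_train, x_test, seed = 1L) {
  im <- impute_median(x_train, x_test)
  x_train <- im$train; x_test <- im$test
  y <- factor(y_train, levels = c(0, 1))
  withr::with_seed(seed, switch(cfg$algorithm,
    RF = {
      fit <- randomForest::randomForest(
        x = x_train, y = y, ntree = cfg$hyper$trees,
        nodesize = cfg$hyper$min_leaf)
      unname(predict(fit, x_test, type = "prob")[, "1"])
    },
    SVM = {
      fit <- e1071::svm(x = x_train, y = y, kernel = "radial",
                        cost = cfg$hyper$cost, probability = TRUE)
      pr <- predict(fit, x_test, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    KNN = {
      pr <- class::knn(train = x_train, test = x_test, cl = y,
                       k = cfg$hyper$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    logistic = {
      d <- as.data.frame(x_train); d$.y <- y_train
      fit <- suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
      unname(predict(fit, as.data.frame(x_test), type = "response"))
    }))
}

#' ROC operating point closest to the upper-left corner
#'
#' Evaluates every distinct score threshold and returns the one whose ROC
#' point minimizes the Euclidean distance to (FPR = 0, sensitivity = 1).
#'
#' @param labels 0/1 vector.
#' @param scores classifier scores (higher = more positive).
#' @return A list: `threshold`, `sensitivity`, `specificity` (fractions).
#' @export
roc_operating_point <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  P <- sum(y); N <- length(y) - P
  last <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct score
  sens <- tp[last] / P
  fpr <- fp[last] / N
  d2 <- fpr^2 + (1 - sens)^2
  i <- which.min(d2)
  list(threshold = s[last][i], sensitivity = sens[i], specificity = 1 - fpr[i])
}

# Confusion-matrix rates (%) at a threshold (predict positive when
# score >= threshold).
confusion_metrics <- function(labels, scores, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.finite(ppv) && is.finite(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  c(sensitivity = 100 * sens, specificity = 100 * spec,
    ppv = 100 * ppv, f1 = 100 * f1)
}

auc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c("0", "1"))))
}

boot_ci <- function(x, n_boot = 1000L, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(c(NA_real_, NA_real_))
  withr::with_seed(seed, {
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(sample(x, replace = TRUE)), numeric(1))
  })
  unname(quantile(bm, c(0.025, 0.975)))
}

#' Train and evaluate one model configuration
#'
#' Runs the repeated grouped cross-validation on the training partition
#' (undersampling applied to CV-training folds per the configuration),
#' derives per-repeat ROC metrics at the operating point closest to the
#' upper-left corner, picks the repeat with the highest CV AUC to fix the
#' operating threshold, refits on the full training partition and evaluates
#' once on the held-out test partition at that CV-derived threshold.
#'
#' @param table feature tibble with `label`, `group_id`, `map_id`.
#' @param split a [grouped_split()] plan.
#' @param cfg a [model_config()].
#' @param k,repeats cross-validation geometry (default 10 x 10).
#' @param seed RNG seed.
#' @return A `vts_eval` report: per-repeat CV metrics, CV AUC mean and 95%
#'   bootstrap CI, the chosen threshold and the held-out test metrics.
#' @export
train_eval <- function(table, split, cfg, k = 10L, repeats = 10L, seed = 1L) {
  folds <- make_folds(table, split$train, k = k, repeats = repeats,
                      seed = child_seed(seed, "folds"))
  rows <- split$train
  x_all <- as.matrix(table[, cfg$features])
  y_all <- table$label

  cv <- purrr::map_dfr(seq_len(repeats), function(r) {
    fold <- folds[[r]]
    scores <- rep(NA_real_, length(rows))
    for (f in seq_len(k)) {
      va <- rows[fold == f]
      tr <- rows[fold != f]
      tr <- undersample(table, tr, cfg$undersample,
                        seed = child_seed(seed, sprintf("us%d_%d", r, f)))
      if (length(unique(y_all[tr])) < 2L || !length(va)) next  # degenerate fold
      scores[match(va, rows)] <- fit_predict(
        cfg, x_all[tr, , drop = FALSE], y_all[tr], x_all[va, , drop = FALSE],
        seed = child_seed(seed, sprintf("fit%d_%d", r, f)))
    }
    ok <- is.finite(scores)
    yv <- y_all[rows[ok]]; sv <- scores[ok]
    op <- roc_operating_point(yv, sv)
    m <- confusion_metrics(yv, sv, op$threshold)
    tibble(repeat_id = r, auc = auc_score(yv, sv), threshold = op$threshold,
           f1 = m[["f1"]], ppv = m[["ppv"]],
           sensitivity = m[["sensitivity"]], specificity = m[["specificity"]])
  })

  best <- which.max(cv$auc)
  threshold <- cv$threshold[best]
  tr <- undersample(table, rows, cfg$undersample, seed = child_seed(seed, "usfin"))
  test_scores <- fit_predict(cfg, x_all[tr, , drop = FALSE], y_all[tr],
                             x_all[split$test, , drop = FALSE],
                             seed = child_seed(seed, "final"))
  y_test <- y_all[split$test]
  tm <- confusion_metrics(y_test, test_scores, threshold)
  structure(list(
    config = cfg,
    cv = cv,
    cv_auc_mean = mean(cv$auc, na.rm = TRUE),
    cv_auc_ci = boot_ci(cv$auc, seed = child_seed(seed, "boot")),
    threshold = threshold,
    test = tibble(auc = auc_score(y_test, test_scores),
                  f1 = tm[["f1"]], ppv = tm[["ppv"]],
                  sensitivity = tm[["sensitivity"]],
                  specificity = tm[["specificity"]],
                  n_test = length(y_test), prevalence = mean(y_test))),
    class = "vts_eval")
}

#' @export
print.vts_eval <- function(x, ...) {
  cat(sprintf("<vts_eval %s (%d features, undersample %s)>\n",
              x$config$algorithm, length(x$config$features),
              x$config$undersample))
  cat(sprintf("  CV AUC %.3f (95%% CI %.3f-%.3f over %d repeats)\n",
              x$cv_auc_mean, x$cv_auc_ci[1], x$cv_auc_ci[2], nrow(x$cv)))
  cat(sprintf("  test AUC %.3f | F1 %.1f%% | PPV %.1f%% | Se %.1f%% | Sp %.1f%%\n",
              x$test$auc, x$test$f1, x$test$ppv,
              x$test$sensitivity, x$test$specificity))
  invisible(x)
}

#' @rdname train_eval
#' @param x a `vts_eval`.
#' @param ... unused.
#' @method tidy vts_eval
#' @export
tidy.vts_eval <- function(x, ...) x$cv

#' @rdname train_eval
#' @method glance vts_eval
#' @export
glance.vts_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(algorithm = x$config$algorithm,
           n_features = length(x$config$features),
           undersample = x$config$undersample,
           cv_auc = x$cv_auc_mean,
           cv_auc_lo = x$cv_auc_ci[1], cv_auc_hi = x$cv_auc_ci[2],
           threshold = x$threshold),
    x$test)
}
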