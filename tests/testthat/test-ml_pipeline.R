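test_that("grouped split never separates a positive group and is seeded", {
  for (sd in 1:20) {
    tab <- make_fake_table(seed = sd)
    sp <- grouped_split(tab, seed = sd)
    tr_g <- unique(tab$group_id[sp$train][tab$label[sp$train] == 1L])
    te_g <- unique(tab$group_id[sp$test][tab$label[sp$test] == 1L])
    expect_length(intersect(tr_g, te_g), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(nrow(tab)))
  }
  tab <- make_fake_table(seed = 3)
  expect_identical(grouped_split(tab, seed = 9), grouped_split(tab, seed = 9))

  # 10 groups at frac 0.8: 8 groups (+-1) in train
  tab10 <- make_fake_table(n_groups = 10, seed = 6)
  sp <- grouped_split(tab10, frac = 0.8, seed = 2)
  n_tr <- length(unique(tab10$group_id[sp$train][tab10$label[sp$train] == 1L]))
  expect_gte(n_tr, 7L); expect_lte(n_tr, 9L)

  one <- make_fake_table(n_groups = 1, seed = 1)
  expect_error(grouped_split(one), "positive groups")
})

test_that("folds partition the training rows with group-wise positives", {
  tab <- make_fake_table(n_groups = 14, seed = 8)
  sp <- grouped_split(tab, seed = 1)
  folds <- make_folds(tab, sp$train, k = 10, repeats = 10, seed = 4)
  expect_length(folds, 10L)
  for (r in 1:10) {
    fold <- folds[[r]]
    expect_true(all(fold %in% 1:10))
    expect_length(fold, length(sp$train))
    # no positive group spans folds
    pos <- tab$label[sp$train] == 1L
    spans <- tapply(fold[pos], tab$group_id[sp$train][pos],
                    function(f) length(unique(f)))
    expect_true(all(spans == 1L))
  }
  # negative assignment differs across repeats under the same root seed
  neg <- tab$label[sp$train] == 0L
  expect_false(identical(folds[[1]][neg], folds[[2]][neg]))
  expect_error(make_folds(tab, sp$train, k = 15, repeats = 2, seed = 1),
               "positive groups")
})

test_that("undersampling hits exact ratios, keeps positives, warns when short", {
  tab <- make_fake_table(n_maps = 8, points_per_map = 200, seed = 10)
  rows <- seq_len(nrow(tab))
  n_pos <- sum(tab$label)
  r11 <- undersample(tab, rows, "1:1", seed = 3)
  expect_equal(sum(tab$label[r11] == 0L), n_pos)
  expect_equal(sum(tab$label[r11] == 1L), n_pos)
  r15 <- undersample(tab, rows, "1:5", seed = 3)
  expect_equal(sum(tab$label[r15] == 0L), 5L * n_pos)
  expect_identical(undersample(tab, rows, "none"), rows)

  few <- tab[c(which(tab$label == 1L), which(tab$label == 0L)[1:10]), ]
  expect_warning(rr <- undersample(few, seq_len(nrow(few)), "1:5", seed = 1),
                 "not enough negatives")
  expect_equal(length(rr), nrow(few))
})

test_that("the ROC operating point matches an exhaustive search", {
  # ROC points {(0,0),(0.2,0.9),(1,1)}: the corner point (0.2,0.9) wins
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.8, 9), 0.1, rep(0.8, 2), rep(0.1, 8))
  op <- roc_operating_point(labels, scores)
  expect_equal(op$sensitivity, 0.9)
  expect_equal(op$specificity, 0.8)
  expect_equal(op$threshold, 0.8)

  # brute force over every candidate threshold on random scores
  withr::with_seed(5, {
    y <- rbinom(300, 1, 0.3)
    s <- runif(300) + 0.4 * y
  })
  op2 <- roc_operating_point(y, s)
  cands <- sort(unique(s))
  d2 <- vapply(cands, function(t) {
    sens <- sum(s >= t & y == 1) / sum(y == 1)
    fpr <- sum(s >= t & y == 0) / sum(y == 0)
    fpr^2 + (1 - sens)^2
  }, numeric(1))
  best <- min(d2)
  got <- (1 - op2$specificity)^2 + (1 - op2$sensitivity)^2
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("PPV follows the closed form and falls with prevalence", {
  ppv_closed <- function(sens, spec, prev) {
    100 * sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  }
  withr::with_seed(7, {
    y <- rbinom(4000, 1, 0.3)
    s <- rnorm(4000, mean = y)
  })
  m <- vtsubstrate:::confusion_metrics(y, s, 0.5)
  expect_equal(m[["ppv"]],
               ppv_closed(m[["sensitivity"]] / 100, m[["specificity"]] / 100,
                          mean(y)),
               tolerance = 1e-9)
  # at fixed sensitivity/specificity, PPV decreases with prevalence
  expect_gt(ppv_closed(0.8, 0.7, 0.3), ppv_closed(0.8, 0.7, 0.073))
  expect_gt(ppv_closed(0.8, 0.7, 0.073), ppv_closed(0.8, 0.7, 0.02))
})

test_that("RF importance ranks a strong feature first and noise near zero", {
  first <- 0L
  for (sd in 1:10) {
    tab <- make_fake_table(n_maps = 4, points_per_map = 150, signal = 3,
                           seed = sd)
    imp <- rf_importance(tab, paste0("f", 1:6), seed = sd)
    expect_equal(nrow(imp), 6L)
    if (imp$feature[1] == "f1") first <- first + 1L
    noise_scores <- imp$score[imp$feature %in% paste0("f", 3:6)]
    expect_lt(mean(noise_scores), imp$score[imp$feature == "f1"] / 3)
  }
  expect_gte(first, 9L)
  expect_identical(rf_importance(tab, paste0("f", 1:6), seed = 1),
                   rf_importance(tab, paste0("f", 1:6), seed = 1))
})

test_that("sequential addition plateaus once the informative features are in", {
  tab <- make_fake_table(n_maps = 6, points_per_map = 150, n_features = 8,
                         signal = 2.5, seed = 2)
  sp <- grouped_split(tab, seed = 1)
  rank <- rf_importance(tab, paste0("f", 1:8), rows = sp$train, seed = 1)
  sa <- sequential_addition(tab, rank, sp, k_grid = c(1, 2, 4, 8),
                            cv_k = 4, cv_repeats = 2, select_k = 4, seed = 1)
  expect_equal(nrow(sa$curve), 4L)
  expect_true(all(sa$curve$auc >= 0 & sa$curve$auc <= 1))
  expect_length(sa$selected, 4L)
  # plateau: all informative features in by k = 2; k = 8 adds nothing big
  a2 <- sa$curve$auc[sa$curve$k == 2]
  a8 <- sa$curve$auc[sa$curve$k == 8]
  expect_lt(abs(a8 - a2), 0.05)
})

test_that("PCA baseline keeps the fewest components for the variance target", {
  tab <- make_fake_table(n_features = 6, seed = 5)
  sp <- grouped_split(tab, seed = 1)
  pb <- pca_baseline(tab, paste0("f", 1:6), sp, variance_target = 0.9)
  expect_gte(pb$explained_variance, 0.9)
  pcs <- as.matrix(pb$table[, seq_len(pb$n_components)])
  cc <- crossprod(scale(pcs[sp$train, ], scale = FALSE))
  off <- cc[upper.tri(cc)] / max(diag(cc))
  expect_lt(max(abs(off)), 1e-8)

  # rank-2 structure needs exactly 2 components
  withr::with_seed(9, {
    z1 <- rnorm(300); z2 <- rnorm(300)
    low <- tibble::tibble(f1 = z1, f2 = z2, f3 = z1 + z2, f4 = z1 - z2,
                          label = rbinom(300, 1, 0.2),
                          group_id = sprintf("g%d", sample(10, 300, TRUE)),
                          map_id = "m1")
  })
  sp2 <- list(train = 1:200, test = 201:300)
  pb2 <- pca_baseline(low, paste0("f", 1:4), sp2, variance_target = 0.9)
  expect_equal(pb2$n_components, 2L)
})

test_that("train_eval separates separable data and evaluates at the CV threshold", {
  tab <- make_fake_table(n_maps = 6, points_per_map = 120, signal = 30,
                         seed = 12)
  sp <- grouped_split(tab, seed = 2)
  ev <- train_eval(tab, sp, model_config("logistic", c("f1", "f2")),
                   k = 5, repeats = 2, seed = 3)
  expect_equal(ev$test$auc, 1, tolerance = 1e-6)
  expect_equal(ev$test$sensitivity, 100)
  expect_equal(ev$test$specificity, 100)
  expect_true(all(tidy(ev)$auc >= 0.99))
  g <- glance(ev)
  expect_true(all(c("auc", "f1", "ppv", "sensitivity", "specificity")
                  %in% names(g)))
})

test_that("every classifier in the config set trains and scores", {
  tab <- make_fake_table(n_maps = 4, points_per_map = 100, signal = 2, seed = 13)
  sp <- grouped_split(tab, seed = 1)
  for (alg in c("RF", "SVM", "KNN", "logistic")) {
    ev <- train_eval(tab, sp, model_config(alg, paste0("f", 1:6)),
                     k = 4, repeats = 2, seed = 2)
    expect_true(is.finite(ev$test$auc), label = alg)
    expect_gt(ev$test$auc, 0.6)
  }
})

test_that("the model suite enumerates 10 configurations with channel filtering", {
  cfgs <- suite_configs()
  expect_equal(nrow(cfgs), 10L)
  expect_equal(sum(cfgs$channels == "both"), 4L)
  expect_equal(sum(cfgs$channels == "unipolar"), 3L)
  expect_equal(sum(cfgs$channels == "bipolar"), 3L)
  expect_false("BIV" %in% cfgs$maps)   # BIV maps are never modelled alone

  reg <- build_registry()
  tab <- make_fake_table(seed = 1)
  for (f in reg$name) tab[[f]] <- rnorm(nrow(tab))
  feats_uni <- vtsubstrate:::suite_features(tab, "unipolar", "SR")
  expect_setequal(feats_uni, registry_features(reg, "unipolar"))
  expect_false(any(reg$name[reg$channel == "bipolar"] %in% feats_uni))
  feats_all <- vtsubstrate:::suite_features(tab, "both", "all")
  expect_true(all(paste0("is_", c("SR", "LV", "RV", "BIV")) %in% feats_all))
})

test_that("single-feature benchmarks orient AUC above 0.5 and flag constants", {
  withr::with_seed(4, {
    tab <- tibble::tibble(label = rbinom(500, 1, 0.3))
    tab$perfect <- tab$label
    tab$inverse <- -tab$label + rnorm(500, sd = 0.01)
    tab$noise <- rnorm(500)
    tab$flat <- 1
  })
  out <- single_feature_benchmark(
    tab, features = c(a = "perfect", b = "inverse", c = "noise", d = "flat"))
  expect_equal(out$auc[1], 1)
  expect_gt(out$auc[2], 0.99)    # orientation flipped
  expect_lt(abs(out$auc[3] - 0.5), 0.08)
  expect_true(is.na(out$auc[4]))
})
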