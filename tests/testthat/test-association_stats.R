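test_that("normalization yields zero-mean unit-SD training columns", {
  withr::with_seed(1, {
    tab <- tibble::tibble(a = rnorm(500, 10, 3), b = rlnorm(500, sdlog = 1.5) * 100,
                          c = rep(4, 500))
  })
  train <- 1:400
  expect_warning(out <- normalize_features(tab, c("a", "b", "c"), train = train),
                 "zero-variance")
  expect_equal(mean(out$a[train]), 0, tolerance = 1e-9)
  expect_equal(sd(out$a[train]), 1, tolerance = 1e-9)
  # skewed column gets log-transformed: skewness reduced
  rec <- attr(out, "norm_recipe")
  expect_true(rec$b$log)
  expect_lt(abs(vtsubstrate:::skewness(out$b[train])),
            abs(vtsubstrate:::skewness(tab$b[train])))
  expect_true(rec$c$constant)
  expect_true(all(out$c == 0))
  # test rows use training statistics (not re-standardized)
  expect_false(isTRUE(all.equal(mean(out$a[-train]), 0, tolerance = 1e-3)))
})

test_that("correlation matrices behave as expected", {
  withr::with_seed(2, {
    tab <- tibble::tibble(x = rnorm(1000))
    tab$y <- -tab$x
    tab$z <- rnorm(1000)
  })
  cm <- correlation_heatmap(tab, c("x", "y", "z"))
  expect_equal(diag(cm$pearson), c(x = 1, y = 1, z = 1))
  expect_equal(cm$pearson["x", "y"], -1)
  expect_equal(cm$spearman["x", "y"], -1)
  expect_lt(abs(cm$pearson["x", "z"]), 0.1)
  expect_equal(cm$pearson, t(cm$pearson))
})

test_that("VIF matches the 1/(1-R^2) closed form and prunes collinearity", {
  withr::with_seed(3, {
    n <- 400
    x1 <- as.numeric(scale(rnorm(n)))
    x2 <- as.numeric(scale(rnorm(n)))
    e <- rnorm(n)
    e <- residuals(lm(e ~ x1 + x2))           # orthogonal to x1, x2, intercept
    e <- as.numeric(scale(e))
  })
  x3 <- sqrt(0.95) * x1 + sqrt(0.05) * e      # R^2 on (x1, x2) is exactly 0.95
  tab <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)
  v <- vtsubstrate:::compute_vif(tab, c("x1", "x2", "x3"))
  expect_equal(unname(v["x3"]), 20, tolerance = 1e-6)

  kept <- vif_prune(tab, c("x1", "x2", "x3"), threshold = 10)
  expect_lt(length(kept), 3L)
  expect_true(all(vtsubstrate:::compute_vif(tab, kept) <= 10))

  # independent cross-check of the VIF definition against car::vif
  y <- x1 + rnorm(400)
  cv <- car::vif(lm(y ~ x1 + x2 + x3, data = tab))
  expect_equal(unname(v), unname(cv), tolerance = 1e-6)

  # exact duplicate: one member dropped first
  dup <- tibble::tibble(a = x1, b = x1, c = x2)
  kept2 <- suppressWarnings(vif_prune(dup, c("a", "b", "c")))
  expect_equal(length(kept2), 2L)
  expect_true("c" %in% kept2)

  # orthogonal features are all retained
  ort <- tibble::tibble(a = x1, b = x2, c = e)
  expect_equal(as.character(vif_prune(ort, c("a", "b", "c"))), c("a", "b", "c"))
})

test_that("mixed fit reduces to pooled logistic when map variance is zero", {
  d <- simulate_mixed_logistic(n_maps = 10, points_per_map = 400,
                               odds_ratio = 2, re_sd = 0, seed = 11)
  mixed <- fit_single_mixed(d, "x")
  pooled <- glm(label ~ x, data = d, family = binomial())
  expect_equal(mixed$odds_ratio, unname(exp(coef(pooled)["x"])),
               tolerance = 0.02)
})

test_that("mixed fit recovers a known odds ratio with random intercepts", {
  d <- simulate_mixed_logistic(n_maps = 20, points_per_map = 500,
                               odds_ratio = 2, re_sd = 1, seed = 5)
  r <- fit_single_mixed(d, "x")
  expect_gt(r$odds_ratio, 1.7)
  expect_lt(r$odds_ratio, 2.3)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_lt(r$p_value, 0.001)
})

test_that("multivariable fit finds active features and not nulls", {
  make_multi <- function(seed) {
    withr::with_seed(seed, {
      n_maps <- 12; ppm <- 400
      purrr::map_dfr(seq_len(n_maps), function(m) {
        b <- rnorm(1, 0, 0.5)
        x <- matrix(rnorm(ppm * 10), ppm, 10)
        colnames(x) <- paste0("f", 1:10)
        eta <- -2.3 + b + log(2) * x[, 1] + log(0.5) * x[, 2]
        dplyr::bind_cols(
          tibble::tibble(map_id = sprintf("m%02d", m),
                         label = rbinom(ppm, 1, plogis(eta))),
          tibble::as_tibble(x))
      })
    })
  }
  hits <- 0L
  for (sd in 1:3) {
    d <- make_multi(sd)
    res <- fit_multivariable(d, paste0("f", 1:10))
    act <- res[res$feature %in% c("f1", "f2"), ]
    nulls <- res[!res$feature %in% c("f1", "f2"), ]
    if (all(act$p_value < 0.05 / 10) && sum(nulls$p_value < 0.05) <= 2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)

  # single-feature table: multivariable reduces to the single fit
  d <- simulate_mixed_logistic(n_maps = 8, points_per_map = 300, seed = 2)
  m1 <- fit_multivariable(d, "x")
  s1 <- fit_single_mixed(d, "x")
  expect_equal(m1$odds_ratio, s1$odds_ratio, tolerance = 1e-6)

  expect_warning(empty <- fit_multivariable(d, character(0)), "no features")
  expect_equal(nrow(empty), 0L)
})

test_that("associate() computes the Bonferroni threshold from the tested count", {
  tab <- make_fake_table(n_maps = 6, points_per_map = 150, signal = 1.5, seed = 4)
  res <- associate(tab, features = paste0("f", 1:6))
  expect_equal(res$bonferroni_p, 0.05 / 6)
  g <- glance(res)
  expect_equal(g$n_features, 6L)
  expect_true(all(c("f1", "f2") %in% res$single$feature[
    res$single$p_value < res$bonferroni_p]))
  td <- tidy(res)
  expect_true(all(c("single", "multi") %in% td$model))
  expect_true(all(td$ci_low <= td$ci_high))
  # association tables are sorted by ascending p-value
  expect_false(is.unsorted(res$multi$p_value))
})
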