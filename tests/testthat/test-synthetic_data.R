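test_that("geometry generation is deterministic and respects the scar fraction", {
  cfg <- tiny_sim_config()
  g1 <- generate_geometry(cfg, n_points = 200, seed = 5)
  g2 <- generate_geometry(cfg, n_points = 200, seed = 5)
  expect_identical(g1$xyz, g2$xyz)
  expect_identical(g1$sites, g2$sites)

  g0 <- generate_geometry(sim_config(scar_fraction = 0), n_points = 100, seed = 1)
  expect_false(any(g0$scar))

  # binomial/area oracle: scar cap covers ~30% of the shell
  g3 <- generate_geometry(sim_config(scar_fraction = 0.3), n_points = 1000, seed = 2)
  expect_gte(sum(g3$scar), 250)
  expect_lte(sum(g3$scar), 350)
})

test_that("site layout keeps labeling balls disjoint and phases assigned", {
  g <- generate_geometry(sim_config(), n_points = 50, seed = 3)
  s <- g$sites
  expect_equal(nrow(s), 6L)
  expect_setequal(unique(s$phase), c("early", "mid", "late"))
  d <- as.matrix(dist(s[, c("x_mm", "y_mm", "z_mm")]))
  diag(d) <- Inf
  expect_gte(min(d), 1.5 * 6)
})

test_that("ground-truth fields satisfy RT = LAT + ARI and the gradient boost", {
  cfg <- sim_config()
  geo <- generate_geometry(cfg, n_points = 400, seed = 9)
  f <- simulate_fields(geo, cfg)
  expect_equal(f$rt_ms - f$lat_ms, f$ari_ms)

  # ARI spatial gradient is elevated near critical sites (10-mm rule)
  g <- spatial_gradient(geo$xyz, f$ari_ms, 10)
  d <- apply(vtsubstrate:::cross_dist(
    geo$xyz, as.matrix(geo$sites[, c("x_mm", "y_mm", "z_mm")])), 1, min)
  expect_gt(mean(g[d <= 6], na.rm = TRUE), mean(g[d > 6], na.rm = TRUE))
})

test_that("without scar, activation time is proportional to source distance", {
  cfg <- sim_config(scar_fraction = 0, n_vts = 0L)
  geo <- generate_geometry(cfg, n_points = 150, seed = 4)
  f <- simulate_fields(geo, cfg, rhythm = "SR")
  org <- vtsubstrate:::pacing_origin("SR", geo$axes)[[1]]
  dist <- sqrt(rowSums(sweep(geo$xyz, 2, org)^2))
  expect_equal(f$lat_ms - 25, dist / 1.5, tolerance = 1e-8)
})

test_that("EGM synthesis is seeded, quiet far from scar, and amplitude-scaled at sites", {
  cfg <- sim_config(noise_sd = 0)
  geo <- generate_geometry(cfg, n_points = 300, seed = 6)
  f <- simulate_fields(geo, cfg)
  p1 <- synthesize_egms(geo, f, cfg, seed = 21)
  p2 <- synthesize_egms(geo, f, cfg, seed = 21)
  expect_identical(p1$bip[[1]]$samples, p2$bip[[1]]$samples)

  # far from scar and sites: bipolar post-QRS is quiet relative to the QRS
  far <- which(f$site_w < 1e-4 & f$scar_m < 0.02)
  lp_free <- FALSE
  for (i in far) {
    tr <- p1$bip[[i]]
    s <- segment(tr)
    if (amplitude(tr, s$post) < 0.05 * amplitude(tr, s$qrs)) lp_free <- TRUE
    if (lp_free) break
  }
  expect_true(lp_free)

  # amplitude-scale recovery: site vs remote QRS amplitude ratio tracks the
  # generator rule (amp factor x mean jitter), within a generous band
  site <- which(f$site_w > 0.7)
  a_site <- mean(vapply(site, function(i) {
    amplitude(p1$uni[[i]], segment(p1$uni[[i]])$qrs)
  }, numeric(1)))
  a_far <- mean(vapply(far, function(i) {
    amplitude(p1$uni[[i]], segment(p1$uni[[i]])$qrs)
  }, numeric(1)))
  expected <- 1 - (1 - cfg$amp_factor) * mean(pmin(1, f$amp_w[site] * 0.85))
  expect_equal(a_site / a_far, expected, tolerance = 0.15)
})

test_that("generate_study hits the target prevalence and is schema-stable", {
  st <- generate_study(sim_config())
  lab <- label_points(st, 6)
  expect_gte(mean(lab$label), 0.05)
  expect_lte(mean(lab$label), 0.10)
  expect_equal(nrow(st$maps), 16L)

  st2 <- generate_study(sim_config(seed = 2))
  expect_identical(names(st2$points), names(st$points))
  expect_false(identical(st$points$uni[[1]]$samples, st2$points$uni[[1]]$samples))

  st3 <- generate_study(sim_config())
  expect_identical(st$points$uni[[5]]$samples, st3$points$uni[[5]]$samples)
})

test_that("a study without VTs yields all-zero labels", {
  cfg <- tiny_sim_config(n_vts = 0L)
  st <- generate_study(cfg)
  expect_equal(nrow(st$sites), 0L)
  expect_warning(lab <- label_points(st), "no VT critical sites")
  expect_true(all(lab$label == 0L))
})
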