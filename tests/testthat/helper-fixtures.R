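# Fixture builders shared across test files. Everything is generated in code;
# no data files.

FS <- 2034.5

# A deterministic synthetic trace: R/S deflection at lat_ms plus a T-wave
# whose maximum upslope sits at rt_ms.
make_trace <- function(kind = "unipolar", fs = FS, dur_ms = 400,
                       lat_ms = 60, rt_ms = 280, a_r = 1, a_t = 0.4,
                       qrs_on_ms = 20, qrs_end_ms = 140, t_end_ms = 390) {
  t <- seq(0, dur_ms - 1000 / fs, by = 1000 / fs)
  w_r <- 7; w_t <- 24
  a <- (t - lat_ms) / w_r
  x <- -a_r * a * exp(-0.5 * a^2) +
    a_t * exp(-0.5 * ((t - (rt_ms + w_t)) / w_t)^2)
  egm_trace(x, fs, kind,
            qrs_on = round(qrs_on_ms / 1000 * fs) + 1,
            qrs_end = round(qrs_end_ms / 1000 * fs) + 1,
            t_end = if (kind == "unipolar") round(t_end_ms / 1000 * fs) + 1
                    else length(x))
}

# Minimal hand-built study: one map, a few points on a line, one VT site.
make_tiny_study <- function(n_points = 3, site_xyz = c(0, 0, 0),
                            point_dist = c(2, 5.9, 6.1)) {
  pts <- purrr::map(seq_len(n_points), function(i) {
    list(uni = make_trace("unipolar", lat_ms = 55 + i, rt_ms = 270 + 2 * i),
         bip = make_trace("bipolar", lat_ms = 55 + i, a_t = 0.05))
  })
  points <- tibble::tibble(
    map_id = "m1",
    point_id = sprintf("p%02d", seq_len(n_points)),
    x_mm = site_xyz[1] + point_dist[seq_len(n_points)],
    y_mm = site_xyz[2], z_mm = site_xyz[3],
    lat_ms = 55 + seq_len(n_points),
    rt_ms = 270 + 2 * seq_len(n_points),
    ari_ms = 215 + seq_len(n_points),
    uni = purrr::map(pts, "uni"), bip = purrr::map(pts, "bip"))
  new_study(
    subjects = "s1",
    maps = tibble::tibble(map_id = "m1", subject_id = "s1",
                          rhythm = "SR", protocol = "none"),
    points = points,
    sites = tibble::tibble(site_id = "vt1_s1", vt_id = "vt1", phase = "early",
                           x_mm = site_xyz[1], y_mm = site_xyz[2],
                           z_mm = site_xyz[3]))
}

# Small generator config used where a full study is needed quickly.
tiny_sim_config <- function(seed = 3L, ...) {
  sim_config(seed = seed,
             n_subjects = 1L,
             maps_per_subject = tibble::tibble(
               rhythm = c("SR", "RV"), protocol = c("none", "SE"),
               points = c(150L, 120L)),
             ...)
}

# A fabricated modelling table (features carry a known signal) for protocol
# tests that do not need real EGM extraction.
make_fake_table <- function(n_maps = 6, points_per_map = 80, n_groups = 12,
                            n_features = 6, signal = 2, seed = 1) {
  withr::with_seed(seed, {
    tab <- purrr::map_dfr(seq_len(n_maps), function(m) {
      n <- points_per_map
      lab <- rbinom(n, 1, 0.12)
      x <- matrix(rnorm(n * n_features), n, n_features)
      x[, 1] <- x[, 1] + signal * lab
      x[, 2] <- x[, 2] - 0.5 * signal * lab
      colnames(x) <- paste0("f", seq_len(n_features))
      dplyr::bind_cols(
        tibble::tibble(
          map_id = sprintf("m%02d", m),
          point_id = sprintf("m%02d_p%03d", m, seq_len(n)),
          label = lab,
          group_id = ifelse(lab == 1L,
                            sprintf("g%02d", sample.int(n_groups, n, TRUE)),
                            sprintf("neg_m%02d", m))),
        tibble::as_tibble(x))
    })
    tab$is_SR <- as.integer(tab$map_id %in% sprintf("m%02d", 1:3))
    tab$is_LV <- as.integer(!tab$is_SR)
    tab$is_RV <- 0L
    tab$is_BIV <- 0L
    tab
  })
}
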