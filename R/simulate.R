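#' Configuration for the synthetic electroanatomical-study generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' multi-map studies per subject on an ellipsoidal endocardial shell, a
#' contiguous low-voltage scar patch with a conducting channel, VT critical
#' sites (early/mid/late diastolic) placed inside the channel, and
#' signal-level effects near the critical sites matching the directions the
#' association analysis screens for: reduced amplitude, late high-frequency
#' fractionated components in bipolar EGMs, flattened T-waves and boosted
#' repolarization-gradient heterogeneity in unipolar EGMs, plus a per-map
#' random intercept on the log-odds of late-potential occurrence.
#'
#' The shell is scaled so that the expected fraction of points within
#' `label_radius_mm` of a critical site equals `target_prevalence` (the cap
#' area of a chord-radius ball on the shell), so prevalence is controlled by
#' construction.
#'
#' @param seed root seed; all randomness derives from it.
#' @param n_subjects number of subjects.
#' @param maps_per_subject tibble with columns `rhythm`, `protocol`,
#'   `points`: the maps acquired per subject and their point counts.
#' @param scar_fraction fraction of the shell covered by scar.
#' @param n_vts VTs mapped per subject.
#' @param sites_per_vt critical sites per VT (<= 3; phases early/mid/late).
#' @param amp_factor amplitude scale factor at critical sites (< 1).
#' @param late_potential_prob length-2: baseline and near-site probability of
#'   a late fractionated component in bipolar EGMs.
#' @param late_band_hz frequency band of late components (Hz).
#' @param t_flatten T-wave amplitude factor at critical sites (< 1).
#' @param ari_boost_ms amplitude of the ARI bump at critical sites (ms).
#' @param effect_sigma_mm spatial scale of near-site effects (mm).
#' @param noise_sd additive white noise (mV).
#' @param map_random_effect_sd SD of the per-map random intercept (log-odds).
#' @param target_prevalence expected positive-class fraction at
#'   `label_radius_mm`.
#' @param label_radius_mm labeling radius used to size the shell (mm).
#' @param fs sampling rate (Hz).
#' @param duration_ms trace duration (ms).
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 4L,
                       maps_per_subject = tibble(
                         rhythm   = c("SR", "LV", "RV", "BIV"),
                         protocol = c("none", "SE", "SE", "SE"),
                         points   = c(250L, 180L, 180L, 120L)),
                       scar_fraction = 0.25,
                       n_vts = 2L,
                       sites_per_vt = 3L,
                       amp_factor = 0.45,
                       late_potential_prob = c(base = 0.04, site = 0.65),
                       late_band_hz = c(40, 160),
                       t_flatten = 0.35,
                       ari_boost_ms = 25,
                       effect_sigma_mm = 4,
                       noise_sd = 0.02,
                       map_random_effect_sd = 0.5,
                       target_prevalence = 0.0731,
                       label_radius_mm = 6,
                       fs = 2034.5,
                       duration_ms = 400) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              maps_per_subject = as_tibble(maps_per_subject),
              scar_fraction = scar_fraction, n_vts = as.integer(n_vts),
              sites_per_vt = as.integer(sites_per_vt),
              amp_factor = amp_factor,
              late_potential_prob = late_potential_prob,
              late_band_hz = late_band_hz, t_flatten = t_flatten,
              ari_boost_ms = ari_boost_ms, effect_sigma_mm = effect_sigma_mm,
              noise_sd = noise_sd,
              map_random_effect_sd = map_random_effect_sd,
              target_prevalence = target_prevalence,
              label_radius_mm = label_radius_mm,
              fs = fs, duration_ms = duration_ms)
  fr <- c(cfg$scar_fraction, cfg$target_prevalence,
          cfg$amp_factor, cfg$t_flatten, cfg$late_potential_prob)
  if (any(fr < 0 | fr > 1)) abort("fractions and probabilities must be in [0, 1]")
  if (cfg$sites_per_vt > 3L) abort("sites_per_vt must be <= 3 (early/mid/late)")
  class(cfg) <- "sim_config"
  cfg
}

# Ellipsoid surface area (Thomsen approximation).
ellipsoid_area <- function(axes) {
  p <- 1.6075
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Shell axes solved so the expected labeled fraction matches the target:
# union of disjoint caps of chord radius r over the shell area.
shell_axes <- function(cfg) {
  n_sites <- cfg$n_vts * cfg$sites_per_vt
  if (n_sites == 0L) return(c(1, 1, 1.3) * 25)
  area <- n_sites * pi * cfg$label_radius_mm^2 / cfg$target_prevalence
  s <- sqrt(area / ellipsoid_area(c(1, 1, 1.3)))
  c(s, s, 1.3 * s)
}

# Uniform sample on the ellipsoid surface (rejection on the area element).
sample_shell <- function(n, axes) {
  out <- matrix(NA_real_, 0, 3)
  m_max <- max(axes[2] * axes[3], axes[1] * axes[3], axes[1] * axes[2])
  while (nrow(out) < n) {
    k <- 2L * (n - nrow(out)) + 16L
    u <- matrix(rnorm(3 * k), k, 3)
    u <- u / sqrt(rowSums(u^2))
    m <- sqrt((u[, 1] * axes[2] * axes[3])^2 +
              (u[, 2] * axes[1] * axes[3])^2 +
              (u[, 3] * axes[1] * axes[2])^2)
    acc <- runif(k) < m / m_max
    p <- sweep(u[acc, , drop = FALSE], 2, axes, "*")
    out <- rbind(out, p)
  }
  out[seq_len(n), , drop = FALSE]
}

# Point on the shell in direction v (unit-ish), by radial scaling.
shell_point <- function(v, axes) {
  v / sqrt(sum((v / axes)^2))
}

# Rotate unit vector u towards unit vector w by angle theta (radians).
rotate_towards <- function(u, w, theta) {
  w_perp <- w - sum(w * u) * u
  if (sqrt(sum(w_perp^2)) < 1e-12) return(u)
  w_perp <- w_perp / sqrt(sum(w_perp^2))
  cos(theta) * u + sin(theta) * w_perp
}

#' Generate one subject's geometry
#'
#' Samples a point cloud on an ellipsoidal shell (axes solved from the target
#' prevalence), marks a contiguous scar patch (a cap sized to
#' `scar_fraction`), and places the VT critical sites along channels through
#' the scar, spaced so their labeling balls do not overlap.
#'
#' @param cfg a [sim_config()].
#' @param n_points points to sample (>= 20).
#' @param seed seed for this geometry (defaults to the config root seed).
#' @return A list with `xyz` (n x 3, mm), `scar` (logical), `sites` (tibble:
#'   site_id, vt_id, phase, x_mm, y_mm, z_mm), `axes`, `scar_centre`,
#'   `scar_radius_mm`.
#' @export
generate_geometry <- function(cfg, n_points = 250L, seed = cfg$seed) {
  if (n_points < 20L) abort("n_points must be >= 20")
  axes <- shell_axes(cfg)
  area <- ellipsoid_area(axes)
  scar_radius <- sqrt(cfg$scar_fraction * area / pi)
  site_gap <- 2 * cfg$label_radius_mm + 1
  span <- (cfg$sites_per_vt - 1) * site_gap
  if (cfg$n_vts > 0L && span > 2.2 * max(scar_radius, site_gap)) {
    abort("infeasible config: VT channel does not fit inside the scar patch")
  }
  withr::with_seed(seed, {
    xyz <- sample_shell(n_points, axes)
    # scar centred on the anterior wall with a little jitter
    cdir <- c(1, 0.15 * rnorm(1), 0.3 + 0.1 * rnorm(1))
    cdir <- cdir / sqrt(sum(cdir^2))
    centre <- shell_point(cdir, axes)
    scar <- if (cfg$scar_fraction > 0) {
      sqrt(rowSums(sweep(xyz, 2, centre)^2)) <= scar_radius
    } else rep(FALSE, n_points)

    sites <- tibble(site_id = character(0), vt_id = character(0),
                    phase = character(0), x_mm = numeric(0),
                    y_mm = numeric(0), z_mm = numeric(0))
    if (cfg$n_vts > 0L) {
      R <- mean(axes)
      # orthonormal tangent basis at the scar centre, randomly oriented:
      # each VT channel is a chain of sites along e2, channels offset along e1
      ref <- if (abs(cdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * cdir) * cdir; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(cdir[2] * e1[3] - cdir[3] * e1[2],
              cdir[3] * e1[1] - cdir[1] * e1[3],
              cdir[1] * e1[2] - cdir[2] * e1[1])
      phi <- runif(1, 0, 2 * pi)
      b1 <- cos(phi) * e1 + sin(phi) * e2
      b2 <- -sin(phi) * e1 + cos(phi) * e2
      for (v in seq_len(cfg$n_vts)) {
        a <- (v - (cfg$n_vts + 1) / 2) * site_gap
        for (k in seq_len(cfg$sites_per_vt)) {
          b <- (k - (cfg$sites_per_vt + 1) / 2) * site_gap
          u <- cdir + (a * b1 + b * b2) / R
          p <- shell_point(u / sqrt(sum(u^2)), axes)
          sites <- dplyr::add_row(sites,
            site_id = sprintf("vt%d_s%d", v, k), vt_id = sprintf("vt%d", v),
            phase = phase_levels[min(k, 3L)],
            x_mm = p[1], y_mm = p[2], z_mm = p[3])
        }
      }
      # labeling balls must stay essentially disjoint for the prevalence rule
      if (nrow(sites) > 1L) {
        sxyz <- as.matrix(sites[, c("x_mm", "y_mm", "z_mm")])
        dd <- cross_dist(sxyz, sxyz); diag(dd) <- Inf
        if (min(dd) < 1.5 * cfg$label_radius_mm) {
          abort("infeasible config: critical sites too close for the target prevalence")
        }
      }
    }
    list(xyz = xyz, scar = scar, sites = sites, axes = axes,
         scar_centre = centre, scar_radius_mm = scar_radius)
  })
}

# Resample the point cloud of an existing subject layout (scar and sites
# fixed): one subject's maps share a heart but not mapping points.
resample_geometry <- function(geo, cfg, n_points, seed) {
  withr::with_seed(seed, {
    xyz <- sample_shell(n_points, geo$axes)
    geo$xyz <- xyz
    geo$scar <- if (cfg$scar_fraction > 0) {
      sqrt(rowSums(sweep(xyz, 2, geo$scar_centre)^2)) <= geo$scar_radius_mm
    } else rep(FALSE, n_points)
    geo
  })
}

pacing_origin <- function(rhythm, axes) {
  dirs <- list(SR = c(0, 0, -1), LV = c(-1, 0, 0.2),
               RV = c(0.9, 0.4, 0.2), BIV = NULL)
  if (rhythm == "BIV") {
    list(shell_point(dirs$LV, axes), shell_point(dirs$RV, axes))
  } else {
    list(shell_point(dirs[[rhythm]] / sqrt(sum(dirs[[rhythm]]^2)), axes))
  }
}

#' Ground-truth activation and repolarization fields
#'
#' Activation time is a propagation-time field: distance from the pacing
#' origin divided by conduction speed, slowed inside scar. The
#' activation-recovery interval is a smooth field with a Gaussian bump near
#' each critical site (boosting its spatial gradient there), and
#' `RT = LAT + ARI` everywhere by construction.
#'
#' @param geometry from [generate_geometry()].
#' @param cfg a [sim_config()].
#' @param rhythm one of `"SR","LV","RV","BIV"` (selects the pacing origin).
#' @param speed_mm_ms conduction speed outside scar.
#' @param scar_slowing multiplicative slowing of propagation inside scar.
#' @param ari_noise_sd SD of the spatially rough ARI noise (ms), giving the
#'   gradient maps a realistic background level.
#' @param seed seed for the ARI noise draw.
#' @return A tibble with `lat_ms`, `ari_ms`, `rt_ms` and helper columns
#'   `site_w` (near-site effect weight in 0..1) and `scar`.
#' @export
simulate_fields <- function(geometry, cfg, rhythm = "SR",
                            speed_mm_ms = 1.5, scar_slowing = 1.8,
                            ari_noise_sd = 3, seed = cfg$seed) {
  xyz <- geometry$xyz
  ari_noise <- withr::with_seed(child_seed(seed, "arinoise"),
                                rnorm(nrow(xyz), 0, ari_noise_sd))
  origins <- pacing_origin(rhythm, geometry$axes)
  lat <- do.call(pmin, lapply(origins, function(o) {
    sqrt(rowSums(sweep(xyz, 2, o)^2)) / speed_mm_ms
  }))
  lat <- lat * ifelse(geometry$scar, scar_slowing, 1)
  lat <- 25 + pmin(lat, 110)

  site_w <- rep(0, nrow(xyz))
  if (nrow(geometry$sites)) {
    d <- cross_dist(xyz, as.matrix(geometry$sites[, c("x_mm", "y_mm", "z_mm")]))
    dmin <- apply(d, 1, min)
    site_w <- exp(-dmin^2 / (2 * cfg$effect_sigma_mm^2))
  }
  # graded scar membership: 1 deep inside the patch, 0 outside, smooth border.
  # Most EGM abnormality is scar-wide; the critical channel only adds to it,
  # so scar points far from the channel are hard negatives.
  scar_m <- if (cfg$scar_fraction > 0) {
    dc <- sqrt(rowSums(sweep(xyz, 2, geometry$scar_centre)^2))
    plogis((geometry$scar_radius_mm - dc) / 4)
  } else rep(0, nrow(xyz))
  # amplitude loss saturates across the scar: dense scar looks uniformly
  # low-voltage, so voltage alone separates scar from healthy tissue but not
  # the critical channel from the rest of the scar
  scar_sat <- pmin(1, scar_m / 0.5)
  amp_w <- pmin(1, 0.8 * scar_sat + 0.1 * site_w)
  rep_w <- pmin(1, 0.35 * scar_sat + 0.5 * site_w)
  u <- sweep(xyz, 2, geometry$axes, "/")   # smooth base variation over the shell
  ari <- 205 + 18 * u[, 3] + 8 * u[, 1] - 12 * scar_m + cfg$ari_boost_ms * site_w +
    ari_noise
  tibble(lat_ms = lat, ari_ms = ari, rt_ms = lat + ari,
         site_w = site_w, scar_m = scar_m, amp_w = amp_w, rep_w = rep_w,
         scar = geometry$scar)
}

gauss_deriv <- function(t, centre, width) {
  a <- (t - centre) / width
  -a * exp(-0.5 * a^2)   # peaks at centre - width, trough at centre + width
}

wavelet <- function(t, centre, freq, width) {
  sin(2 * pi * freq * (t - centre)) * exp(-0.5 * ((t - centre) / width)^2)
}

#' Synthesize unipolar and bipolar electrograms
#'
#' Single-template morphology with parametric distortions. The unipolar EGM
#' is an R/S deflection at the local activation time plus a T-wave whose
#' maximum upslope falls at the repolarization time; near critical sites its
#' amplitude is scaled down and the T-wave flattened. The bipolar EGM is the
#' difference of two spatially offset unipolar sources (3 mm electrode
#' spacing), plus late fractionated high-frequency bursts after the QRS whose
#' probability is elevated near sites (with a per-map random intercept on the
#' log-odds), plus near-site high-frequency components inside the QRS.
#' White noise of `cfg$noise_sd` mV is added to both channels.
#'
#' @param geometry from [generate_geometry()].
#' @param fields from [simulate_fields()].
#' @param cfg a [sim_config()].
#' @param map_effect per-map random intercept (log-odds) for late potentials.
#' @param seed RNG seed for noise and burst placement.
#' @return A tibble of map points: `point_id`, coordinates, ground-truth
#'   annotations (`lat_ms`, `rt_ms`, `ari_ms`) and trace list-columns
#'   `uni`, `bip`.
#' @export
synthesize_egms <- function(geometry, fields, cfg, map_effect = 0,
                            seed = cfg$seed) {
  fs <- cfg$fs
  n_samp <- as.integer(round(cfg$duration_ms / 1000 * fs))
  t_ms <- (seq_len(n_samp) - 1) / fs * 1000
  qrs_on <- ms_to_sample(18, fs)
  qrs_end <- ms_to_sample(142, fs)
  t_end <- ms_to_sample(cfg$duration_ms - 8, fs)
  n <- nrow(geometry$xyz)

  withr::with_seed(seed, {
    uni_l <- vector("list", n); bip_l <- vector("list", n)
    jitter <- runif(n, 0.6, 1.1)   # per-point effect heterogeneity
    amp_fac <- 1 - (1 - cfg$amp_factor) * pmin(1, fields$amp_w * jitter)
    t_fac <- 1 - (1 - cfg$t_flatten) * pmin(1, fields$rep_w * jitter)
    lp_w <- pmin(1, 0.5 * pmin(1, fields$scar_m / 0.5) + 0.45 * fields$site_w)
    lp_logit <- qlogis(cfg$late_potential_prob[["base"]]) +
      (qlogis(cfg$late_potential_prob[["site"]]) -
         qlogis(cfg$late_potential_prob[["base"]])) * lp_w + map_effect
    has_lp <- runif(n) < plogis(lp_logit)

    for (i in seq_len(n)) {
      lat <- min(fields$lat_ms[i], sample_to_ms(qrs_end, fs) - 15)
      rt <- min(fields$rt_ms[i], sample_to_ms(t_end, fs) - 40)
      a_r <- 2.0 * amp_fac[i] * runif(1, 0.9, 1.1)
      a_t <- 0.55 * t_fac[i] * amp_fac[i] * runif(1, 0.9, 1.1)
      w_r <- 7; w_t <- 24

      u1 <- a_r * gauss_deriv(t_ms, lat, w_r) +
        a_t * exp(-0.5 * ((t_ms - (rt + w_t)) / w_t)^2)
      dlat <- 3 / 1.5   # 3 mm electrode spacing / conduction speed
      # the far-field T-wave is nearly common-mode across the 3-mm pair, so
      # it cancels almost completely in the bipolar difference
      u2 <- 0.88 * a_r * gauss_deriv(t_ms, lat + dlat, w_r) +
        0.99 * a_t * exp(-0.5 * ((t_ms - (rt + w_t)) / w_t)^2)
      bip <- u1 - u2

      fr_w <- min(1, 0.45 * fields$scar_m[i] + 0.55 * fields$site_w[i])
      if (fr_w > 0.05) {
        # high-frequency fractionation inside the QRS, strongest in the channel
        bip <- bip + 0.15 * amp_fac[i] * fr_w *
          wavelet(t_ms, lat + runif(1, 5, 18), runif(1, 120, 160), 6)
      }
      if (has_lp[i]) {
        for (b in seq_len(sample(2:3, 1))) {
          f0 <- runif(1, cfg$late_band_hz[1], cfg$late_band_hz[2])
          t0 <- sample_to_ms(qrs_end, fs) + runif(1, 12, 70)
          bip <- bip + 0.16 * amp_fac[i] * runif(1, 0.7, 1.3) *
            wavelet(t_ms, t0, f0, 8)
        }
      }
      if (cfg$noise_sd > 0) {
        u1 <- u1 + rnorm(n_samp, 0, cfg$noise_sd)
        bip <- bip + rnorm(n_samp, 0, cfg$noise_sd)
      }
      uni_l[[i]] <- egm_trace(u1, fs, "unipolar", qrs_on, qrs_end, t_end)
      bip_l[[i]] <- egm_trace(bip, fs, "bipolar", qrs_on, qrs_end, n_samp)
    }
    tibble(point_id = sprintf("p%04d", seq_len(n)),
           x_mm = geometry$xyz[, 1], y_mm = geometry$xyz[, 2],
           z_mm = geometry$xyz[, 3],
           lat_ms = fields$lat_ms, rt_ms = fields$rt_ms,
           ari_ms = fields$rt_ms - fields$lat_ms,
           uni = uni_l, bip = bip_l)
  })
}

#' Generate a complete synthetic study
#'
#' Runs geometry, field and EGM synthesis for every subject and map in the
#' configuration, all deterministically from the root seed, and verifies that
#' the realized positive-class prevalence at the labeling radius is within
#' 30% (relative) of the configured target.
#'
#' @param cfg a [sim_config()].
#' @return A validated `vts_study`.
#' @export
generate_study <- function(cfg = sim_config()) {
  subjects <- sprintf("subj%02d", seq_len(cfg$n_subjects))
  maps <- tibble(map_id = character(0), subject_id = character(0),
                 rhythm = character(0), protocol = character(0))
  points <- NULL
  sites <- NULL
  for (si in seq_along(subjects)) {
    geo_seed <- child_seed(cfg$seed, paste0("geom", si))
    # each subject's heart lives in its own region of the shared frame, as
    # separate animals' maps are never co-registered
    offset <- c(300 * (si - 1), 0, 0)
    layout <- generate_geometry(cfg, n_points = 20L, seed = geo_seed)
    for (mi in seq_len(nrow(cfg$maps_per_subject))) {
      row <- cfg$maps_per_subject[mi, ]
      map_id <- sprintf("%s_%s_%s", subjects[si], row$rhythm, row$protocol)
      geo <- resample_geometry(layout, cfg, n_points = row$points,
                               seed = child_seed(geo_seed, map_id))
      flds <- simulate_fields(geo, cfg, rhythm = row$rhythm,
                              seed = child_seed(geo_seed, paste0("fld", map_id)))
      b_map <- withr::with_seed(child_seed(geo_seed, paste0("re", map_id)),
                                rnorm(1, 0, cfg$map_random_effect_sd))
      pts <- synthesize_egms(geo, flds, cfg, map_effect = b_map,
                             seed = child_seed(geo_seed, paste0("egm", map_id)))
      pts <- dplyr::mutate(pts, map_id = map_id, .before = 1,
                           x_mm = .data$x_mm + offset[1],
                           y_mm = .data$y_mm + offset[2],
                           z_mm = .data$z_mm + offset[3])
      maps <- dplyr::add_row(maps, map_id = map_id, subject_id = subjects[si],
                             rhythm = row$rhythm, protocol = row$protocol)
      points <- dplyr::bind_rows(points, pts)
      if (mi == 1L) {
        s <- geo$sites
        if (nrow(s)) {
          s$site_id <- paste0(subjects[si], "_", s$site_id)
          s$vt_id <- paste0(subjects[si], "_", s$vt_id)
          s$x_mm <- s$x_mm + offset[1]
          s$y_mm <- s$y_mm + offset[2]
          s$z_mm <- s$z_mm + offset[3]
        }
        sites <- dplyr::bind_rows(sites, s)
      }
    }
  }
  study <- new_study(subjects, maps, points, sites %||%
                       tibble(site_id = character(0), vt_id = character(0),
                              phase = character(0), x_mm = numeric(0),
                              y_mm = numeric(0), z_mm = numeric(0)))
  if (nrow(study$sites)) {
    lab <- label_points(study, radius_mm = cfg$label_radius_mm)
    prev <- mean(lab$label)
    if (abs(prev - cfg$target_prevalence) > 0.3 * cfg$target_prevalence) {
      abort(sprintf(
        "prevalence %.4f outside 30%% of target %.4f: geometry/site layout infeasible at this size",
        prev, cfg$target_prevalence))
    }
  }
  study
}

#' Simulate grouped binary data from a random-intercept logistic model
#'
#' A small generator used to check that the mixed-effects association fit
#' recovers a known odds ratio: `logit P(y=1) = intercept + b_map + beta * x`
#' with `x ~ N(0, 1)` and `b_map ~ N(0, re_sd)` per map.
#'
#' @param n_maps,points_per_map design size.
#' @param odds_ratio true odds ratio per 1-SD increase of `x`.
#' @param intercept log-odds intercept (controls prevalence).
#' @param re_sd random-intercept SD (log-odds); 0 gives a pooled logistic.
#' @param seed RNG seed.
#' @return A tibble with `map_id`, `x`, `label`.
#' @export
simulate_mixed_logistic <- function(n_maps = 20L, points_per_map = 500L,
                                    odds_ratio = 2, intercept = -2.5,
                                    re_sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    b <- rnorm(n_maps, 0, re_sd)
    purrr::map_dfr(seq_len(n_maps), function(m) {
      x <- rnorm(points_per_map)
      p <- plogis(intercept + b[m] + log(odds_ratio) * x)
      tibble(map_id = sprintf("m%02d", m), x = x,
             label = rbinom(points_per_map, 1L, p))
    })
  })
}
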