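#' Remove duplicated mapping points
#'
#' Within each map, points whose coordinates coincide (within
#' `tolerance_mm`) and whose unipolar and bipolar samples are identical
#' collapse to the first occurrence. The number of removed points is
#' reported via a message.
#'
#' @param study a `vts_study`.
#' @param tolerance_mm coordinate tolerance for duplicates (default 0.01).
#' @return The deduplicated study.
#' @export
deduplicate <- function(study, tolerance_mm = 0.01) {
  p <- study$points
  keep <- rep(TRUE, nrow(p))
  for (mid in unique(p$map_id)) {
    idx <- which(p$map_id == mid)
    if (length(idx) < 2L) next
    xyz <- as.matrix(p[idx, c("x_mm", "y_mm", "z_mm")])
    key <- paste(round(xyz[, 1] / tolerance_mm), round(xyz[, 2] / tolerance_mm),
                 round(xyz[, 3] / tolerance_mm))
    for (k in unique(key[duplicated(key)])) {
      grp <- idx[key == k]
      first <- grp[1]
      for (j in grp[-1]) {
        same <- identical(p$uni[[j]]$samples, p$uni[[first]]$samples) &&
          identical(p$bip[[j]]$samples, p$bip[[first]]$samples)
        if (same) keep[j] <- FALSE
      }
    }
  }
  removed <- sum(!keep)
  if (removed > 0L) {
    message(sprintf("deduplicate: removed %d duplicated point(s)", removed))
    study$points <- p[keep, ]
  }
  study
}

#' Label potential ablation targets by distance to VT critical sites
#'
#' A point is positive (label 1) when its 3D Euclidean distance to any VT
#' critical site is at most `radius_mm` (closed ball). Each positive point's
#' `group_id` is the id of its nearest critical site (ties broken by lowest
#' `site_id`); negatives are grouped by map. These groups are the leakage
#' units the split/fold machinery never separates.
#'
#' @param study a `vts_study`.
#' @param radius_mm labeling radius in mm (default 6).
#' @return Tibble: `map_id`, `point_id`, `dist_mm` (to nearest site),
#'   `label`, `group_id`.
#' @export
label_points <- function(study, radius_mm = 6) {
  p <- study$points
  s <- study$sites
  out <- tibble(map_id = p$map_id, point_id = p$point_id)
  if (!nrow(s)) {
    warn("study has no VT critical sites: all labels are 0")
    out$dist_mm <- Inf
    out$label <- 0L
    out$group_id <- paste0("neg_", p$map_id)
    return(out)
  }
  s <- s[order(s$site_id), ]
  d <- cross_dist(as.matrix(p[, c("x_mm", "y_mm", "z_mm")]),
                  as.matrix(s[, c("x_mm", "y_mm", "z_mm")]))
  nearest <- apply(d, 1, which.min)   # first minimum = lowest site_id on ties
  out$dist_mm <- d[cbind(seq_len(nrow(p)), nearest)]
  out$label <- as.integer(out$dist_mm <= radius_mm)
  out$group_id <- ifelse(out$label == 1L, s$site_id[nearest],
                         paste0("neg_", p$map_id))
  out
}

#' Label prevalence across a radius sweep
#'
#' Re-labels the study at each radius and reports the positive-class
#' prevalence; label sets are nested (non-decreasing in the radius).
#'
#' @param study a `vts_study`.
#' @param radii_mm ascending radii (default 3..10 mm).
#' @return A list with `labels` (tibble: map_id, point_id, one label column
#'   `r<radius>` per radius) and `prevalence` (tibble: radius_mm, prevalence).
#' @export
radius_sweep <- function(study, radii_mm = 3:10) {
  if (is.unsorted(radii_mm)) abort("radii must be sorted ascending")
  base <- label_points(study, radius_mm = max(radii_mm))
  labels <- base[, c("map_id", "point_id")]
  prev <- numeric(length(radii_mm))
  for (i in seq_along(radii_mm)) {
    lab <- as.integer(base$dist_mm <= radii_mm[i])
    labels[[sprintf("r%g", radii_mm[i])]] <- lab
    prev[i] <- mean(lab)
  }
  list(labels = labels,
       prevalence = tibble(radius_mm = radii_mm, prevalence = prev))
}
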