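#' Spatial gradient of a scalar field over a 3D point cloud
#'
#' For each mapping point `p` with value `v(p)`, the gradient is the mean of
#' `|v(p) - v(q)| / ||p - q||` over all neighbours `q` within `radius_mm`
#' (closed ball, 3D chord distance). Points at exactly zero distance
#' (duplicate coordinates) and points with missing values are excluded from
#' neighbour sets. Gradients are computed per map; never across maps.
#'
#' @param xyz numeric matrix (n x 3) of point coordinates in mm.
#' @param values numeric vector of length n (ms); may contain `NA`.
#' @param radius_mm neighbourhood radius (default 10).
#' @return Numeric vector of gradients (ms/mm); `NA` where a point has no
#'   neighbour with a value, or its own value is missing.
#' @export
spatial_gradient <- function(xyz, values, radius_mm = 10) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n != length(values)) abort("values length must match number of points")
  if (radius_mm <= 0) abort("radius_mm must be > 0")
  out <- rep(NA_real_, n)
  ok <- which(is.finite(values))
  if (length(ok) < 2L) return(out)
  m <- xyz[ok, , drop = FALSE]
  v <- values[ok]
  for (i in seq_along(ok)) {
    d <- sqrt(rowSums(sweep(m, 2, m[i, ])^2))
    nb <- which(d > 0 & d <= radius_mm)
    if (length(nb)) {
      out[ok[i]] <- mean(abs(v[i] - v[nb]) / d[nb])
    }
  }
  out
}

# Per-map gradients of LAT, RT and ARI appended to a points tibble.
map_spatial_gradients <- function(points, radius_mm = 10) {
  points |>
    dplyr::group_by(.data$map_id) |>
    dplyr::group_modify(function(df, key) {
      xyz <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
      df$GradAT <- spatial_gradient(xyz, df$lat_ms, radius_mm)
      df$GradRT <- spatial_gradient(xyz, df$rt_ms, radius_mm)
      df$GradARI <- spatial_gradient(xyz, df$ari_ms, radius_mm)
      df
    }) |>
    dplyr::ungroup()
}
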